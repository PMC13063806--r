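## Trajectory container: coordinates as an (n_atoms x 3 x n_frames) array
## plus per-frame rectangular box edges and times.  Memory-friendly for the
## coarse systems this package targets and O(1) frame slicing.

#' Construct a trajectory
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm).
#' @param box numeric matrix `n_frames x 3` of rectangular box edges (nm),
#'   or a length-3 vector recycled to all frames.
#' @param time numeric vector of frame times (ns); defaults to `0:(n-1)`.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, box, time = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (nrow(box) != nf) stop_input("box must have one row per frame")
  if (any(!is.finite(box)) || any(box <= 0))
    stop_input("box edges must be positive and finite")
  if (any(!is.finite(coords))) stop_input("coordinates must be finite")
  if (is.null(time)) time <- seq_len(nf) - 1
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, t = [%g, %g] ns\n",
              n_atoms(x), n_frames(x), x$time[1], x$time[n_frames(x)]))
  cat(sprintf("mean box: %.3f x %.3f x %.3f nm\n",
              mean(x$box[, 1]), mean(x$box[, 2]), mean(x$box[, 3])))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame
#'
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return list with `coords` (N x 3 matrix), `box` (length 3), `time`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  list(coords = traj$coords[, , i, drop = TRUE],
       box = traj$box[i, ], time = traj$time[i])
}

## Frame-wise box areas (x*y), nm^2.
box_area_series <- function(traj) traj$box[, 1] * traj$box[, 2]

## ----------------------------------------------------------------------
## GRO format (fixed-width, nm, box on the final line of each frame)

#' Read a (possibly multi-frame) GRO file
#'
#' Positions are parsed as nm from the fixed GRO columns; each frame must
#' end with a box line.  Triclinic boxes (non-zero off-diagonal components)
#' are rejected: the package only supports rectangular boxes.
#'
#' @param path path to a `.gro` file.
#' @return a `trajectory`; atom and residue names of the first frame are
#'   attached as attributes `atom_name` and `residue_id`.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stop_input("empty GRO file: %s", path)
  frames <- list(); boxes <- list(); times <- c()
  atom_names <- NULL; res_ids <- NULL
  i <- 1; nf <- 0; natoms_ref <- NA
  while (i <= length(lines)) {
    if (i + 1 > length(lines)) stop_input("truncated GRO frame at line %d", i)
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(natoms)) stop_input("bad atom-count line at line %d", i + 1)
    if (!is.na(natoms_ref) && natoms != natoms_ref)
      stop_input("atom-count mismatch between frames (%d vs %d)",
                 natoms, natoms_ref)
    natoms_ref <- natoms
    if (i + 1 + natoms + 1 > length(lines))
      stop_input("GRO frame starting at line %d is missing its box line", i)
    at <- lines[(i + 2):(i + 1 + natoms)]
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    if (any(!is.finite(xyz)))
      stop_input("unparseable coordinates in GRO frame starting at line %d", i)
    if (is.null(atom_names)) {
      atom_names <- trimws(substr(at, 11, 15))
      res_ids <- as.integer(substr(at, 1, 5))
    }
    boxline <- as.numeric(strsplit(trimws(lines[i + 1 + natoms + 1]),
                                   "\\s+")[[1]])
    if (length(boxline) < 3 || any(!is.finite(boxline[1:3])))
      stop_input("missing or invalid box line in GRO frame at line %d",
                 i + 1 + natoms + 1)
    if (length(boxline) > 3 && any(abs(boxline[-(1:3)]) > 1e-9))
      stop_input("triclinic box not supported (off-diagonal components present)")
    tm <- NA_real_
    if (grepl("t=", title))
      tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([0-9.eE+-]+).*", "\\1",
                                            title)))
    nf <- nf + 1
    frames[[nf]] <- xyz; boxes[[nf]] <- boxline[1:3]; times[nf] <- tm
    i <- i + 1 + natoms + 2
  }
  coords <- array(unlist(frames), c(natoms_ref, 3, nf))
  if (all(is.na(times))) times <- seq_len(nf) - 1
  tr <- trajectory(coords, do.call(rbind, boxes), times)
  attr(tr, "atom_name") <- atom_names
  attr(tr, "residue_id") <- res_ids
  tr
}

#' Write a trajectory as (multi-frame) GRO
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @param topology optional `topology` supplying atom/residue names;
#'   defaults to generic names.
#' @export
write_gro <- function(traj, path, topology = NULL) {
  na <- n_atoms(traj)
  if (is.null(topology)) {
    atom_name <- sprintf("A%d", seq_len(na) %% 100000)
    res_id <- seq_len(na); res_name <- rep("MOL", na)
  } else {
    stopifnot(nrow(topology) == na)
    atom_name <- topology$atom_name
    res_id <- topology$residue_id
    res_name <- substr(topology$species, 1, 5)
  }
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f]
    writeLines(sprintf("frame t= %.4f", traj$time[f]), con)
    writeLines(sprintf("%5d", na), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       res_id %% 100000, res_name,
                       substr(atom_name, 1, 5), seq_len(na) %% 100000,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1],
                       traj$box[f, 2], traj$box[f, 3]), con)
  }
  invisible(path)
}

## ----------------------------------------------------------------------
## XYZ format (Angstrom on disk, converted to nm in memory)

#' Read a (possibly multi-frame) XYZ file
#'
#' XYZ carries no box; supply one. Coordinates on disk are Angstrom and
#' converted to nm.
#'
#' @param path path to an `.xyz` file.
#' @param box length-3 box edges in nm to attach to every frame.
#' @return a `trajectory` with attribute `atom_name` (the element column).
#' @export
read_xyz <- function(path, box) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stop_input("empty XYZ file: %s", path)
  frames <- list(); i <- 1; nf <- 0; natoms_ref <- NA; elements <- NULL
  while (i <= length(lines)) {
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) stop_input("bad atom-count line at line %d", i)
    if (!is.na(natoms_ref) && natoms != natoms_ref)
      stop_input("atom-count mismatch between frames (%d vs %d)",
                 natoms, natoms_ref)
    natoms_ref <- natoms
    if (i + 1 + natoms > length(lines))
      stop_input("truncated XYZ frame at line %d", i)
    toks <- strsplit(trimws(lines[(i + 2):(i + 1 + natoms)]), "\\s+")
    if (is.null(elements)) elements <- vapply(toks, `[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))) / 10
    nf <- nf + 1; frames[[nf]] <- xyz
    i <- i + 2 + natoms
  }
  coords <- array(unlist(frames), c(natoms_ref, 3, nf))
  tr <- trajectory(coords, box)
  attr(tr, "atom_name") <- elements
  tr
}

#' Write a trajectory as XYZ (Angstrom on disk)
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @param elements optional element symbols (defaults to "C").
#' @export
write_xyz <- function(traj, path, elements = NULL) {
  na <- n_atoms(traj)
  if (is.null(elements)) elements <- rep("C", na)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f] * 10
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%-3s %12.5f %12.5f %12.5f", elements,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory, dispatching on format
#'
#' @param path input file.
#' @param format `"gro"`, `"xyz"`, or `NULL` to guess from the extension.
#' @param ... passed to the format reader (`box` for XYZ).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, format = NULL, ...) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         gro = read_gro(path),
         xyz = read_xyz(path, ...),
         stop_input("unsupported trajectory format: '%s'", format))
}

#' Write a results table as TSV
#'
#' Writes any data.frame of results (metrics, contact summaries, isotherm
#' features) as a tab-separated file with a header.
#'
#' @param table a data.frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
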
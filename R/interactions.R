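## Interaction machinery: geometric hydrogen-bond detection, heavy-atom
## contact counting per lipid species/subregion (cell-list accelerated,
## with an all-pairs reference path), minimum-distance traces, the
## cumulative strong-binding-time statistic, and Shrake-Rupley SASA
## partitioned between lipid headgroups and tails.

#' Detect hydrogen bonds in a frame by geometric criteria
#'
#' A bond is recorded iff the donor-acceptor minimum-image distance is
#' `<= d_cut` AND the donor-hydrogen-acceptor angle is `>= angle_cut`.
#' Defaults are the conventional 3.0 Angstrom / 150 degree criteria
#' (expressed here as 0.30 nm).
#'
#' @param frame single frame (list with `coords`, `box`).
#' @param topology a `topology` with donor/hydrogen/acceptor roles and
#'   `donor_of` links.
#' @param d_cut donor-acceptor distance cutoff, nm.
#' @param angle_cut D-H-A angle cutoff, degrees.
#' @param pair_filter optional function `(donor_species, acceptor_species)
#'   -> logical` restricting which species pairs are reported, or a
#'   two-column matrix/data.frame of allowed (donor, acceptor) species.
#' @param exclude_same_residue drop bonds within one residue.
#' @return data.frame of class `hbond_records` with donor / hydrogen /
#'   acceptor atom ids and names, species, distance (nm) and angle (deg).
#' @export
detect_hbonds <- function(frame, topology, d_cut = 0.30, angle_cut = 150,
                          pair_filter = NULL, exclude_same_residue = TRUE) {
  hyd <- which(topology$is_hydrogen)
  acc <- which(topology$is_acceptor)
  if (length(hyd) && anyNA(topology$donor_of[hyd]))
    stop_input("hydrogen without donor parent in topology")
  out <- list()
  if (length(hyd) && length(acc)) {
    don <- match(topology$donor_of[hyd], topology$atom_id)
    xyz <- frame$coords; box <- frame$box
    for (i in seq_along(hyd)) {
      d_at <- don[i]; h_at <- hyd[i]
      cand <- acc[acc != d_at]
      if (exclude_same_residue)
        cand <- cand[topology$residue_id[cand] != topology$residue_id[d_at]]
      if (!length(cand)) next
      da <- min_image_dist_one(xyz[d_at, ], xyz[cand, , drop = FALSE], box)
      cand <- cand[da <= d_cut]; da <- da[da <= d_cut]
      if (!length(cand)) next
      ## D-H-A angle at the hydrogen, minimum-image vectors
      hd <- min_image_diff(matrix(xyz[d_at, ], 1), matrix(xyz[h_at, ], 1), box)
      ha <- min_image_diff(xyz[cand, , drop = FALSE],
                           matrix(xyz[h_at, ], length(cand), 3, byrow = TRUE),
                           box)
      nh <- sqrt(sum(hd^2)); na_ <- sqrt(rowSums(ha^2))
      cosang <- as.numeric(ha %*% t(hd)) / (nh * na_)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      ok <- ang >= angle_cut
      if (!any(ok)) next
      out[[length(out) + 1]] <- data.frame(
        donor = topology$atom_id[d_at], hydrogen = topology$atom_id[h_at],
        acceptor = topology$atom_id[cand[ok]],
        donor_name = topology$atom_name[d_at],
        acceptor_name = topology$atom_name[cand[ok]],
        donor_residue = topology$residue_id[d_at],
        acceptor_residue = topology$residue_id[cand[ok]],
        donor_species = topology$species[d_at],
        acceptor_species = topology$species[cand[ok]],
        distance_nm = da[ok], angle_deg = ang[ok])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
               donor_name = character(), acceptor_name = character(),
               donor_residue = integer(), acceptor_residue = integer(),
               donor_species = character(), acceptor_species = character(),
               distance_nm = numeric(), angle_deg = numeric())
  if (!is.null(pair_filter) && nrow(res)) {
    keep <- if (is.function(pair_filter)) {
      pair_filter(res$donor_species, res$acceptor_species)
    } else {
      pf <- as.data.frame(pair_filter)
      paste(res$donor_species, res$acceptor_species) %in%
        paste(pf[[1]], pf[[2]])
    }
    res <- res[keep, , drop = FALSE]
  }
  class(res) <- c("hbond_records", "data.frame")
  res
}

#' Time-averaged hydrogen-bond counts over a trajectory
#'
#' Runs [detect_hbonds()] on every frame and aggregates mean counts per
#' donor-acceptor species pair and per donor hydroxyl/oxygen name (the
#' per-hydroxyl accounting used for ligand OH groups, keyed by the donor
#' atom's name).
#'
#' @param traj a `trajectory`.
#' @param topology a `topology`.
#' @param dedupe_hydrogens count at most one bond per donor-acceptor atom
#'   pair and frame even when several hydrogens of the donor satisfy the
#'   criteria.
#' @param ... passed to [detect_hbonds()].
#' @return list with `by_pair` (species pair means), `by_donor_name`
#'   (mean count per donor atom name), `per_frame` (total per frame).
#' @export
hbond_summary <- function(traj, topology, dedupe_hydrogens = FALSE, ...) {
  nf <- n_frames(traj)
  pair_tab <- list(); name_tab <- list(); totals <- numeric(nf)
  for (f in seq_len(nf)) {
    rec <- detect_hbonds(traj_frame(traj, f), topology, ...)
    if (dedupe_hydrogens && nrow(rec))
      rec <- rec[!duplicated(rec[, c("donor", "acceptor")]), , drop = FALSE]
    totals[f] <- nrow(rec)
    if (nrow(rec)) {
      pair_tab[[f]] <- table(paste(rec$donor_species, rec$acceptor_species,
                                   sep = "-"))
      name_tab[[f]] <- table(rec$donor_name)
    }
  }
  sum_tab <- function(tabs) {
    all_k <- unique(unlist(lapply(tabs, names)))
    if (!length(all_k)) return(data.frame(key = character(), mean = numeric()))
    m <- vapply(all_k, function(k)
      sum(vapply(tabs, function(t) if (k %in% names(t)) t[[k]] else 0, 0)) / nf,
      0)
    data.frame(key = all_k, mean = unname(m))
  }
  list(by_pair = sum_tab(pair_tab), by_donor_name = sum_tab(name_tab),
       per_frame = totals)
}

## ----------------------------------------------------------------------
## Contact counting

## All-pairs reference counter for one frame.
count_contacts_brute <- function(xa, xb, box, cutoff) {
  sum(min_image_dist_matrix(xa, xb, box) < cutoff)
}

## Cell-list counter: exact same strict-< convention as the brute path.
## Cells at least `cutoff` wide; neighbour cells deduplicated so small
## boxes (under 3 cells per axis) stay exact.
count_contacts_grid <- function(xa, xb, box, cutoff) {
  nc <- pmax(1L, floor(box / cutoff))
  if (any(nc < 3)) return(count_contacts_brute(xa, xb, box, cutoff))
  cell_of <- function(x) {
    ix <- pmin(nc[1] - 1L, floor(x[, 1] / box[1] * nc[1])) %% nc[1]
    iy <- pmin(nc[2] - 1L, floor(x[, 2] / box[2] * nc[2])) %% nc[2]
    iz <- pmin(nc[3] - 1L, floor(x[, 3] / box[3] * nc[3])) %% nc[3]
    cbind(ix, iy, iz)
  }
  ca <- cell_of(wrap_coords(xa, box)); cb <- cell_of(wrap_coords(xb, box))
  idb <- ca2id(cb, nc)
  b_by_cell <- split(seq_len(nrow(xb)), idb)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  total <- 0L
  ida <- ca2id(ca, nc)
  for (ac in unique(ida)) {
    a_idx <- which(ida == ac)
    cell3 <- id2ca(ac, nc)
    neigh <- sweep(offs, 2, cell3, "+")
    neigh <- sweep(neigh, 2, nc, "%%")
    nid <- unique(ca2id(neigh, nc))
    b_idx <- unlist(b_by_cell[as.character(nid)], use.names = FALSE)
    if (!length(b_idx)) next
    total <- total + count_contacts_brute(xa[a_idx, , drop = FALSE],
                                          xb[b_idx, , drop = FALSE],
                                          box, cutoff)
  }
  total
}

ca2id <- function(c3, nc) c3[, 1] + nc[1] * (c3[, 2] + nc[2] * c3[, 3])
id2ca <- function(id, nc) {
  x <- id %% nc[1]; r <- id %/% nc[1]
  c(x, r %% nc[2], r %/% nc[2])
}

#' Per-frame contact counts between two atom groups
#'
#' Counts atom pairs (a in A, b in B) with minimum-image distance strictly
#' below `cutoff`, per frame, optionally split by the subregion tag of the
#' B atoms.  Hydrogens are excluded by default (heavy-atom convention).
#' The cell-list implementation is exact and checked against the all-pairs
#' path in the test suite.
#'
#' @param traj a `trajectory`.
#' @param topology a `topology`.
#' @param group_a,group_b atom index vectors.
#' @param cutoff nm; must be below half the smallest box edge.
#' @param by_subregion split counts by `topology$subregion` of group B.
#' @param heavy_only drop hydrogens from both groups.
#' @param method `"grid"` (cell list) or `"brute"` (all pairs).
#' @return object of class `contact_series`: data.frame with `frame`,
#'   `group`, `count`; attributes `dt` (ns) and `cutoff`.
#' @export
count_contacts <- function(traj, topology, group_a, group_b, cutoff = 0.45,
                           by_subregion = FALSE, heavy_only = TRUE,
                           method = c("grid", "brute")) {
  method <- match.arg(method)
  if (heavy_only) {
    group_a <- group_a[!topology$is_hydrogen[group_a]]
    group_b <- group_b[!topology$is_hydrogen[group_b]]
  }
  if (!length(group_a) || !length(group_b))
    stop_input("empty atom group after filtering")
  if (any(cutoff > min(traj$box) / 2))
    stop_input("cutoff %.3f nm exceeds half the smallest box edge (minimum-image validity)",
               cutoff)
  counter <- if (method == "grid") count_contacts_grid else count_contacts_brute
  groups <- if (by_subregion)
    split(group_b, topology$subregion[group_b]) else list(all = group_b)
  nf <- n_frames(traj)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- traj_frame(traj, f)
    xa <- fr$coords[group_a, , drop = FALSE]
    cnt <- vapply(groups, function(gb)
      counter(xa, fr$coords[gb, , drop = FALSE], fr$box, cutoff), 0L)
    out[[f]] <- data.frame(frame = f, group = names(groups),
                           count = as.integer(cnt))
  }
  res <- do.call(rbind, out)
  dt <- if (nf > 1) traj$time[2] - traj$time[1] else NA_real_
  structure(res, dt = dt, cutoff = cutoff,
            class = c("contact_series", "data.frame"))
}

#' Per-frame minimum distance between two atom groups
#'
#' @inheritParams count_contacts
#' @return numeric vector, nm (one value per frame).
#' @export
min_distance <- function(traj, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop_input("empty atom group")
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- traj_frame(traj, f)
    min(min_image_dist_matrix(fr$coords[group_a, , drop = FALSE],
                              fr$coords[group_b, , drop = FALSE], fr$box))
  }, 0)
}

#' Cumulative strong-binding time from a contact series
#'
#' The strong binding time is the cumulative time during which the
#' per-frame contact count strictly exceeds `threshold`:
#' `dt * #\{frames: count > threshold\}`, per contact group.
#'
#' @param series a `contact_series` (or data.frame with `frame`, `group`,
#'   `count`), typically built at a tight 0.16 nm pair cutoff.
#' @param threshold count threshold (default 800).
#' @param dt frame spacing in ns; defaults to the series' `dt` attribute.
#' @return object of class `binding_time`: data.frame with `group`,
#'   `strong_binding_time_ns`, `n_frames_above`, `n_frames`; attributes
#'   `threshold` and `cutoff`.
#' @export
strong_binding_time <- function(series, threshold = 800, dt = NULL) {
  dt <- dt %||% attr(series, "dt")
  if (is.null(dt) || is.na(dt) || dt <= 0)
    stop_input("dt must be positive (give it explicitly for 1-frame series)")
  if (is.numeric(series))
    series <- data.frame(frame = seq_along(series), group = "all",
                         count = series)
  sp <- split(series$count, series$group)
  out <- data.frame(group = names(sp),
                    strong_binding_time_ns = vapply(sp, function(x)
                      sum(x > threshold) * dt, 0),
                    n_frames_above = vapply(sp, function(x)
                      sum(x > threshold), 0L),
                    n_frames = vapply(sp, length, 0L))
  rownames(out) <- NULL
  structure(out, threshold = threshold, cutoff = attr(series, "cutoff"),
            class = c("binding_time", "data.frame"))
}

## ----------------------------------------------------------------------
## Shrake-Rupley SASA with headgroup/tail attribution

#' Ligand SASA partitioned between lipid headgroups, tails and solvent
#'
#' Shrake-Rupley sphere sampling: each ligand atom's sphere (vdW radius +
#' probe) carries `n_points` deterministic quasi-uniform points; a point is
#' exposed iff it lies inside no other atom's inflated sphere.  Each
#' exposed point is attributed to the nearest non-ligand atom whose
#' inflated surface lies within `contact_tol` of the point (headgroup- or
#' tail-tagged), else to solvent.  Headgroup subregions are choline,
#' phosphate, glycerol and sterol; tails are `tails`.
#'
#' @param frame single frame (list with `coords`, `box`).
#' @param topology a `topology` with vdW radii.
#' @param ligand atom indices of the ligand (default: all atoms with
#'   subregion `"ligand"`).
#' @param probe probe radius, nm (water = 0.14).
#' @param n_points sphere sample points per atom.
#' @param contact_tol attribution tolerance: maximum distance from an
#'   exposed point to a neighbour's inflated surface (default one probe
#'   diameter, nm).
#' @return object of class `sasa_partition`: list with areas in
#'   Angstrom^2 (`total`, `headgroup`, `tails`, `solvent`), plus `probe`,
#'   `n_points`.  Components sum to the total by construction.
#' @export
sasa_partition <- function(frame, topology, ligand = NULL, probe = 0.14,
                           n_points = 960, contact_tol = 2 * probe) {
  if (is.null(ligand)) ligand <- which(topology$subregion == "ligand")
  if (!length(ligand)) stop_input("no ligand atoms")
  if (any(is.na(topology$vdw_radius_nm)))
    stop_input("missing vdW radius in topology")
  xyz <- frame$coords; box <- frame$box
  rad <- topology$vdw_radius_nm + probe
  pts <- sphere_points(n_points)
  others <- setdiff(seq_len(nrow(topology)), 0L)  # all atoms occlude
  nonlig <- setdiff(seq_len(nrow(topology)), ligand)
  headset <- nonlig[topology$subregion[nonlig] %in% HEADGROUP_SUBREGIONS]
  tailset <- nonlig[topology$subregion[nonlig] %in% "tails"]
  area <- c(headgroup = 0, tails = 0, solvent = 0)
  total <- 0
  for (a in ligand) {
    R <- rad[a]
    p <- sweep(pts * R, 2, xyz[a, ], "+")
    ## occlusion by every other atom within reach
    occluded <- rep(FALSE, n_points)
    cand <- setdiff(others, a)
    dcand <- min_image_dist_one(xyz[a, ], xyz[cand, , drop = FALSE], box)
    cand <- cand[dcand < R + rad[cand]]
    for (j in cand) {
      d <- min_image_dist_one(xyz[j, ], p, box)
      occluded <- occluded | d < rad[j]
      if (all(occluded)) break
    }
    exposed <- which(!occluded)
    a_pt <- 4 * pi * R^2 / n_points * 100  # nm^2 -> Angstrom^2
    total <- total + length(exposed) * a_pt
    if (!length(exposed)) next
    ## attribution of exposed points
    near_dist <- function(set) {
      if (!length(set)) return(matrix(Inf, length(exposed), 1))
      dset <- min_image_dist_one(xyz[a, ], xyz[set, , drop = FALSE], box)
      set <- set[dset < R + rad[set] + contact_tol + 1e-9]
      if (!length(set)) return(matrix(Inf, length(exposed), 1))
      vapply(set, function(j)
        min_image_dist_one(xyz[j, ], p[exposed, , drop = FALSE], box) - rad[j],
        numeric(length(exposed)))
    }
    dh <- near_dist(headset); dt_ <- near_dist(tailset)
    dh <- matrix(dh, nrow = length(exposed))
    dt_ <- matrix(dt_, nrow = length(exposed))
    best_h <- apply(dh, 1, min); best_t <- apply(dt_, 1, min)
    lab <- ifelse(pmin(best_h, best_t) > contact_tol, "solvent",
                  ifelse(best_h <= best_t, "headgroup", "tails"))
    tab <- table(factor(lab, c("headgroup", "tails", "solvent")))
    area <- area + as.numeric(tab) * a_pt
  }
  structure(list(total = total, headgroup = unname(area[["headgroup"]]),
                 tails = unname(area[["tails"]]),
                 solvent = unname(area[["solvent"]]),
                 probe = probe, n_points = n_points),
            class = "sasa_partition")
}

#' @export
print.sasa_partition <- function(x, ...) {
  cat(sprintf("ligand SASA: %.2f A^2 (headgroup %.2f, tails %.2f, solvent %.2f; probe %.2f nm, %d pts)\n",
              x$total, x$headgroup, x$tails, x$solvent, x$probe, x$n_points))
  invisible(x)
}
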
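## Membrane structure metrics: leaflet assignment, area per lipid,
## bilayer thickness, area compressibility modulus from box-area
## fluctuations, mass-density profiles along the membrane normal and the
## five-region depth classification.

#' Assign lipids to leaflets
#'
#' Labels each lipid `upper` or `lower` by the sign of its headgroup
#' reference atom's z relative to the midplane (mean reference z of the
#' frame).  A reference atom exactly at the midplane is assigned `upper`
#' with a warning.
#'
#' @param frame single frame (as from [traj_frame()]).
#' @param topology a `topology`.
#' @return data.frame with `residue_id`, `species`, `leaflet`; leaflet
#'   counts attached as attribute `counts`.
#' @export
assign_leaflets <- function(frame, topology) {
  lt <- lipid_reference_table(topology)
  z <- frame$coords[lt$ref_atom, 3]
  midplane <- mean(z)
  if (any(z == midplane))
    warning("reference atom exactly at the midplane; assigned to the upper leaflet")
  leaflet <- ifelse(z >= midplane, "upper", "lower")
  out <- data.frame(residue_id = lt$residue_id, species = lt$species,
                    leaflet = leaflet)
  attr(out, "counts") <- c(upper = sum(leaflet == "upper"),
                           lower = sum(leaflet == "lower"))
  attr(out, "midplane") <- midplane
  out
}

#' Area per lipid over a trajectory
#'
#' Per frame, APL = projected box area / lipids per leaflet, averaged over
#' the two leaflets; reported as mean +/- sd over frames.
#'
#' @param traj a `trajectory`.
#' @param topology a `topology`.
#' @param frames optional frame index window (default: all).
#' @return list with `apl` (nm^2), `apl_sd`, `per_frame`, `n_frames_used`.
#' @export
area_per_lipid <- function(traj, topology, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  leaf <- assign_leaflets(traj_frame(traj, frames[1]), topology)
  n_up <- attr(leaf, "counts")[["upper"]]
  n_lo <- attr(leaf, "counts")[["lower"]]
  if (n_up == 0 || n_lo == 0)
    stop_input("a leaflet has zero lipids; cannot compute APL")
  A <- box_area_series(traj)[frames]
  per_frame <- (A / n_up + A / n_lo) / 2
  list(apl = mean(per_frame), apl_sd = stats::sd(per_frame),
       per_frame = per_frame, n_frames_used = length(frames))
}

#' Bilayer thickness over a trajectory
#'
#' Per frame, the distance between the mean headgroup-reference z of the
#' upper and lower leaflets (phosphate-plane convention), averaged over
#' frames.
#'
#' @inheritParams area_per_lipid
#' @return list with `thickness` (nm), `thickness_sd`, `per_frame`,
#'   `n_frames_used`.
#' @export
bilayer_thickness <- function(traj, topology, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  leaf <- assign_leaflets(traj_frame(traj, frames[1]), topology)
  if (length(unique(leaf$leaflet)) < 2)
    stop_input("need two leaflets to measure thickness")
  lt <- lipid_reference_table(topology)
  up <- lt$ref_atom[leaf$leaflet == "upper"]
  lo <- lt$ref_atom[leaf$leaflet == "lower"]
  per_frame <- vapply(frames, function(f)
    mean(traj$coords[up, 3, f]) - mean(traj$coords[lo, 3, f]), 0)
  list(thickness = mean(per_frame), thickness_sd = stats::sd(per_frame),
       per_frame = per_frame, n_frames_used = length(frames))
}

#' Area compressibility modulus from box-area fluctuations
#'
#' `K_A = kB T <A> / var(A)` with A the projected box area.  Input areas
#' are nm^2; the result is N/m.
#'
#' @param area_series per-frame box areas, nm^2 (or a `trajectory`).
#' @param temperature K.
#' @return list with `k_a` (N/m), `mean_area`, `var_area`, `n_frames`,
#'   and a `units` note documenting the conversion.
#' @export
area_compressibility <- function(area_series, temperature) {
  if (inherits(area_series, "trajectory"))
    area_series <- box_area_series(area_series)
  if (temperature <= 0) stop_input("temperature must be positive")
  if (length(area_series) < 100)
    stop_input("need >= 100 frames for a fluctuation estimate (got %d)",
               length(area_series))
  v <- stats::var(area_series)
  if (v == 0) stop_input("degenerate area series (zero variance)")
  ## nm^2 / nm^4 -> 1/nm^2 = 1e18 1/m^2
  k_a <- BOLTZMANN_J_PER_K * temperature * mean(area_series) / v * 1e18
  list(k_a = k_a, mean_area = mean(area_series), var_area = v,
       n_frames = length(area_series),
       units = "K_A in N/m from areas in nm^2: kB*T*<A>/var(A) * 1e18")
}

#' Mass density profile along the membrane normal
#'
#' Histograms selection atom masses along z, re-centred per frame on the
#' bilayer midplane (mean headgroup-reference z), converts to kg/m^3 using
#' the bin volume `box_x * box_y * bin_width`, and averages over frames.
#'
#' @param traj a `trajectory`.
#' @param topology a `topology`.
#' @param selections named list of atom index vectors (e.g.
#'   `list(headgroup = ..., tails = ..., ligand = ...)`).
#' @param bin_width nm.
#' @return object of class `density_profile`: list with `z` (bin centres,
#'   nm from midplane), `density` (matrix bins x selections, kg/m^3),
#'   `bin_width`.
#' @export
mass_density_profile <- function(traj, topology, selections, bin_width = 0.1) {
  if (bin_width <= 0) stop_input("bin_width must be positive")
  if (!length(selections)) stop_input("no selections given")
  if (is.null(names(selections)))
    names(selections) <- paste0("sel", seq_along(selections))
  empty <- vapply(selections, function(s) length(s) == 0, TRUE)
  if (any(empty))
    stop_input("empty selection(s): %s",
               paste(names(selections)[empty], collapse = ", "))
  ref <- reference_atom_indices(topology)
  half_z <- max(traj$box[, 3]) / 2
  breaks <- seq(-half_z, half_z, by = bin_width)
  if (breaks[length(breaks)] < half_z) breaks <- c(breaks, half_z)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nf <- n_frames(traj)
  dens <- matrix(0, length(centers), length(selections),
                 dimnames = list(NULL, names(selections)))
  for (f in seq_len(nf)) {
    mid <- mean(traj$coords[ref, 3, f])
    Lz <- traj$box[f, 3]
    vol_nm3 <- traj$box[f, 1] * traj$box[f, 2] * bin_width
    for (s in seq_along(selections)) {
      idx <- selections[[s]]
      zrel <- traj$coords[idx, 3, f] - mid
      zrel <- zrel - Lz * round(zrel / Lz)  # wrap into (-Lz/2, Lz/2]
      bin <- findInterval(zrel, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
      m <- tapply(topology$mass_amu[idx], factor(bin, seq_along(centers)),
                  sum, default = 0)
      dens[, s] <- dens[, s] + as.numeric(m) * AMU_KG / (vol_nm3 * 1e-27)
    }
  }
  structure(list(z = centers, density = dens / nf, bin_width = bin_width),
            class = "density_profile")
}

#' Five-region depth classification from lipid density profiles
#'
#' Derives the four symmetric z-boundaries (nm from the midplane) that
#' split each leaflet into five depth regions: 1 bulk water, 2 low-density
#' headgroup periphery, 3 high-density headgroup/glycerol, 4 high-density
#' acyl chains, 5 low-density bilayer centre.  Boundaries, outermost first:
#' region 1|2 where headgroup density decays to `water_frac` of its
#' maximum (or crosses the water profile if one is supplied), 2|3 at the
#' outer headgroup half-maximum, 3|4 at the headgroup/tail density
#' crossover, 4|5 at the half-rise of the tail density from its central
#' trough.  Profiles are symmetrised over the two leaflets first.
#'
#' @param profile a `density_profile` containing `headgroup` and `tails`
#'   columns (and optionally `water`).
#' @param water_frac fallback threshold fraction for the 1|2 boundary when
#'   no water profile is available.
#' @param boundaries optional length-4 increasing numeric vector
#'   (nm from midplane, innermost first: b45, b34, b23, b12) to use
#'   verbatim instead of the density-derived recipe.
#' @return object of class `region_scheme`: list with `boundaries`
#'   (b45 < b34 < b23 < b12, nm) and `labels`.
#' @export
classify_regions <- function(profile, water_frac = 0.05, boundaries = NULL) {
  labels <- c("bulk water", "headgroup periphery", "headgroup/glycerol",
              "acyl chain", "bilayer centre")
  if (!is.null(boundaries)) {
    if (length(boundaries) != 4 || any(diff(boundaries) <= 0))
      stop_input("boundaries must be 4 strictly increasing values")
    return(structure(list(boundaries = boundaries, labels = labels),
                     class = "region_scheme"))
  }
  stopifnot(inherits(profile, "density_profile"))
  need <- c("headgroup", "tails")
  if (!all(need %in% colnames(profile$density)))
    stop_input("profile must contain 'headgroup' and 'tails' selections")
  z <- profile$z
  ## symmetrise: average density at +z and -z on the |z| grid
  sym <- function(v) {
    pos <- z >= 0
    zp <- z[pos]
    vneg <- stats::approx(-z, v, xout = zp, rule = 2)$y
    list(z = zp, v = (v[pos] + vneg) / 2)
  }
  hg <- sym(profile$density[, "headgroup"])
  tl <- sym(profile$density[, "tails"])
  zp <- hg$z
  if (max(hg$v) == 0 || max(tl$v) == 0)
    stop_input("non-overlapping or empty lipid profiles")
  ipk_h <- which.max(hg$v)

  ## 4|5: half-rise of tail density from the central trough
  ipk_t <- which.max(tl$v)
  trough <- tl$v[1]
  half_t <- trough + 0.5 * (max(tl$v) - trough)
  i45 <- which(tl$v[seq_len(ipk_t)] >= half_t)[1]
  b45 <- zp[max(i45, 2) - 1] + diff(zp[c(max(i45, 2) - 1, max(i45, 2))]) / 2

  ## 3|4: headgroup/tail crossover between the tail peak and headgroup peak
  seg <- seq(min(ipk_t, ipk_h), max(ipk_t, ipk_h))
  cross <- seg[which(hg$v[seg] >= tl$v[seg])[1]]
  if (is.na(cross)) cross <- round(mean(c(ipk_t, ipk_h)))
  b34 <- zp[cross]

  ## 2|3: outer headgroup half-maximum
  outer <- seq(ipk_h, length(zp))
  i23 <- outer[which(hg$v[outer] <= 0.5 * max(hg$v))[1]]
  if (is.na(i23)) i23 <- length(zp)
  b23 <- zp[i23]

  ## 1|2: water crossover, or decay to water_frac of headgroup max
  if ("water" %in% colnames(profile$density)) {
    wt <- sym(profile$density[, "water"])
    i12 <- outer[which(wt$v[outer] >= hg$v[outer])[1]]
  } else {
    i12 <- outer[which(hg$v[outer] <= water_frac * max(hg$v))[1]]
  }
  if (is.na(i12)) i12 <- length(zp)
  b12 <- zp[i12]

  b <- c(b45, b34, b23, b12)
  if (any(diff(b) <= 0))
    stop_input("derived region boundaries are not strictly ordered (%s); supply `boundaries` explicitly",
               paste(sprintf("%.2f", b), collapse = ", "))
  structure(list(boundaries = b, labels = labels), class = "region_scheme")
}

#' Region index of depths
#'
#' @param scheme a `region_scheme`.
#' @param z depths (nm from midplane; sign ignored).
#' @return integer region indices 1-5 (1 = bulk water, 5 = bilayer centre).
#' @export
region_of <- function(scheme, z) {
  5L - findInterval(abs(z), scheme$boundaries)
}

#' Locate a ligand within the membrane depth regions
#'
#' @param ligand_profile a `density_profile` with a single column (or the
#'   column named by `column`) for the ligand.
#' @param scheme a `region_scheme`.
#' @param column column of the profile to use.
#' @return list with `occupancy` (mass fraction per region, named 1-5),
#'   `peak_region`, `peak_z`.
#' @export
locate_ligand <- function(ligand_profile, scheme, column = 1) {
  stopifnot(inherits(ligand_profile, "density_profile"))
  v <- ligand_profile$density[, column]
  if (all(v == 0)) stop_input("ligand profile is identically zero")
  reg <- region_of(scheme, ligand_profile$z)
  occ <- tapply(v, factor(reg, 1:5), sum, default = 0)
  occ <- as.numeric(occ) / sum(v)
  names(occ) <- as.character(1:5)
  ipk <- which.max(v)
  list(occupancy = occ, peak_region = reg[ipk], peak_z = ligand_profile$z[ipk])
}
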
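## Synthetic planar-bilayer generator.  Produces coarse pseudo-lipid
## configurations, free-Brownian lateral dynamics with box-area
## fluctuations, two-state binding traces, planted hydrogen-bond
## geometries and parametric Langmuir isotherms -- all with known ground
## truth so every downstream estimator can be validated without MD.

BOLTZMANN_J_PER_K <- 1.380649e-23
AMU_KG <- 1.66053906660e-27
## 1 nm^2/ns = 1e-5 cm^2/s
NM2_PER_NS_TO_CM2_PER_S <- 1e-5

## Coarse pseudo-lipid templates: 6 beads for phospholipid-like species,
## 4 for sterols.  z offsets are relative to the headgroup reference plane,
## positive pointing OUT of the membrane (flipped for the lower leaflet).
## Masses are lumped per subregion; radii are bead-scale, not atomistic.
lipid_template <- function(kind) {
  switch(kind,
    popc = data.frame(  # phospho-oxygens acceptor-only, no donors
      atom_name = c("CHO", "P", "GLY", "T1", "T2", "T3"),
      subregion = c("choline", "phosphate", "glycerol", rep("tails", 3)),
      element = c("N", "P", "C", "C", "C", "C"),
      mass_amu = c(87, 123, 146, 140, 140, 124),
      vdw_radius_nm = c(0.28, 0.30, 0.28, 0.32, 0.32, 0.32),
      is_donor = FALSE,
      is_hydrogen = FALSE,
      is_acceptor = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
      z_off = c(0.35, 0.00, -0.40, -0.90, -1.30, -1.70)),
    psm = data.frame(   # sphingosine amide: donor + acceptor, carries an H
      atom_name = c("CHO", "P", "AMD", "HN", "T1", "T2", "T3"),
      subregion = c("choline", "phosphate", "glycerol", "glycerol",
                    rep("tails", 3)),
      element = c("N", "P", "N", "H", "C", "C", "C"),
      mass_amu = c(87, 123, 130, 1, 150, 150, 124),
      vdw_radius_nm = c(0.28, 0.30, 0.28, 0.11, 0.32, 0.32, 0.32),
      is_donor = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      is_hydrogen = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
      is_acceptor = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
      z_off = c(0.35, 0.00, -0.40, -0.31, -0.90, -1.30, -1.70)),
    chol = data.frame(  # sterol hydroxyl: donor + acceptor
      atom_name = c("O3", "HO3", "R1", "R2", "R3"),
      subregion = c("sterol", "sterol", rep("tails", 3)),
      element = c("O", "H", "C", "C", "C"),
      mass_amu = c(17, 1, 120, 140, 109),
      vdw_radius_nm = c(0.25, 0.11, 0.34, 0.34, 0.34),
      is_donor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      is_hydrogen = c(FALSE, TRUE, FALSE, FALSE, FALSE),
      is_acceptor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      z_off = c(-0.10, -0.01, -0.60, -1.05, -1.50)),
    stop_input("no pseudo-lipid template for kind '%s'", kind))
}

## Map species name -> template kind.  PSM-like names carry donors,
## POPC-like are acceptor-only, CHOL-like are sterols.
species_kind <- function(species) {
  s <- toupper(species)
  if (grepl("CHOL|CHL|STEROL", s)) return("chol")
  if (grepl("SM$|^PSM|^SSM|^NSM", s)) return("psm")
  "popc"
}

#' Specification of a synthetic planar bilayer
#'
#' @param composition_per_leaflet named integer vector of lipid counts per
#'   leaflet, e.g. `c(POPC = 40)` or `c(PSM = 40, CHOL = 80)`.
#' @param apl_target target area per lipid, nm^2.
#' @param thickness_target headgroup-reference-plane separation, nm.
#' @param box_z box height, nm.
#' @param seed integer seed (generators never touch global random state
#'   beyond an explicit `set.seed` here).
#' @return object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(composition_per_leaflet, apl_target = 0.651,
                         thickness_target = 3.90, box_z = 9, seed = 1) {
  if (is.null(names(composition_per_leaflet)) ||
      any(!nzchar(names(composition_per_leaflet))))
    stop_input("composition_per_leaflet must be a named count vector")
  if (any(composition_per_leaflet <= 0) ||
      any(composition_per_leaflet != round(composition_per_leaflet)))
    stop_input("lipid counts must be positive integers")
  if (apl_target <= 0) stop_input("apl_target must be positive")
  if (thickness_target <= 0) stop_input("thickness_target must be positive")
  if (thickness_target >= box_z)
    stop_input("thickness_target (%.2f nm) must be smaller than box_z (%.2f nm)",
               thickness_target, box_z)
  structure(list(composition_per_leaflet = composition_per_leaflet,
                 apl_target = apl_target, thickness_target = thickness_target,
                 box_z = box_z, seed = as.integer(seed)),
            class = "bilayer_spec")
}

#' Build a single-frame coarse bilayer configuration
#'
#' Places two leaflets of coarse pseudo-lipids on jittered square lattices.
#' Box x,y satisfy `x*y = lipids_per_leaflet * apl_target`; the two
#' headgroup reference planes sit at `box_z/2 +/- thickness_target/2`.
#' Species are interleaved randomly across lattice sites and both leaflets
#' carry identical composition.
#'
#' @param spec a [bilayer_spec()].
#' @return list with elements `trajectory` (1 frame) and `topology`.
#' @export
build_bilayer_config <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  set.seed(spec$seed)
  counts <- spec$composition_per_leaflet
  n_leaf <- sum(counts)
  L <- sqrt(n_leaf * spec$apl_target)
  box <- c(L, L, spec$box_z)
  ngrid <- ceiling(sqrt(n_leaf))
  spacing <- L / ngrid
  site <- expand.grid(ix = seq_len(ngrid) - 1, iy = seq_len(ngrid) - 1)
  z_mid <- spec$box_z / 2
  z_plane <- c(upper = z_mid + spec$thickness_target / 2,
               lower = z_mid - spec$thickness_target / 2)

  rows <- list(); coords <- list(); atom_id <- 0L; res_id <- 0L
  for (leaf in c("upper", "lower")) {
    species_seq <- sample(rep(names(counts), counts))
    use <- sample(nrow(site), n_leaf)
    sgn <- if (leaf == "upper") 1 else -1
    for (j in seq_len(n_leaf)) {
      res_id <- res_id + 1L
      sp <- species_seq[j]
      tpl <- lipid_template(species_kind(sp))
      xy <- c(site$ix[use[j]], site$iy[use[j]]) * spacing + spacing / 2 +
        stats::runif(2, -0.1, 0.1) * spacing
      n_at <- nrow(tpl)
      jit <- matrix(stats::rnorm(n_at * 2, 0, 0.02), n_at, 2)
      xyz <- cbind(xy[1] + jit[, 1], xy[2] + jit[, 2],
                   z_plane[leaf] + sgn * tpl$z_off)
      ids <- atom_id + seq_len(n_at)
      donor_of <- rep(NA_integer_, n_at)
      if (any(tpl$is_hydrogen)) {
        ## each hydrogen bonds to the nearest preceding donor bead
        don_rows <- which(tpl$is_donor)
        for (h in which(tpl$is_hydrogen))
          donor_of[h] <- ids[don_rows[which.min(abs(don_rows - h))]]
      }
      rows[[res_id]] <- data.frame(
        atom_id = ids, atom_name = tpl$atom_name, residue_id = res_id,
        species = sp, subregion = tpl$subregion, element = tpl$element,
        mass_amu = tpl$mass_amu, vdw_radius_nm = tpl$vdw_radius_nm,
        is_donor = tpl$is_donor, is_hydrogen = tpl$is_hydrogen,
        is_acceptor = tpl$is_acceptor, donor_of = donor_of,
        leaflet_hint = leaf)
      coords[[res_id]] <- xyz
      atom_id <- atom_id + n_at
    }
  }
  top <- as_topology(do.call(rbind, rows))
  xyz <- wrap_coords(do.call(rbind, coords), box)
  ## sanity: headgroup reference atoms must not overlap within a leaflet
  ref <- reference_atom_indices(top)
  for (leaf in c("upper", "lower")) {
    ri <- ref[top$leaflet_hint[ref] == leaf]
    if (length(ri) > 1) {
      dm <- min_image_dist_matrix(xyz[ri, , drop = FALSE],
                                  xyz[ri, , drop = FALSE], box)
      diag(dm) <- Inf
      if (min(dm) < 0.05)
        stop_input("generated configuration has overlapping lipids (min ref-ref distance %.3f nm)",
                   min(dm))
    }
  }
  list(trajectory = trajectory(xyz, box, time = 0), topology = top)
}

#' Specification of synthetic lateral dynamics
#'
#' @param d_map named numeric vector: lateral diffusion coefficient per
#'   species, cm^2/s.
#' @param n_frames number of frames.
#' @param dt frame spacing, ns.
#' @param area_mean,area_var mean (nm^2) and variance (nm^4) of the
#'   stationary Gaussian box-area series; `NULL` keeps the box fixed.
#'   Alternatively give `k_a` (N/m) and `temperature` (K) and the variance
#'   is set so the fluctuation estimator recovers `k_a`.
#' @param k_a,temperature optional target area compressibility modulus and
#'   temperature used to derive `area_var` when `area_var` is `NULL`.
#' @param z_jitter_sd sd of the per-frame z jitter around the leaflet
#'   plane, nm (0 disables).
#' @param seed integer seed.
#' @return object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(d_map, n_frames, dt = 0.1, area_mean = NULL,
                          area_var = NULL, k_a = NULL, temperature = 310,
                          z_jitter_sd = 0.02, seed = 1) {
  if (any(d_map < 0)) stop_input("diffusion coefficients must be >= 0")
  if (dt <= 0) stop_input("dt must be positive")
  if (!is.null(area_var) && area_var < 0)
    stop_input("area variance must be >= 0")
  if (!is.null(k_a) && is.null(area_var)) {
    if (is.null(area_mean)) stop_input("k_a target needs area_mean")
    ## K_A = kB T <A> / var(A); solve for var(A), in nm^4
    area_var <- BOLTZMANN_J_PER_K * temperature * area_mean / k_a * 1e18
  }
  structure(list(d_map = d_map, n_frames = as.integer(n_frames), dt = dt,
                 area_mean = area_mean, area_var = area_var,
                 temperature = temperature, z_jitter_sd = z_jitter_sd,
                 seed = as.integer(seed)),
            class = "dynamics_spec")
}

#' Simulate free Brownian lateral diffusion of a bilayer configuration
#'
#' Each lipid performs an independent 2-D random walk with per-axis step
#' variance `2 D dt` (D converted from cm^2/s to nm^2/ns); all beads of a
#' lipid move rigidly with it.  z stays at the leaflet plane plus optional
#' jitter.  If an area series is requested, box x,y follow
#' `sqrt(A_t)` and all lateral coordinates rescale affinely with the box.
#' Coordinates are wrapped into the periodic box.
#'
#' @param config output of [build_bilayer_config()].
#' @param spec a [dynamics_spec()].
#' @param atoms `"all"` to propagate every bead, `"reference"` to emit only
#'   the per-lipid headgroup reference atoms (identical for MSD analysis,
#'   much lighter for long runs).
#' @return a `trajectory`; the subset topology used is attached as
#'   attribute `topology`, the per-species input D as attribute `true_d`.
#' @export
simulate_lateral_diffusion <- function(config, spec, atoms = c("all", "reference")) {
  stopifnot(inherits(spec, "dynamics_spec"))
  atoms <- match.arg(atoms)
  set.seed(spec$seed)
  top <- config$topology
  frame0 <- traj_frame(config$trajectory, 1)
  box0 <- frame0$box
  lt <- lipid_reference_table(top)
  if (atoms == "reference") {
    keep <- lt$ref_atom
  } else {
    keep <- seq_len(nrow(top))
  }
  top_out <- as_topology(top[keep, , drop = FALSE])
  n_mol <- nrow(lt)
  nf <- spec$n_frames
  d_nm <- spec$d_map[lt$species] * 1 / NM2_PER_NS_TO_CM2_PER_S  # nm^2/ns
  if (anyNA(d_nm))
    stop_input("d_map is missing species: %s",
               paste(setdiff(lt$species, names(spec$d_map)), collapse = ", "))
  step_sd <- sqrt(2 * d_nm * spec$dt)

  ## cumulative per-lipid lateral displacements, frames x molecules
  dx <- matrix(apply(matrix(stats::rnorm(nf * n_mol, 0, rep(step_sd, each = nf)),
                            nf, n_mol), 2, cumsum), nf, n_mol)
  dy <- matrix(apply(matrix(stats::rnorm(nf * n_mol, 0, rep(step_sd, each = nf)),
                            nf, n_mol), 2, cumsum), nf, n_mol)
  dx <- rbind(0, dx[-nf, , drop = FALSE])
  dy <- rbind(0, dy[-nf, , drop = FALSE])

  ## box-area series
  if (!is.null(spec$area_mean)) {
    A <- stats::rnorm(nf, spec$area_mean, sqrt(spec$area_var %||% 0))
    if (any(A <= 0)) stop_input("area series hit non-positive values; check spec")
  } else {
    A <- rep(box0[1] * box0[2], nf)
  }
  Lx <- sqrt(A * box0[1] / box0[2]); Ly <- A / Lx
  scale_x <- Lx / box0[1]; scale_y <- Ly / box0[2]

  mol_of_atom <- match(top$residue_id[keep], lt$residue_id)
  x0 <- frame0$coords[keep, 1]; y0 <- frame0$coords[keep, 2]
  z0 <- frame0$coords[keep, 3]
  n_at <- length(keep)
  coords <- array(NA_real_, c(n_at, 3, nf))
  zj <- if (spec$z_jitter_sd > 0)
    matrix(stats::rnorm(n_at * nf, 0, spec$z_jitter_sd), n_at, nf)
  else matrix(0, n_at, nf)
  for (f in seq_len(nf)) {
    xf <- (x0 + dx[f, mol_of_atom]) * scale_x[f]
    yf <- (y0 + dy[f, mol_of_atom]) * scale_y[f]
    bf <- c(Lx[f], Ly[f], box0[3])
    coords[, , f] <- wrap_coords(cbind(xf, yf, z0 + zj[, f]), bf)
  }
  tr <- trajectory(coords, cbind(Lx, Ly, box0[3]),
                   time = (seq_len(nf) - 1) * spec$dt)
  attr(tr, "topology") <- top_out
  attr(tr, "true_d") <- spec$d_map
  tr
}

#' Specification of a two-state binding trace
#'
#' @param k_on,k_off transition rates, 1/ns.
#' @param contact_level_bound,contact_level_unbound mean per-frame contact
#'   counts in the bound / unbound state (`bound > unbound`).
#' @param dispersion sd of per-frame Gaussian count noise.
#' @param n_frames,dt trace length and frame spacing (ns).
#' @param start initial state.
#' @param seed integer seed.
#' @export
binding_kinetics_spec <- function(k_on, k_off, contact_level_bound = 1000,
                                  contact_level_unbound = 10, dispersion = 0,
                                  n_frames = 1000, dt = 0.1,
                                  start = c("bound", "unbound"), seed = 1) {
  if (k_on < 0 || k_off < 0) stop_input("rates must be >= 0")
  if (contact_level_bound < 0 || contact_level_unbound < 0)
    stop_input("contact levels must be >= 0")
  if (contact_level_bound <= contact_level_unbound)
    stop_input("contact_level_bound must exceed contact_level_unbound")
  if (dispersion < 0) stop_input("dispersion must be >= 0")
  if (dt <= 0) stop_input("dt must be positive")
  structure(list(k_on = k_on, k_off = k_off,
                 contact_level_bound = contact_level_bound,
                 contact_level_unbound = contact_level_unbound,
                 dispersion = dispersion, n_frames = as.integer(n_frames),
                 dt = dt, start = match.arg(start), seed = as.integer(seed)),
            class = "binding_kinetics_spec")
}

#' Simulate a two-state (bound/unbound) contact trace
#'
#' Discrete-time Markov chain with per-frame transition probabilities
#' `1 - exp(-k dt)`; per-frame contact counts are
#' `round(level_state + noise)`, floored at 0.  The exact cumulative bound
#' time is returned alongside the series as ground truth.
#'
#' @param spec a [binding_kinetics_spec()].
#' @return list with `counts` (integer per frame), `states`
#'   (`"bound"`/`"unbound"`), `dt`, and `bound_time_true` (ns).
#' @export
simulate_binding_trace <- function(spec) {
  stopifnot(inherits(spec, "binding_kinetics_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  p_on <- 1 - exp(-spec$k_on * spec$dt)
  p_off <- 1 - exp(-spec$k_off * spec$dt)
  u <- stats::runif(nf)
  state <- logical(nf)  # TRUE = bound
  state[1] <- spec$start == "bound"
  for (f in seq_len(nf)[-1])
    state[f] <- if (state[f - 1]) u[f] >= p_off else u[f] < p_on
  level <- ifelse(state, spec$contact_level_bound, spec$contact_level_unbound)
  noise <- if (spec$dispersion > 0)
    stats::rnorm(nf, 0, spec$dispersion) else 0
  counts <- pmax(0L, as.integer(round(level + noise)))
  list(counts = counts,
       states = ifelse(state, "bound", "unbound"),
       dt = spec$dt,
       bound_time_true = sum(state) * spec$dt)
}

#' Plant donor-hydrogen-acceptor geometries with known truth labels
#'
#' Places isolated D-H-A triplets on a sparse grid (no cross-triplet
#' interference) with donor-acceptor distance and D-H-A angle drawn either
#' inside or deliberately outside the acceptance box
#' (`d <= 0.30 nm`, `angle >= 150` degrees).  The truth list records which
#' triplets qualify, making the construction an exact oracle for
#' [detect_hbonds()].
#'
#' @param n_true number of qualifying triplets.
#' @param n_near_miss_distance triplets failing only the distance cut
#'   (d in 0.305-0.40 nm).
#' @param n_near_miss_angle triplets failing only the angle cut
#'   (angle in 100-145 degrees).
#' @param seed integer seed.
#' @param d_cut,angle_cut the acceptance box the truth labels refer to
#'   (nm, degrees).
#' @return list with `frame` (list: coords, box), `topology`, and `truth`
#'   data.frame (donor/hydrogen/acceptor atom_ids, distance, angle,
#'   `is_bond`).
#' @export
plant_hbond_geometries <- function(n_true, n_near_miss_distance = 0,
                                   n_near_miss_angle = 0, seed = 1,
                                   d_cut = 0.30, angle_cut = 150) {
  stopifnot(n_true >= 0, n_near_miss_distance >= 0, n_near_miss_angle >= 0)
  set.seed(seed)
  n <- n_true + n_near_miss_distance + n_near_miss_angle
  if (n == 0) stop_input("need at least one triplet")
  kind <- sample(rep(c("true", "miss_d", "miss_a"),
                     c(n_true, n_near_miss_distance, n_near_miss_angle)))
  ngrid <- ceiling(n^(1 / 3))
  spacing <- 2.0  # nm; far beyond any cutoff
  box <- rep(ngrid * spacing, 3)
  grid <- as.matrix(expand.grid(seq_len(ngrid), seq_len(ngrid),
                                seq_len(ngrid)))[seq_len(n), , drop = FALSE]
  centers <- (grid - 0.5) * spacing

  rows <- list(); coords <- list(); truth <- list()
  for (i in seq_len(n)) {
    d <- switch(kind[i],
                true = stats::runif(1, 0.25, 0.295),
                miss_d = stats::runif(1, 0.305, 0.40),
                miss_a = stats::runif(1, 0.25, 0.295))
    theta <- switch(kind[i],
                    true = stats::runif(1, 152, 178),
                    miss_d = stats::runif(1, 152, 178),
                    miss_a = stats::runif(1, 100, 145)) * pi / 180
    ## random D->A direction
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    D <- centers[i, ]
    A <- D + d * u
    ## triangle D-H-A with |DH| = 0.1 nm and angle theta at H
    dh <- 0.1
    ang_A <- asin(pmin(1, dh * sin(theta) / d))
    ang_D <- pi - theta - ang_A
    ## rotate u by ang_D about a random axis perpendicular to u
    p <- stats::rnorm(3); p <- p - sum(p * u) * u; p <- p / sqrt(sum(p^2))
    dir_DH <- cos(ang_D) * u + sin(ang_D) * p
    H <- D + dh * dir_DH
    ids <- (i - 1) * 3 + 1:3
    rows[[i]] <- data.frame(
      atom_id = ids, atom_name = c("OD", "HD", "OA"),
      residue_id = c(i * 2 - 1, i * 2 - 1, i * 2),
      species = c("DON", "DON", "ACC"),
      subregion = "other", element = c("O", "H", "O"),
      mass_amu = c(16, 1, 16), vdw_radius_nm = c(0.25, 0.11, 0.25),
      is_donor = c(TRUE, FALSE, FALSE), is_hydrogen = c(FALSE, TRUE, FALSE),
      is_acceptor = c(FALSE, FALSE, TRUE),
      donor_of = c(NA, ids[1], NA), leaflet_hint = NA)
    coords[[i]] <- rbind(D, H, A)
    truth[[i]] <- data.frame(donor = ids[1], hydrogen = ids[2],
                             acceptor = ids[3], distance_nm = d,
                             angle_deg = theta * 180 / pi,
                             is_bond = d <= d_cut && theta * 180 / pi >= angle_cut)
  }
  list(frame = list(coords = do.call(rbind, coords), box = box, time = 0),
       topology = as_topology(do.call(rbind, rows)),
       truth = do.call(rbind, truth))
}

#' Specification of a parametric Langmuir isotherm
#'
#' @param limiting_area zero-pressure extrapolated area of the condensed
#'   branch, Angstrom^2 per molecule.
#' @param condensed_slope condensed-branch slope, mN/m per Angstrom^2.
#' @param collapse_pressure plateau onset, mN/m.
#' @param mole_fraction additive mole fraction of the composition.
#' @param mixing_slope lateral area shift per unit mole fraction,
#'   Angstrom^2 (negative = condensing, positive = expanding).
#' @param noise_sd additive Gaussian pressure noise, mN/m.
#' @param area_range,area_step sampled area grid (Angstrom^2).
#' @param seed integer seed.
#' @export
isotherm_spec <- function(limiting_area = 84.8, condensed_slope = 1.2,
                          collapse_pressure = 40.6, mole_fraction = 0,
                          mixing_slope = 0, noise_sd = 0,
                          area_range = c(30, 120), area_step = 0.25,
                          seed = 1) {
  if (limiting_area <= 0) stop_input("limiting_area must be positive")
  if (collapse_pressure <= 0) stop_input("collapse_pressure must be positive")
  if (condensed_slope <= 0) stop_input("condensed_slope must be positive")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(limiting_area = limiting_area,
                 condensed_slope = condensed_slope,
                 collapse_pressure = collapse_pressure,
                 mole_fraction = mole_fraction, mixing_slope = mixing_slope,
                 noise_sd = noise_sd, area_range = area_range,
                 area_step = area_step, seed = as.integer(seed)),
            class = "isotherm_spec")
}

#' Simulate a surface-pressure--area isotherm
#'
#' Piecewise curve over a descending area grid: zero-pressure gas phase at
#' large areas, a linear condensed branch
#' `pi = slope * (A0 - A)` below the (mole-fraction-shifted) onset area
#' `A0 = limiting_area + mixing_slope * mole_fraction`, and a flat plateau
#' once `pi` reaches the collapse pressure.  Gaussian pressure noise is
#' added and clipped at 0.
#'
#' @param spec an [isotherm_spec()].
#' @param replicate replicate id recorded on the curve.
#' @return an `isotherm` object (see [as_isotherm()]).
#' @export
simulate_isotherm <- function(spec, replicate = 1) {
  stopifnot(inherits(spec, "isotherm_spec"))
  set.seed(spec$seed)
  area <- seq(spec$area_range[2], spec$area_range[1], by = -spec$area_step)
  a0 <- spec$limiting_area + spec$mixing_slope * spec$mole_fraction
  pi_core <- pmax(0, spec$condensed_slope * (a0 - area))
  pi_core <- pmin(pi_core, spec$collapse_pressure)
  pi_obs <- pi_core
  if (spec$noise_sd > 0)
    pi_obs <- pmax(0, pi_core + stats::rnorm(length(area), 0, spec$noise_sd))
  as_isotherm(data.frame(area_A2 = area, pi_mN_m = pi_obs),
              mole_fraction = spec$mole_fraction, replicate = replicate)
}
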
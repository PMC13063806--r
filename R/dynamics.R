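## Lateral dynamics: periodic-boundary unwrapping, mean-square
## displacement with strided time origins, and lateral diffusion
## coefficients from an ordinary least-squares fit of MSD(tau) = 4 D tau
## over a configurable lag window (default 10-200 ns).

#' Unwrap lateral (x,y) tracks under periodic boundaries
#'
#' Accumulates nearest-image frame-to-frame displacements of the selected
#' atoms into continuous x,y tracks.  Optionally removes per-leaflet
#' centre-of-mass drift (on by default).  Valid only while per-frame
#' displacements stay below half a box edge; larger jumps raise an error
#' advising denser sampling.
#'
#' @param traj a `trajectory`.
#' @param topology a `topology` matching the trajectory's atoms.
#' @param selection atom indices to track (default: per-lipid headgroup
#'   reference atoms).
#' @param remove_com_drift subtract the per-frame mean displacement of each
#'   leaflet's selected atoms.
#' @return object of class `lateral_tracks`: list with `x`, `y`
#'   (frames x molecules matrices, nm), `time` (ns), `species`,
#'   `leaflet`.
#' @export
unwrap_lateral <- function(traj, topology, selection = NULL,
                           remove_com_drift = TRUE) {
  if (is.null(selection)) {
    lt <- lipid_reference_table(topology)
    selection <- lt$ref_atom
    species <- lt$species
  } else {
    species <- topology$species[selection]
  }
  if (!length(selection)) stop_input("empty selection")
  nf <- n_frames(traj)
  leaf <- assign_leaflets(traj_frame(traj, 1), topology)
  leaflet <- leaf$leaflet[match(topology$residue_id[selection],
                                leaf$residue_id)]
  X <- t(matrix(traj$coords[selection, 1, ], nrow = length(selection)))
  Y <- t(matrix(traj$coords[selection, 2, ], nrow = length(selection)))
  if (nf == 1) return(structure(list(x = X, y = Y, time = traj$time,
                                     species = species, leaflet = leaflet),
                                class = "lateral_tracks"))
  unwrap_axis <- function(M, L) {
    d <- diff(M)
    shift <- L[-1] * round(d / L[-1])
    if (any(abs(d - shift) >= L[-1] / 2 - 1e-9))
      stop_input("frame-to-frame displacement >= half box; sample frames more densely")
    apply(rbind(M[1, , drop = FALSE], d - shift), 2, cumsum)
  }
  Xu <- unwrap_axis(X, traj$box[, 1])
  Yu <- unwrap_axis(Y, traj$box[, 2])
  if (remove_com_drift) {
    for (lf in unique(leaflet)) {
      cols <- which(leaflet == lf)
      dx <- rowMeans(Xu[, cols, drop = FALSE])
      dy <- rowMeans(Yu[, cols, drop = FALSE])
      Xu[, cols] <- Xu[, cols] - (dx - dx[1])
      Yu[, cols] <- Yu[, cols] - (dy - dy[1])
    }
  }
  structure(list(x = Xu, y = Yu, time = traj$time, species = species,
                 leaflet = leaflet),
            class = "lateral_tracks")
}

## Re-wrap unwrapped tracks into the box (round-trip check helper).
wrap_tracks <- function(tracks, box) {
  list(x = tracks$x - box[1] * floor(tracks$x / box[1]),
       y = tracks$y - box[2] * floor(tracks$y / box[2]))
}

#' Mean-square lateral displacement
#'
#' `msd(tau)` averaged over molecules and over time origins taken every
#' `origin_stride` frames.
#'
#' @param tracks a `lateral_tracks` object.
#' @param max_lag largest lag in frames (default: half the track length).
#' @param origin_stride spacing of time origins in frames.
#' @param lags integer lag vector in frames (overrides `max_lag`); use a
#'   coarse grid to keep long trajectories cheap.
#' @return object of class `msd_curve`: list with `tau` (ns), `msd`
#'   (nm^2), `n_origin_pairs`, `per_molecule` (lags x molecules matrix),
#'   `species`.
#' @export
msd <- function(tracks, max_lag = NULL, origin_stride = 1, lags = NULL) {
  stopifnot(inherits(tracks, "lateral_tracks"))
  nf <- nrow(tracks$x)
  if (!ncol(tracks$x)) stop_input("empty selection")
  if (is.null(lags)) {
    max_lag <- max_lag %||% floor(nf / 2)
    if (max_lag >= nf) stop_input("max_lag must be below the track length")
    lags <- seq_len(max_lag)
  }
  lags <- sort(unique(as.integer(lags)))
  if (max(lags) >= nf) stop_input("requested lag beyond track length")
  dt <- tracks$time[2] - tracks$time[1]
  n_mol <- ncol(tracks$x)
  per_mol <- matrix(NA_real_, length(lags), n_mol)
  n_pairs <- integer(length(lags))
  for (i in seq_along(lags)) {
    lag <- lags[i]
    org <- seq(1, nf - lag, by = origin_stride)
    dx <- tracks$x[org + lag, , drop = FALSE] - tracks$x[org, , drop = FALSE]
    dy <- tracks$y[org + lag, , drop = FALSE] - tracks$y[org, , drop = FALSE]
    per_mol[i, ] <- colMeans(dx * dx + dy * dy)
    n_pairs[i] <- length(org)
  }
  structure(list(tau = c(0, lags * dt), msd = c(0, rowMeans(per_mol)),
                 n_origin_pairs = c(nf, n_pairs),
                 per_molecule = per_mol, lags = lags, dt = dt,
                 species = tracks$species),
            class = "msd_curve")
}

#' Fit lateral diffusion coefficients from an MSD curve
#'
#' OLS of `msd` on `tau` restricted to the lag window; the 2-D Einstein
#' relation gives `D_xy = slope / 4`, converted from nm^2/ns to cm^2/s
#' (factor 1e-5).  Per-molecule fits over the same window give the
#' species-level mean +/- sd.  A warning is raised when the ensemble fit
#' r^2 falls below `r2_warn` (non-linear MSD, e.g. too-short sampling).
#'
#' @param curve an `msd_curve`.
#' @param window lag window `c(tau_min, tau_max)` in ns (default 10-200).
#' @param r2_warn r^2 threshold below which a warning is emitted.
#' @return object of class `diffusion_fit`: list with `d_xy` (cm^2/s,
#'   ensemble), `intercept`, `r2`, `window`, `per_molecule` (cm^2/s),
#'   `by_species` (data.frame species, d_mean, d_sd, n).
#' @export
fit_diffusion <- function(curve, window = c(10, 200), r2_warn = 0.98) {
  stopifnot(inherits(curve, "msd_curve"))
  tau <- curve$lags * curve$dt
  sel <- which(tau >= window[1] & tau <= window[2])
  if (length(sel) < 2)
    stop_input("need >= 2 MSD points in the fit window [%g, %g] ns; available lags span [%g, %g] ns",
               window[1], window[2], min(tau), max(tau))
  x <- tau[sel]
  y <- curve$msd[-1][sel]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- if (stats::var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else 1
  if (is.finite(r2) && r2 < r2_warn)
    warning(sprintf("MSD fit r^2 = %.3f below %.2f: MSD may not be linear in this window",
                    r2, r2_warn))
  d_ens <- slope / 4 * NM2_PER_NS_TO_CM2_PER_S
  ## per-molecule fits, same window; negative slopes retained
  X <- cbind(1, x)
  per_mol <- apply(curve$per_molecule[sel, , drop = FALSE], 2, function(yy)
    stats::lm.fit(X, yy)$coefficients[2] / 4 * NM2_PER_NS_TO_CM2_PER_S)
  by_species <- do.call(rbind, lapply(split(seq_along(per_mol), curve$species),
    function(ix) data.frame(d_mean = mean(per_mol[ix]),
                            d_sd = stats::sd(per_mol[ix]), n = length(ix))))
  by_species <- cbind(species = rownames(by_species), by_species)
  rownames(by_species) <- NULL
  structure(list(d_xy = unname(d_ens), intercept = unname(fit$coefficients[1]),
                 r2 = r2, window = window, per_molecule = per_mol,
                 by_species = by_species),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("lateral diffusion fit: D_xy = %.3g cm^2/s (r^2 = %.4f, window %g-%g ns)\n",
              x$d_xy, x$r2, x$window[1], x$window[2]))
  print(x$by_species)
  invisible(x)
}
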
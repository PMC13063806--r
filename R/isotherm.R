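## Langmuir pi-A isotherm analysis: limiting molecular area by
## condensed-branch extrapolation, collapse-point detection, the in-plane
## compressibility modulus Cs^-1(pi), and the mean-area-vs-mole-fraction
## mixing slopes used as a condensation/expansion indicator.

#' Construct an isotherm object
#'
#' @param df data.frame with columns `area_A2` (Angstrom^2 per molecule)
#'   and `pi_mN_m` (mN/m), ordered as a compression sweep (areas strictly
#'   monotone).
#' @param mole_fraction additive mole fraction of the composition.
#' @param replicate replicate id.
#' @return object of class `isotherm` (a data.frame with attributes).
#' @export
as_isotherm <- function(df, mole_fraction = 0, replicate = 1) {
  if (!all(c("area_A2", "pi_mN_m") %in% names(df)))
    stop_input("isotherm needs columns area_A2 and pi_mN_m")
  d <- diff(df$area_A2)
  if (!(all(d > 0) || all(d < 0)))
    stop_input("areas must be strictly monotone within a compression sweep")
  if (any(df$pi_mN_m < -1e-9))
    stop_input("negative surface pressure; baseline-correct first")
  structure(df, mole_fraction = mole_fraction, replicate = replicate,
            class = c("isotherm", "data.frame"))
}

#' Read isotherms from CSV
#'
#' Expects columns `area_A2`, `pi_mN_m`, `mole_fraction`, `replicate`;
#' one `isotherm` object is returned per (mole_fraction, replicate) group.
#'
#' @param path CSV path.
#' @return list of `isotherm` objects.
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop_input("isotherm file not found: %s", path)
  if (file.size(path) == 0) stop_input("isotherm file is empty: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_A2", "pi_mN_m", "mole_fraction", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_input("isotherm CSV missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop_input("isotherm CSV has no data rows: %s", path)
  groups <- split(df, list(df$mole_fraction, df$replicate), drop = TRUE)
  lapply(unname(groups), function(g)
    as_isotherm(g[order(-g$area_A2), c("area_A2", "pi_mN_m")],
                mole_fraction = g$mole_fraction[1],
                replicate = g$replicate[1]))
}

#' Write isotherms to CSV
#'
#' @param isotherms an `isotherm` or list of them.
#' @param path output path.
#' @export
write_isotherm_csv <- function(isotherms, path) {
  if (inherits(isotherms, "isotherm")) isotherms <- list(isotherms)
  rows <- lapply(isotherms, function(iso)
    data.frame(area_A2 = iso$area_A2, pi_mN_m = iso$pi_mN_m,
               mole_fraction = attr(iso, "mole_fraction"),
               replicate = attr(iso, "replicate")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Simple-regression helper: slope/intercept with slope se and r^2,
## warning-free on exact fits (noise-free synthetic curves are exact).
ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  tss <- sum((y - mean(y))^2)
  list(intercept = intercept, slope = slope,
       se_slope = if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_,
       r2 = if (tss > 0) 1 - rss / tss else 1)
}

## Smoothed running slope d(pi)/dA via centred local OLS over `window`
## points (exact on straight segments).
running_slope <- function(area, pi, window = 5) {
  n <- length(area)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    ix <- max(1, i - half):min(n, i + half)
    a <- area[ix]; p <- pi[ix]
    sum((a - mean(a)) * (p - mean(p))) / sum((a - mean(a))^2)
  }, 0)
}

## Centred running mean (partial windows at the edges).
running_mean <- function(x, window = 5) {
  n <- length(x)
  half <- window %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), 0)
}

#' Detect the collapse point of an isotherm
#'
#' Collapse is taken as the first point, along compression (decreasing
#' area), after the condensed branch is established, where the smoothed
#' running slope |d(pi)/dA| drops below `frac` of the condensed-branch
#' slope.  The condensed-branch slope is estimated by OLS over the points
#' whose smoothed pressure lies between 25 and 85 percent of the maximum
#' smoothed pressure (robust to measurement noise, exact on noise-free
#' curves); the search for the slope drop starts past that band.  If no
#' such plateau exists the global pressure maximum is returned with a
#' `"no-collapse-plateau"` flag.
#'
#' @param isotherm an `isotherm`.
#' @param frac slope-drop fraction defining the plateau (default 0.10).
#' @param window window (points) for pressure smoothing and the running
#'   slope.
#' @return list with `pi_c` (mN/m), `area_c` (Angstrom^2), `index`
#'   (row of the input), `method` (`"slope-drop"` or
#'   `"no-collapse-plateau"`), and `condensed_slope` (mN/m per
#'   Angstrom^2, positive).
#' @export
collapse_point <- function(isotherm, frac = 0.10, window = 5) {
  ord <- order(-isotherm$area_A2)
  A <- isotherm$area_A2[ord]; P <- isotherm$pi_mN_m[ord]
  Ps <- running_mean(P, window)
  pi_top <- max(Ps)
  band <- which(Ps >= 0.25 * pi_top & Ps <= 0.85 * pi_top)
  if (length(band) < 3) band <- seq_along(A)
  s_cond <- abs(ols_line(A[band], P[band])$slope)
  sl <- abs(running_slope(A, running_mean(P, window), window))
  after <- seq(min(max(band) + 1, length(A)), length(A))
  idx <- after[which(sl[after] < frac * s_cond)[1]]
  if (is.na(idx)) {
    i <- which.max(P)
    return(list(pi_c = P[i], area_c = A[i], index = ord[i],
                method = "no-collapse-plateau", condensed_slope = s_cond))
  }
  ## plateau pressure: maximum smoothed pressure from the drop point on
  list(pi_c = max(Ps[seq(idx, length(A))]), area_c = A[idx], index = ord[idx],
       method = "slope-drop", condensed_slope = s_cond)
}

#' Limiting molecular area by condensed-branch extrapolation
#'
#' Fits the linear condensed branch over a pressure band (by default 60
#' to 95 percent of the collapse pressure) and extrapolates to zero
#' pressure.
#'
#' @param isotherm an `isotherm`.
#' @param fit_band pressure band as fractions of the collapse pressure
#'   `c(lo, hi)`, or absolute pressures if `absolute = TRUE`.
#' @param absolute interpret `fit_band` as absolute mN/m values.
#' @return list with `limiting_area_A2`, `slope` (mN/m per Angstrom^2,
#'   signed), `r2`, `n_points`, `band` (mN/m).
#' @export
limiting_area <- function(isotherm, fit_band = c(0.60, 0.95),
                          absolute = FALSE) {
  cp <- collapse_point(isotherm)
  band <- if (absolute) fit_band else fit_band * cp$pi_c
  ## band membership judged on the smoothed pressure (reduces selection
  ## bias under measurement noise; identical on noise-free curves)
  ord <- order(-isotherm$area_A2)
  Ps <- running_mean(isotherm$pi_mN_m[ord], 5)[order(ord)]
  sel <- which(Ps >= band[1] & Ps <= band[2] &
                 isotherm$area_A2 >= cp$area_c - 1e-9)
  if (length(sel) < 5)
    stop_input("only %d points in the condensed-branch band [%.1f, %.1f] mN/m; widen fit_band",
               length(sel), band[1], band[2])
  a <- isotherm$area_A2[sel]; p <- isotherm$pi_mN_m[sel]
  fit <- ols_line(a, p)
  list(limiting_area_A2 = -fit$intercept / fit$slope, slope = fit$slope,
       r2 = fit$r2, n_points = length(sel), band = band)
}

#' In-plane compressibility modulus curve Cs^-1(pi)
#'
#' `Cs^-1 = -A * d(pi)/dA`, with the derivative from a smoothed (local
#' OLS) finite difference.  Exact (`m * A`) on a straight branch
#' `pi = m (A0 - A)`; tends to 0 on a collapse plateau.
#'
#' @param isotherm an `isotherm`.
#' @param window smoothing window in points.
#' @return data.frame with `area_A2`, `pi_mN_m`, `cs_inverse_mN_m`.
#' @export
cs_inverse <- function(isotherm, window = 5) {
  ord <- order(-isotherm$area_A2)
  A <- isotherm$area_A2[ord]; P <- isotherm$pi_mN_m[ord]
  sl <- running_slope(A, P, window)
  data.frame(area_A2 = A, pi_mN_m = P, cs_inverse_mN_m = -A * sl)
}

#' Mean-molecular-area mixing slopes across mole fractions
#'
#' For each reference pressure, interpolates the area `A(pi)` on every
#' curve's rising branch (curves whose collapse pressure lies below the
#' target are excluded with a warning) and regresses area on additive mole
#' fraction.  A negative slope flags a condensing additive, a positive
#' slope an expanding one.
#'
#' @param isotherms list of `isotherm` objects with `mole_fraction`
#'   attributes; the fractions must include 0 and span at least 3 values.
#' @param pi_list reference pressures, mN/m.
#' @return data.frame of class `mixing_slope` with `pi_mN_m`, `slope_A2`
#'   (Angstrom^2 per unit mole fraction), `se`, `n`, `interpretation`.
#' @export
mixing_slope <- function(isotherms, pi_list = c(10, 20, 30)) {
  fr <- vapply(isotherms, function(i) attr(i, "mole_fraction"), 0)
  if (length(unique(fr)) < 3)
    stop_input("need isotherms at >= 3 mole fractions (got %d)",
               length(unique(fr)))
  if (!any(fr == 0)) stop_input("mole fractions must include 0 (pure film)")
  out <- lapply(pi_list, function(p) {
    a_at <- mapply(function(iso, f) {
      cp <- collapse_point(iso)
      if (p > cp$pi_c) {
        warning(sprintf("pi = %g mN/m above collapse (%.1f) of curve at fraction %.2f; excluded",
                        p, cp$pi_c, f))
        return(NA_real_)
      }
      ## rising branch only (compression order up to the collapse index),
      ## interpolated on the smoothed curve to damp pressure noise
      ord <- order(-iso$area_A2)
      A <- iso$area_A2[ord]; P <- running_mean(iso$pi_mN_m[ord], 5)
      ic <- which(ord == cp$index)
      seg <- seq_len(ic)
      stats::approx(P[seg], A[seg], xout = p, ties = mean)$y
    }, isotherms, fr)
    ok <- is.finite(a_at)
    if (sum(ok) < 3 || length(unique(fr[ok])) < 3)
      return(data.frame(pi_mN_m = p, slope_A2 = NA, se = NA,
                        n = sum(ok), interpretation = NA))
    fit <- ols_line(fr[ok], a_at[ok])
    sl <- fit$slope
    data.frame(pi_mN_m = p, slope_A2 = sl, se = fit$se_slope, n = sum(ok),
               interpretation = if (sl < 0) "condensing" else
                 if (sl > 0) "expanding" else "neutral")
  })
  res <- do.call(rbind, out)
  class(res) <- c("mixing_slope", "data.frame")
  res
}
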
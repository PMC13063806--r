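#' @keywords internal
"_PACKAGE"

## Periodic-boundary helpers. All internal lengths are nm; boxes are
## rectangular (3-vector of edge lengths).

#' Wrap coordinates into the primary box image
#'
#' @param x numeric matrix (N x 3) or vector of coordinates in nm.
#' @param box numeric length-3 box edges in nm.
#' @return coordinates wrapped into `[0, box)` per axis.
#' @keywords internal
wrap_coords <- function(x, box) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  sweep(x, 2, box, function(v, L) v - L * floor(v / L))
}

## Minimum-image difference of two coordinate matrices (same nrow).
min_image_diff <- function(a, b, box) {
  d <- a - b
  sweep(d, 2, box, function(v, L) v - L * round(v / L))
}

## Minimum-image distances between one point and a matrix of points.
min_image_dist_one <- function(p, xyz, box) {
  d <- sweep(xyz, 2, p, "-")
  d <- sweep(d, 2, box, function(v, L) v - L * round(v / L))
  sqrt(rowSums(d * d))
}

## All-pairs minimum-image distance matrix between two coordinate sets.
## O(Na*Nb) memory; fine for the desk-scale frames this package targets.
min_image_dist_matrix <- function(xa, xb, box) {
  na <- nrow(xa); nb <- nrow(xb)
  dd <- matrix(0, na, nb)
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    dd <- dd + dk * dk
  }
  sqrt(dd)
}

## Deterministic quasi-uniform points on the unit sphere (golden-spiral
## / Fibonacci lattice), used by the Shrake-Rupley SASA sampler.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
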
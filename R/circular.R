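# Circular geometry and smoothing primitives shared by all analysis stages.
# Positions live on a circle of circumference L (cm); phases on [0, 360) deg.

#' Signed circular distance
#'
#' Shortest signed displacement from `b` to `a` on a circle of circumference
#' `L`. Positive values mean `a` lies ahead of `b` in the running direction.
#' The result lies in `(-L/2, L/2]`.
#'
#' @param a,b Positions in cm (recycled to common length).
#' @param L Circumference in cm (corridor length).
#' @return Numeric vector of signed distances in cm.
#' @examples
#' circular_distance(10, 190, 200)  # +20, wrap-around
#' circular_distance(190, 10, 200)  # -20
#' @export
circular_distance <- function(a, b, L) {
  stopifnot(L > 0)
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

#' Wrap positions onto [0, L)
#' @param x Positions in cm.
#' @param L Circumference in cm.
#' @return Wrapped positions.
#' @export
wrap_position <- function(x, L) x %% L

#' Wrap angles onto [0, 360)
#' @param deg Angles in degrees.
#' @return Angles in `[0, 360)`.
#' @export
wrap_deg <- function(deg) {
  r <- deg %% 360
  ifelse(r >= 360, 0, r)  # guards the floating-point 360 boundary
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Circular mean of angles in degrees
#' @param deg Angles in degrees.
#' @param w Optional non-negative weights.
#' @return Mean direction in `[0, 360)`, or `NA` if the resultant is ~0.
#' @export
circ_mean_deg <- function(deg, w = NULL) {
  th <- deg2rad(deg)
  if (is.null(w)) w <- rep(1, length(th))
  s <- sum(w * sin(th)); c <- sum(w * cos(th))
  if (sqrt(s^2 + c^2) < 1e-12 * max(sum(w), 1)) return(NA_real_)
  wrap_deg(rad2deg(atan2(s, c)))
}

#' Mean resultant length of angles in degrees
#' @param deg Angles in degrees.
#' @return Value in `[0, 1]`.
#' @export
circ_resultant <- function(deg) {
  th <- deg2rad(deg)
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}

#' Circular median of angles in degrees
#'
#' Minimizer (over observed angles) of the mean absolute circular deviation.
#' Returns `NA` with a warning when the objective is flat (near-uniform data,
#' median undefined).
#'
#' @param deg Angles in degrees.
#' @return Median direction in `[0, 360)` or `NA`.
#' @export
circ_median_deg <- function(deg) {
  deg <- wrap_deg(deg)
  n <- length(deg)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(deg)
  cand <- deg
  dev <- vapply(cand, function(m) {
    mean(abs(circular_distance(deg, m, 360)))
  }, numeric(1))
  if (diff(range(dev)) < 1e-9) {
    warning("circular median undefined (flat deviation profile)")
    return(NA_real_)
  }
  cand[which.min(dev)]
}

#' Circular mean of positions on a track of circumference L
#' @param x Positions in cm.
#' @param L Circumference in cm.
#' @param w Optional weights.
#' @return Mean position in `[0, L)`.
#' @export
circ_mean_pos <- function(x, L, w = NULL) {
  m <- circ_mean_deg(x / L * 360, w)
  if (is.na(m)) return(NA_real_)
  m / 360 * L
}

# Wrapped-Gaussian smoothing kernel over nbins circular bins; sd given in
# bins. Kernel sums to 1 so smoothing conserves totals exactly.
circular_kernel <- function(nbins, sd_bins) {
  if (sd_bins <= 0) {
    k <- numeric(nbins); k[1] <- 1
    return(k)
  }
  off <- seq_len(nbins) - 1L
  off <- ifelse(off > nbins / 2, off - nbins, off)
  # wrap the Gaussian a few times around the circle
  k <- rep(0, nbins)
  for (wrapk in -3:3) k <- k + stats::dnorm(off + wrapk * nbins, sd = sd_bins)
  k / sum(k)
}

# Circulant smoothing matrix K such that K %*% v smooths v circularly.
circular_smoother <- function(nbins, sd_bins) {
  k <- circular_kernel(nbins, sd_bins)
  idx <- outer(seq_len(nbins), seq_len(nbins), function(i, j) ((i - j) %% nbins) + 1L)
  matrix(k[idx], nbins, nbins)
}

#' Circular Gaussian smoothing
#'
#' Smooths a vector (or the rows/columns of a matrix) defined on circular
#' bins with a wrapped Gaussian kernel. The kernel is normalized so that the
#' sum of the input is conserved.
#'
#' @param x Numeric vector, or matrix when smoothing along one margin.
#' @param sd_bins Kernel standard deviation in bin units.
#' @param margin For matrices: 1 smooths down columns (i.e., along the first
#'   dimension), 2 along rows.
#' @return Smoothed object of the same shape.
#' @export
smooth_circular <- function(x, sd_bins, margin = 1) {
  if (is.matrix(x)) {
    if (margin == 1) {
      K <- circular_smoother(nrow(x), sd_bins)
      return(K %*% x)
    } else {
      K <- circular_smoother(ncol(x), sd_bins)
      return(x %*% t(K))
    }
  }
  K <- circular_smoother(length(x), sd_bins)
  drop(K %*% x)
}

# Rotate a vector circularly by k bins: result[i] = x[i - k] (forward shift).
rotate_bins <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Rayleigh test of circular uniformity
#'
#' Standard Rayleigh test with the usual finite-sample correction to the
#' asymptotic p-value. By convention `n = 1` returns `p = 1`.
#'
#' @param deg Angles in degrees.
#' @return List with `r` (mean resultant length), `z` statistic and `p.value`.
#' @export
rayleigh_test <- function(deg) {
  n <- length(deg)
  stopifnot(n >= 1)
  r <- circ_resultant(deg)
  if (n == 1L) return(list(r = r, z = r^2, p.value = 1))
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r = r, z = z, p.value = min(max(p, 0), 1))
}
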
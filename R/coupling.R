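# Co-fluctuation of V1 and CA1 decoding errors beyond position and speed:
# joint error maps against within-(position, speed) shuffles, the
# split-thirds overfitting control, decoded-position mismatch distributions
# and cycle-by-cycle theta-amplitude coupling.

speed_quintile <- function(speed, n_quant = 5) {
  q <- stats::quantile(speed, probs = seq(0, 1, length.out = n_quant + 1),
                       names = FALSE)
  q[1] <- -Inf; q[n_quant + 1] <- Inf
  findInterval(speed, q, rightmost.closed = TRUE)
}

cell_index <- function(position_cm, speed, L, bin_cm = 2, n_quant = 5) {
  pb <- profile_bins(position_cm, L, bin_cm)
  sq <- speed_quintile(speed, n_quant)
  (pb - 1L) * n_quant + sq
}

err_hist2 <- function(e1, e2, L, err_bin) {
  nb <- as.integer(round(L / err_bin))
  b1 <- profile_bins(e1 + L / 2, L, err_bin)
  b2 <- profile_bins(e2 + L / 2, L, err_bin)
  matrix(tabulate(b1 + nb * (b2 - 1L), nb * nb), nb, nb)
}

finish_map <- function(H, L, err_bin, sd_cm) {
  H <- smooth_circular(smooth_circular(H, sd_cm / err_bin, 1),
                       sd_cm / err_bin, 2)
  H / sum(H)
}

#' Joint distribution of V1 and CA1 decoding errors
#'
#' Joint histogram of simultaneous signed circular errors, accumulated over
#' (2-cm position x speed-quintile) conditioning cells, smoothed with a
#' 4x4-cm circular Gaussian and normalized to sum to 1.
#'
#' @param err_v1,err_ca1 Signed errors per simultaneous window (cm).
#' @param position_cm,speed Position and speed per window (conditioning).
#' @param L Corridor length (cm).
#' @param err_bin Error bin width (cm).
#' @param sd_cm Smoothing s.d. (cm).
#' @param pos_bin Conditioning position bin (cm).
#' @param n_quant Number of speed quantile bins.
#' @return List of class `joint_error_map`: `map` (V1 x CA1), `centers_cm`,
#'   `cells` (cell index per window).
#' @export
joint_error_map <- function(err_v1, err_ca1, position_cm, speed, L,
                            err_bin = 4, sd_cm = 4, pos_bin = 2,
                            n_quant = 5) {
  ok <- is.finite(err_v1) & is.finite(err_ca1)
  if (sum(ok) < 2) stop("need at least 2 simultaneous windows")
  err_v1 <- err_v1[ok]; err_ca1 <- err_ca1[ok]
  cells <- cell_index(position_cm[ok], speed[ok], L, pos_bin, n_quant)
  H <- err_hist2(err_v1, err_ca1, L, err_bin)
  structure(list(map = finish_map(H, L, err_bin, sd_cm),
                 centers_cm = (seq_len(nrow(H)) - 0.5) * err_bin - L / 2,
                 cells = cells, err_v1 = err_v1, err_ca1 = err_ca1,
                 L = L, err_bin = err_bin, sd_cm = sd_cm),
            class = "joint_error_map")
}

#' Within-(position, speed) shuffle of error pairings
#'
#' Permutes the CA1 errors among windows sharing a conditioning cell (same
#' 2-cm position bin and speed quintile), preserving both marginals per
#' cell; singleton cells are left fixed and counted. The returned map
#' averages `n_rep` shuffles.
#'
#' @param jem A `joint_error_map`.
#' @param n_rep Number of shuffle repetitions to average.
#' @param seed Seed.
#' @return List with `map` (shuffled, same normalization), `difference`
#'   (measured - shuffled), `n_singleton`.
#' @export
shuffle_within_bins <- function(jem, n_rep = 100, seed = 1) {
  if (n_rep <= 0) stop("n_rep must be positive")
  set.seed(seed)
  cells <- jem$cells
  L <- jem$L; err_bin <- jem$err_bin
  groups <- split(seq_along(cells), cells)
  n_singleton <- sum(lengths(groups) == 1)
  acc <- 0
  for (r in seq_len(n_rep)) {
    e2 <- jem$err_ca1
    for (g in groups) if (length(g) > 1) e2[g] <- e2[sample(g)]
    acc <- acc + err_hist2(jem$err_v1, e2, L, err_bin)
  }
  sh <- finish_map(acc / n_rep, L, err_bin, jem$sd_cm)
  list(map = sh, difference = jem$map - sh, n_singleton = n_singleton)
}

#' Integrated diagonal excess of a difference map
#'
#' Sum of the difference map over cells within `band_cm` of the identity
#' diagonal (circular distance between the two error axes); positive values
#' indicate co-fluctuating errors beyond position/speed.
#'
#' @param difference Difference map (measured - shuffled).
#' @param centers_cm Error-bin centers.
#' @param band_cm Diagonal half-width (cm).
#' @return Scalar excess.
#' @export
diagonal_excess <- function(difference, centers_cm, band_cm = 10) {
  L <- length(centers_cm) * diff(centers_cm[1:2])
  D <- outer(centers_cm, centers_cm,
             function(a, b) abs(circular_distance(a, b, L)))
  sum(difference[D <= band_cm])
}

#' Distribution of V1-CA1 decoded-position mismatches
#'
#' Density of the circular distance between simultaneously decoded V1 and
#' CA1 positions, measured versus the within-(position, speed) shuffle.
#'
#' @inheritParams joint_error_map
#' @param dec_v1,dec_ca1 Decoded positions per simultaneous window (cm).
#' @param n_rep,seed Shuffle parameters.
#' @return List with `centers_cm`, `measured`, `shuffled`, `difference`
#'   (densities over mismatch bins).
#' @export
mismatch_distribution <- function(dec_v1, dec_ca1, position_cm, speed, L,
                                  err_bin = 4, sd_cm = 4, pos_bin = 2,
                                  n_quant = 5, n_rep = 100, seed = 1) {
  ok <- is.finite(dec_v1) & is.finite(dec_ca1)
  if (sum(ok) < 2) stop("need at least 2 simultaneous windows")
  dec_v1 <- dec_v1[ok]; dec_ca1 <- dec_ca1[ok]
  cells <- cell_index(position_cm[ok], speed[ok], L, pos_bin, n_quant)
  nb <- as.integer(round(L / err_bin))
  dens <- function(d) {
    h <- tabulate(profile_bins(d + L / 2, L, err_bin), nb)
    h <- smooth_circular(h, sd_cm / err_bin)
    h / sum(h)
  }
  meas <- dens(circular_distance(dec_v1, dec_ca1, L))
  set.seed(seed)
  groups <- split(seq_along(cells), cells)
  acc <- 0
  for (r in seq_len(n_rep)) {
    d2 <- dec_ca1
    for (g in groups) if (length(g) > 1) d2[g] <- d2[sample(g)]
    acc <- acc + dens(circular_distance(dec_v1, d2, L))
  }
  sh <- acc / n_rep
  list(centers_cm = (seq_len(nb) - 0.5) * err_bin - L / 2, measured = meas,
       shuffled = sh, difference = meas - sh)
}

#' Split-thirds control for error coupling
#'
#' Guards against common overfitting of behavioral events: the V1 encoding
#' model is trained on the first third of the usable trials, the CA1 model
#' on the second third, and the error coupling is evaluated on the final
#' third only.
#'
#' @param spikes Spike table.
#' @param timeline Session timeline.
#' @param trials Trial table.
#' @param ids_v1,ids_ca1 Neuron ids per region.
#' @param mask Speed mask.
#' @param outcomes Optional outcomes; correct trials only when given.
#' @param medium_gain Gain condition used throughout.
#' @param window_s Counting window (s).
#' @param n_rep,seed Shuffle parameters.
#' @param ... Passed to [fit_encoding_model()].
#' @return List with `measured`, `shuffled`, `difference` maps,
#'   `diag_excess`, and the evaluation `windows`.
#' @export
split_thirds_control <- function(spikes, timeline, trials, ids_v1, ids_ca1,
                                 mask = NULL, outcomes = NULL,
                                 medium_gain = 1, window_s = 0.25,
                                 n_rep = 50, seed = 1, ...) {
  L <- attr(timeline, "geometry")$corridor_length
  sample_trial <- attr(trials, "sample_trial")
  if (is.null(sample_trial)) sample_trial <- timeline$trial_id
  keep <- if (is.null(mask)) rep(TRUE, nrow(timeline)) else mask
  use <- trials$trial_id[trials$gain == medium_gain]
  if (!is.null(outcomes))
    use <- intersect(use, outcomes$trial_id[outcomes$outcome == "correct"])
  use <- sort(use)
  if (length(use) < 3) stop("need at least 3 usable trials")
  parts <- split(use, cut(seq_along(use), 3, labels = FALSE))
  stopifnot(!any(duplicated(unlist(parts))))
  m_v1 <- fit_encoding_model(spikes, timeline, ids_v1,
                             keep & sample_trial %in% parts[[1]], ...)
  m_ca1 <- fit_encoding_model(spikes, timeline, ids_ca1,
                              keep & sample_trial %in% parts[[2]], ...)
  ev <- keep & sample_trial %in% parts[[3]]
  windows <- decode_windows(timeline, ev, window_s)
  if (is.null(windows) || nrow(windows) < 2)
    stop("too few evaluation windows")
  dec <- function(model) {
    cnt <- window_counts(spikes, model$neuron_ids, windows, window_s)
    post <- decode_posterior(cnt, model, window_s)
    model$centers_cm[max.col(post, ties.method = "first")]
  }
  dv <- dec(m_v1); dc <- dec(m_ca1)
  ev1 <- circular_distance(dv, windows$actual_cm, L)
  ec1 <- circular_distance(dc, windows$actual_cm, L)
  jem <- joint_error_map(ev1, ec1, windows$actual_cm, windows$speed_cm_s, L)
  sh <- shuffle_within_bins(jem, n_rep = n_rep, seed = seed)
  list(measured = jem$map, shuffled = sh$map, difference = sh$difference,
       diag_excess = diagonal_excess(sh$difference, jem$centers_cm),
       windows = windows)
}

# per-cycle sinusoid amplitude of errors over theta phase
cycle_amplitudes <- function(error_cm, phase_deg, cycle, min_windows = 3) {
  ok <- is.finite(error_cm) & is.finite(phase_deg)
  res <- lapply(split(which(ok), cycle[ok]), function(ii) {
    if (length(ii) < min_windows) return(NULL)
    th <- deg2rad(phase_deg[ii])
    X <- cbind(sin(th), cos(th), 1)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-10) return(NULL)
    cf <- solve(XtX, crossprod(X, error_cm[ii]))
    data.frame(cycle = cycle[ii[1]], amplitude = sqrt(cf[1]^2 + cf[2]^2),
               n = length(ii))
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Cycle-by-cycle correlation of theta error modulation
#'
#' Fits a sinusoid to each region's decoding errors within every theta
#' cycle (>= 3 windows), takes the absolute amplitude per cycle, and
#' correlates the two regions' amplitudes across cycles. The null permutes
#' cycle pairings within (position, speed-quintile) cells of the cycle.
#'
#' @param err_v1,err_ca1 Errors per 50-ms window (aligned across regions).
#' @param phase_deg,cycle Theta phase and cycle id per window.
#' @param position_cm,speed Cycle conditioning variables per window.
#' @param L Corridor length.
#' @param min_windows Minimum windows per cycle.
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return List with `r`, `p_value`, `significant`, `n_cycles`,
#'   `n_skipped`, `degenerate`.
#' @export
cycle_modulation_correlation <- function(err_v1, err_ca1, phase_deg, cycle,
                                         position_cm, speed, L,
                                         min_windows = 3, n_shuffle = 100,
                                         alpha = 0.05, seed = 1) {
  a1 <- cycle_amplitudes(err_v1, phase_deg, cycle, min_windows)
  a2 <- cycle_amplitudes(err_ca1, phase_deg, cycle, min_windows)
  common <- intersect(a1$cycle, a2$cycle)
  n_total <- length(unique(cycle))
  if (length(common) < 30)
    stop("need at least 30 complete cycles with >= ", min_windows, " windows")
  x <- a1$amplitude[match(common, a1$cycle)]
  y <- a2$amplitude[match(common, a2$cycle)]
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    return(list(r = NA_real_, p_value = NA_real_, significant = FALSE,
                n_cycles = length(common),
                n_skipped = n_total - length(common), degenerate = TRUE))
  cyc_pos <- vapply(common, function(cc)
    circ_mean_pos(position_cm[cycle == cc], L), numeric(1))
  cyc_speed <- vapply(common, function(cc) mean(speed[cycle == cc]),
                      numeric(1))
  cells <- cell_index(cyc_pos, cyc_speed, L, bin_cm = 2)
  obs <- stats::cor(x, y)
  set.seed(seed)
  groups <- split(seq_along(cells), cells)
  null <- vapply(seq_len(n_shuffle), function(i) {
    y2 <- y
    for (g in groups) if (length(g) > 1) y2[g] <- y2[sample(g)]
    stats::cor(x, y2)
  }, numeric(1))
  list(r = obs, p_value = perm_p(obs, null),
       significant = obs > null_threshold(null, alpha),
       n_cycles = length(common), n_skipped = n_total - length(common),
       degenerate = FALSE)
}
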
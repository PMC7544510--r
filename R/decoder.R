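# Independent-Poisson Bayesian population decoding of position, with
# cross-validated decoding of the reference (medium-gain) condition,
# error/bias summaries with jackknife errors, theta-phase-resolved decoding
# and lick positions in decoded coordinates.

#' Fit an encoding model
#'
#' Per-neuron spatial response profiles `f_i(x)` over 2-cm bins computed
#' from the training samples (typically medium-gain correct trials), plus a
#' position prior (training occupancy or uniform).
#'
#' @param spikes Spike table (`neuron_id`, `time_s`).
#' @param timeline Session timeline.
#' @param neuron_ids Neurons to include.
#' @param train_samples Logical vector of training samples (already masked).
#' @param bin_cm,sd_cm Spatial binning/smoothing.
#' @param prior `"occupancy"` or `"uniform"`.
#' @param rate_floor Minimum rate (Hz) inside the likelihood, avoiding
#'   log(0).
#' @return Object of class `encoding_model`: `f` (neurons x bins, Hz),
#'   `neuron_ids`, `prior`, `centers_cm`, `bin_cm`, `rate_floor`.
#' @export
fit_encoding_model <- function(spikes, timeline, neuron_ids, train_samples,
                               bin_cm = 2, sd_cm = 8,
                               prior = c("occupancy", "uniform"),
                               rate_floor = 0.01) {
  prior <- match.arg(prior)
  L <- attr(timeline, "geometry")$corridor_length
  nbins <- as.integer(round(L / bin_cm))
  f <- matrix(0, length(neuron_ids), nbins)
  for (k in seq_along(neuron_ids)) {
    p <- spatial_profile(spike_times(spikes, neuron_ids[k]), timeline,
                         mask = train_samples, bin_cm = bin_cm, sd_cm = sd_cm)
    f[k, ] <- p$rate_hz
  }
  pr <- if (prior == "uniform") rep(1 / nbins, nbins) else {
    occ <- smooth_circular(tabulate(profile_bins(timeline$position_cm, L,
                                                 bin_cm)[train_samples],
                                    nbins), sd_cm / bin_cm)
    occ / sum(occ)
  }
  structure(list(f = f, neuron_ids = neuron_ids, prior = pr,
                 centers_cm = (seq_len(nbins) - 0.5) * bin_cm,
                 bin_cm = bin_cm, rate_floor = rate_floor),
            class = "encoding_model")
}

#' Posterior over position from a spike-count vector (or matrix)
#'
#' `P(x|R) = 1/Z P(x) (prod_i f_i(x)^{r_i}) exp(-t sum_i f_i(x))`, computed
#' in the log domain with rates floored at `rate_floor`; each posterior row
#' is normalized to sum to 1.
#'
#' @param counts Integer spike counts: vector (one window, length = number of
#'   neurons) or windows x neurons matrix.
#' @param model An `encoding_model`.
#' @param t_window Counting-window length in seconds.
#' @return Matrix (windows x position bins) of posteriors.
#' @export
decode_posterior <- function(counts, model, t_window) {
  if (is.vector(counts)) counts <- matrix(counts, 1)
  stopifnot(t_window > 0, all(counts >= 0))
  f <- pmax(model$f, model$rate_floor)
  logf <- log(f)
  ll <- counts %*% logf
  ll <- sweep(ll, 2, t_window * colSums(f), "-")
  ll <- sweep(ll, 2, log(model$prior), "+")
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  s <- rowSums(p)
  if (any(s <= 0)) stop("all-zero posterior mass")
  p / s
}

# Tile the session into fixed windows; a window is usable when more than
# half of its samples pass the mask. Position/phase are circular means over
# the masked samples; gain/trial come from the center sample.
decode_windows <- function(timeline, mask, window_s, phase_deg = NULL) {
  fs <- attr(timeline, "sample_rate")
  L <- attr(timeline, "geometry")$corridor_length
  n <- nrow(timeline)
  wlen <- max(1L, round(window_s * fs))
  nW <- floor(n / wlen)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  out <- vector("list", nW)
  for (w in seq_len(nW)) {
    i0 <- (w - 1L) * wlen + 1L
    ii <- i0:(i0 + wlen - 1L)
    mi <- ii[keep[ii]]
    if (length(mi) <= wlen / 2) next
    ctr <- ii[ceiling(wlen / 2)]
    out[[w]] <- data.frame(
      window = w, i_start = i0, i_end = i0 + wlen - 1L,
      t_start = timeline$time_s[i0],
      t_mid = timeline$time_s[i0] + window_s / 2,
      actual_cm = circ_mean_pos(timeline$position_cm[mi], L),
      gain = timeline$gain[ctr], trial_id = timeline$trial_id[ctr],
      speed_cm_s = mean(timeline$speed_cm_s[mi]),
      phase_deg = if (is.null(phase_deg)) NA_real_ else
        circ_mean_deg(phase_deg[mi]))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# spike counts per (window, neuron)
window_counts <- function(spikes, neuron_ids, windows, window_s) {
  W <- nrow(windows)
  M <- length(neuron_ids)
  cnt <- matrix(0L, W, M)
  for (k in seq_len(M)) {
    st <- spike_times(spikes, neuron_ids[k])
    w <- findInterval(st, windows$t_start)
    sel <- w >= 1 & w <= W & st < windows$t_start[pmax(w, 1)] + window_s
    cnt[, k] <- tabulate(w[sel], W)
  }
  cnt
}

# contiguous fold assignment over a set of trial ids
fold_trials <- function(trial_ids, folds) {
  trial_ids <- sort(unique(trial_ids))
  split(trial_ids, ceiling(seq_along(trial_ids) / (length(trial_ids) / folds)))
}

#' Decode a session
#'
#' Decodes position from population spike counts in fixed windows (250 ms
#' default). Windows of the reference gain are decoded with fold-held-out
#' encoding models (contiguous trial blocks, 20 folds); windows at other
#' gains are decoded with the full reference model, which is trained on
#' reference-gain (optionally correct-only) trials.
#'
#' @param spikes Spike table.
#' @param timeline Session timeline.
#' @param trials Trial table from [segment_trials()].
#' @param neuron_ids Neurons used for decoding (>= 10 required).
#' @param mask Speed mask over samples.
#' @param outcomes Optional outcome table; training restricted to `correct`
#'   trials when given.
#' @param medium_gain Reference gain (default 1).
#' @param window_s Counting window (s).
#' @param folds Number of cross-validation folds.
#' @param phase_deg Optional theta phase per sample, carried into the result.
#' @param bin_cm,sd_cm,prior,rate_floor Passed to [fit_encoding_model()].
#' @return Object of class `decoding_result`: `data.frame` windows with
#'   decoded position and signed circular error plus the full model as
#'   attribute `model`.
#' @export
decode_session <- function(spikes, timeline, trials, neuron_ids, mask = NULL,
                           outcomes = NULL, medium_gain = 1, window_s = 0.25,
                           folds = 20, phase_deg = NULL, bin_cm = 2,
                           sd_cm = 8, prior = "occupancy",
                           rate_floor = 0.01) {
  if (length(neuron_ids) < 10)
    stop("refusing to decode: fewer than 10 usable neurons")
  L <- attr(timeline, "geometry")$corridor_length
  sample_trial <- attr(trials, "sample_trial")
  if (is.null(sample_trial)) sample_trial <- timeline$trial_id
  keep <- if (is.null(mask)) rep(TRUE, nrow(timeline)) else mask
  train_ok <- trials$trial_id[trials$gain == medium_gain]
  if (!is.null(outcomes))
    train_ok <- intersect(train_ok,
                          outcomes$trial_id[outcomes$outcome == "correct"])
  if (length(train_ok) == 0) stop("no reference-gain training trials")
  windows <- decode_windows(timeline, keep, window_s, phase_deg)
  cnt <- window_counts(spikes, neuron_ids, windows, window_s)
  full_train <- keep & sample_trial %in% train_ok
  model <- fit_encoding_model(spikes, timeline, neuron_ids, full_train,
                              bin_cm, sd_cm, prior, rate_floor)
  decoded <- rep(NA_real_, nrow(windows))
  fold_id <- rep(NA_integer_, nrow(windows))
  is_med <- windows$gain == medium_gain
  # non-reference windows: full model
  if (any(!is_med)) {
    post <- decode_posterior(cnt[!is_med, , drop = FALSE], model, window_s)
    decoded[!is_med] <- model$centers_cm[max.col(post, ties.method = "first")]
  }
  # reference windows: held-out models over contiguous trial folds
  med_trials <- sort(unique(windows$trial_id[is_med]))
  nf <- min(folds, length(med_trials))
  fsets <- fold_trials(med_trials, nf)
  for (fi in seq_along(fsets)) {
    wsel <- is_med & windows$trial_id %in% fsets[[fi]]
    if (!any(wsel)) next
    tr <- keep & sample_trial %in% setdiff(train_ok, fsets[[fi]])
    mk <- fit_encoding_model(spikes, timeline, neuron_ids, tr, bin_cm, sd_cm,
                             prior, rate_floor)
    post <- decode_posterior(cnt[wsel, , drop = FALSE], mk, window_s)
    decoded[wsel] <- mk$centers_cm[max.col(post, ties.method = "first")]
    fold_id[wsel] <- fi
  }
  # pseudo-folds for non-reference windows (jackknife support)
  for (g in setdiff(unique(windows$gain), medium_gain)) {
    sel <- windows$gain == g
    gts <- fold_trials(windows$trial_id[sel], min(folds, length(unique(windows$trial_id[sel]))))
    for (fi in seq_along(gts))
      fold_id[sel & windows$trial_id %in% gts[[fi]]] <- fi
  }
  windows$decoded_cm <- decoded
  windows$error_cm <- circular_distance(decoded, windows$actual_cm, L)
  windows$fold <- fold_id
  attr(windows, "model") <- model
  attr(windows, "L") <- L
  attr(windows, "window_s") <- window_s
  class(windows) <- c("decoding_result", "data.frame")
  windows
}

#' Distribution of decoded versus actual position
#'
#' Joint density of decoded position given actual position, smoothed with a
#' 2x2-cm circular Gaussian and normalized so each actual-position column
#' sums to 1. Unvisited columns are NA and flagged.
#'
#' @param result A `decoding_result`.
#' @param bin_cm Bin width (cm).
#' @param sd_cm Smoothing s.d. (cm) in both dimensions.
#' @return Matrix decoded x actual, attribute `unvisited` marks empty
#'   columns.
#' @export
decoded_distribution <- function(result, bin_cm = 2, sd_cm = 2) {
  if (nrow(result) == 0) stop("empty decoding result")
  L <- attr(result, "L")
  nb <- as.integer(round(L / bin_cm))
  bd <- profile_bins(result$decoded_cm, L, bin_cm)
  ba <- profile_bins(result$actual_cm, L, bin_cm)
  J <- matrix(tabulate(bd + nb * (ba - 1L), nb * nb), nb, nb)
  J <- smooth_circular(smooth_circular(J, sd_cm / bin_cm, margin = 1),
                       sd_cm / bin_cm, margin = 2)
  cs <- colSums(J)
  unvisited <- cs <= 1e-12
  J <- sweep(J, 2, pmax(cs, 1e-12), "/")
  J[, unvisited] <- NA_real_
  attr(J, "unvisited") <- unvisited
  attr(J, "centers_cm") <- (seq_len(nb) - 0.5) * bin_cm
  J
}

jackknife_se <- function(est_k) {
  est_k <- est_k[is.finite(est_k)]
  K <- length(est_k)
  if (K < 2) return(0)
  sqrt((K - 1) / K * sum((est_k - mean(est_k))^2))
}

# per-position error distribution, mean circular error and modal error
error_by_position <- function(errors, actual, L, bin_cm, sd_cm = 2) {
  npos <- as.integer(round(L / bin_cm))
  nerr <- npos
  bp <- profile_bins(actual, L, bin_cm)
  be <- profile_bins(errors + L / 2, L, bin_cm)  # map (-L/2, L/2] onto [0, L)
  D <- matrix(tabulate(be + nerr * (bp - 1L), nerr * npos), nerr, npos)
  D <- smooth_circular(smooth_circular(D, sd_cm / bin_cm, 1), sd_cm / bin_cm, 2)
  err_centers <- (seq_len(nerr) - 0.5) * bin_cm - L / 2
  cs <- colSums(D)
  mean_err <- rep(NA_real_, npos); bias <- rep(NA_real_, npos)
  for (j in which(cs > 1e-12)) {
    w <- D[, j] / cs[j]
    mean_err[j] <- circular_distance(circ_mean_pos(err_centers + L / 2, L, w),
                                     L / 2, L)
    bias[j] <- err_centers[which.max(D[, j])]
  }
  list(density = sweep(D, 2, pmax(cs, 1e-12), "/"), mean_error = mean_err,
       bias = bias, err_centers = err_centers,
       pos_centers = (seq_len(npos) - 0.5) * bin_cm)
}

#' Per-position decoding error and bias summaries
#'
#' For each gain condition: the per-position distribution of signed circular
#' decoding errors, its weighted circular mean (mean decoding error) and its
#' mode (decoding bias). Non-reference gains are reported after subtracting
#' the reference-gain value per position; standard errors come from
#' leave-one-fold-out jackknife over the decoding folds.
#'
#' @param result A `decoding_result`.
#' @param medium_gain Reference gain.
#' @param bin_cm Position/error bin width (cm).
#' @param sd_cm Smoothing s.d. of the error distributions (cm).
#' @return Named list (one entry per gain) of `data.frame(position_cm,
#'   mean_error_cm, bias_cm, se_mean, se_bias, corrected)`.
#' @export
error_summaries <- function(result, medium_gain = 1, bin_cm = 2, sd_cm = 2) {
  L <- attr(result, "L")
  gains <- sort(unique(result$gain))
  if (!medium_gain %in% gains) stop("reference gain absent from result")
  base <- error_by_position(result$error_cm[result$gain == medium_gain],
                            result$actual_cm[result$gain == medium_gain],
                            L, bin_cm, sd_cm)
  out <- list()
  for (g in gains) {
    sel <- result$gain == g
    eb <- error_by_position(result$error_cm[sel], result$actual_cm[sel],
                            L, bin_cm, sd_cm)
    corr <- g != medium_gain
    me <- eb$mean_error; bi <- eb$bias
    if (corr) {
      me <- circular_distance(me, base$mean_error, L)
      bi <- circular_distance(bi, base$bias, L)
    }
    fk <- sort(unique(result$fold[sel]))
    jk_me <- matrix(NA_real_, length(fk), length(me))
    jk_bi <- jk_me
    for (i in seq_along(fk)) {
      s2 <- sel & (is.na(result$fold) | result$fold != fk[i])
      if (sum(s2) < 2) next
      e2 <- error_by_position(result$error_cm[s2], result$actual_cm[s2],
                              L, bin_cm, sd_cm)
      jk_me[i, ] <- e2$mean_error
      jk_bi[i, ] <- e2$bias
    }
    out[[as.character(g)]] <- data.frame(
      position_cm = eb$pos_centers, mean_error_cm = me, bias_cm = bi,
      se_mean = apply(jk_me, 2, jackknife_se),
      se_bias = apply(jk_bi, 2, jackknife_se),
      corrected = corr)
  }
  out
}

#' Theta-phase modulation of decoding errors
#'
#' Mean decoding error per 20-deg theta-phase bin (40-deg smoothing), the
#' best-fitting sinusoid, and a permutation test that randomizes the
#' window phases.
#'
#' @param error_cm Signed circular decoding errors per window.
#' @param phase_deg Theta phase per window.
#' @param L Corridor length (cm).
#' @param bin_deg,sd_deg Phase binning and smoothing.
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return List with `curve` (`data.frame(phase_deg, mean_error_cm)`),
#'   `amplitude_cm`, `offset_deg`, `p_value`, `significant`.
#' @export
phase_error_modulation <- function(error_cm, phase_deg, L, bin_deg = 20,
                                   sd_deg = 40, n_shuffle = 500,
                                   alpha = 0.05, seed = 1) {
  ok <- is.finite(error_cm) & is.finite(phase_deg)
  error_cm <- error_cm[ok]; phase_deg <- phase_deg[ok]
  nb <- as.integer(round(360 / bin_deg))
  if (length(error_cm) < 2 * nb) stop("insufficient windows per phase bin")
  pb <- pmin(floor(wrap_deg(phase_deg) / bin_deg) + 1L, nb)
  centers <- (seq_len(nb) - 0.5) * bin_deg
  curvefn <- function(pb) {
    s <- vapply(seq_len(nb), function(k)
      if (any(pb == k)) mean(error_cm[pb == k]) else NA_real_, numeric(1))
    s[!is.finite(s)] <- mean(error_cm)
    smooth_circular(s, sd_deg / bin_deg)
  }
  ampfn <- function(pb) {
    f <- fit_drift_sinusoid(curvefn(pb), centers)
    f$amplitude_cm
  }
  curve <- curvefn(pb)
  fit <- fit_drift_sinusoid(curve, centers)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) ampfn(sample(pb)), numeric(1))
  thr <- null_threshold(null, alpha)
  list(curve = data.frame(phase_deg = centers, mean_error_cm = curve),
       amplitude_cm = fit$amplitude_cm, offset_deg = fit$offset_deg,
       p_value = perm_p(fit$amplitude_cm, null),
       significant = fit$amplitude_cm > thr, threshold = thr)
}

#' Decode in short windows and test the theta dependence of errors
#'
#' Decodes with a 50-ms counting window using the supplied (full) encoding
#' model and applies [phase_error_modulation()] to the resulting errors.
#'
#' @inheritParams decode_session
#' @param model An `encoding_model` (trained on reference-gain trials).
#' @param gains Optional subset of gains to include (default all).
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return As [phase_error_modulation()], plus `windows` (the decoded table).
#' @export
decode_by_theta_phase <- function(spikes, timeline, model, phase_deg,
                                  mask = NULL, window_s = 0.05, gains = NULL,
                                  n_shuffle = 500, alpha = 0.05, seed = 1) {
  L <- attr(timeline, "geometry")$corridor_length
  windows <- decode_windows(timeline, mask, window_s, phase_deg)
  if (!is.null(gains)) windows <- windows[windows$gain %in% gains, ]
  cnt <- window_counts(spikes, model$neuron_ids, windows, window_s)
  post <- decode_posterior(cnt, model, window_s)
  windows$decoded_cm <- model$centers_cm[max.col(post, ties.method = "first")]
  windows$error_cm <- circular_distance(windows$decoded_cm,
                                        windows$actual_cm, L)
  mod <- phase_error_modulation(windows$error_cm, windows$phase_deg, L,
                                n_shuffle = n_shuffle, alpha = alpha,
                                seed = seed)
  mod$windows <- windows
  mod
}

#' Lick positions in decoded coordinates
#'
#' Assigns each lick the decoded position of its containing decoding window
#' and summarizes the per-gain densities (8-cm s.d. smoothing) and the shift
#' of the circular-mean lick position relative to the reference gain.
#'
#' @param licks Lick table from [lick_events()] (a `gain` column is added
#'   from the containing window).
#' @param result A `decoding_result`.
#' @param medium_gain Reference gain.
#' @param bin_cm,sd_cm Density binning/smoothing (cm).
#' @return List with `density` (bins x gains matrix), `shift_cm` (named, per
#'   gain, vs. reference), `mean_cm` (circular mean decoded lick position per
#'   gain), `n_dropped` (licks outside decoded windows).
#' @export
licks_in_decoded_coordinates <- function(licks, result, medium_gain = 1,
                                         bin_cm = 2, sd_cm = 8) {
  L <- attr(result, "L")
  window_s <- attr(result, "window_s")
  if (nrow(licks) == 0)
    return(list(density = NULL, shift_cm = numeric(0), mean_cm = numeric(0),
                n_dropped = 0L))
  w <- findInterval(licks$time_s, result$t_start)
  inw <- w >= 1 & w <= nrow(result) &
    licks$time_s < result$t_start[pmax(w, 1)] + window_s
  dropped <- sum(!inw)
  dec <- result$decoded_cm[w[inw]]
  gain <- result$gain[w[inw]]
  nb <- as.integer(round(L / bin_cm))
  gains <- sort(unique(gain))
  dens <- sapply(gains, function(g) {
    d <- tabulate(profile_bins(dec[gain == g], L, bin_cm), nb)
    d <- smooth_circular(d, sd_cm / bin_cm)
    if (sum(d) > 0) d / sum(d) else d
  })
  colnames(dens) <- as.character(gains)
  means <- vapply(gains, function(g) circ_mean_pos(dec[gain == g], L),
                  numeric(1))
  names(means) <- as.character(gains)
  ref <- if (as.character(medium_gain) %in% names(means))
    means[[as.character(medium_gain)]] else NA_real_
  shifts <- vapply(means, function(m) circular_distance(m, ref, L), numeric(1))
  list(density = dens, shift_cm = shifts, mean_cm = means,
       n_dropped = dropped)
}
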
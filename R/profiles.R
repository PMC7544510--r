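# Spatial response profiles, circular-shift permutation tests, gain-shift
# estimation and variance decomposition.
#
# Profiles are ratios of circularly smoothed spike-count maps over smoothed
# occupancy maps (2-cm bins, 8-cm s.d. Gaussian by default), computed from
# speed-masked samples only.

profile_bins <- function(position_cm, L, bin_cm) {
  nbins <- as.integer(round(L / bin_cm))
  stopifnot(abs(nbins * bin_cm - L) < 1e-9)
  pmin(floor(wrap_position(position_cm, L) / bin_cm) + 1L, nbins)
}

# rate map from binned spike counts + occupancy counts (in samples)
rate_map <- function(spike_counts, occ_samples, dt, K) {
  sc <- drop(K %*% spike_counts)
  so <- drop(K %*% occ_samples) * dt
  rate <- ifelse(so > 1e-12, sc / pmax(so, 1e-12), 0)
  attr(rate, "flagged") <- so <= 1e-12
  rate
}

#' Spatial response profile
#'
#' Firing rate over circular position bins: smoothed spike-count map divided
#' by the smoothed occupancy map. Bins with (smoothed) zero occupancy are
#' set to 0 and flagged rather than propagating NaN.
#'
#' @param spike_times Spike times of one neuron (s).
#' @param timeline Session timeline.
#' @param mask Logical sample mask (e.g. [speed_mask()]); `NULL` = all.
#' @param bin_cm Position bin width in cm.
#' @param sd_cm Gaussian smoothing s.d. in cm (0 disables smoothing).
#' @param sample_subset Optional logical/index vector further restricting
#'   samples (e.g. one gain condition).
#' @return Object of class `response_profile`: list with `centers_cm`,
#'   `rate_hz`, `counts`, `occupancy_s`, `bin_cm`, `sd_cm`, `flagged`.
#' @export
spatial_profile <- function(spike_times, timeline, mask = NULL, bin_cm = 2,
                            sd_cm = 8, sample_subset = NULL) {
  L <- attr(timeline, "geometry")$corridor_length
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  if (!is.null(sample_subset)) {
    sel <- rep(FALSE, n)
    sel[sample_subset] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep)) stop("empty sample mask")
  bins <- profile_bins(timeline$position_cm, L, bin_cm)
  nbins <- as.integer(round(L / bin_cm))
  K <- circular_smoother(nbins, sd_cm / bin_cm)
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  idx <- idx[keep[idx]]
  counts <- tabulate(bins[idx], nbins)
  occ <- tabulate(bins[keep], nbins)
  rate <- rate_map(counts, occ, 1 / fs, K)
  structure(list(centers_cm = (seq_len(nbins) - 0.5) * bin_cm,
                 rate_hz = as.numeric(rate), counts = counts,
                 occupancy_s = occ / fs, bin_cm = bin_cm, sd_cm = sd_cm,
                 flagged = attr(rate, "flagged")),
            class = "response_profile")
}

# Circular time-shift null: statfn is applied to shifted spike sample
# indices; shifts are uniform on [min_shift, T - min_shift] in samples.
time_shift_null <- function(spike_idx, n_samples, n_shuffle, min_shift_samples,
                            statfn, seed = 1) {
  if (n_shuffle <= 0) stop("n_shuffle must be positive")
  if (2 * min_shift_samples >= n_samples)
    stop("session too short for the requested minimum shift")
  set.seed(seed)
  shifts <- sample(seq(min_shift_samples, n_samples - min_shift_samples),
                   n_shuffle, replace = TRUE)
  vapply(shifts, function(s) statfn(((spike_idx + s - 1L) %% n_samples) + 1L),
         numeric(1))
}

# shared permutation-threshold convention: significant iff observed strictly
# exceeds the (1 - alpha) null order statistic. The order statistic is taken
# at ceiling((1 - alpha) * (n + 1)) so that, for a continuous exchangeable
# statistic, P(observed > threshold) is alpha exactly.
null_threshold <- function(null_stats, alpha) {
  s <- sort(null_stats)
  s[min(ceiling((1 - alpha) * (length(s) + 1)), length(s))]
}

perm_p <- function(observed, null_stats) {
  (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
}

#' Permutation test for spatial modulation
#'
#' Statistic: maximal amplitude of the response profile, defined as
#' `max(rate) - mean(rate)`. The null circularly shifts the spike train in
#' time by random periods larger than `min_shift_s`, recomputing the profile
#' each time. Significant when the observed amplitude exceeds the
#' `(1 - alpha)` quantile of the null.
#'
#' @inheritParams spatial_profile
#' @param n_shuffle Number of circular shifts.
#' @param min_shift_s Minimum shift in seconds.
#' @param alpha Significance level (default 0.01).
#' @param seed Seed for the shuffle.
#' @return List with `observed`, `p_value`, `significant`, `threshold`.
#' @export
profile_significance <- function(spike_times, timeline, mask = NULL,
                                 n_shuffle = 500, min_shift_s = 5,
                                 alpha = 0.01, bin_cm = 2, sd_cm = 8,
                                 seed = 1) {
  L <- attr(timeline, "geometry")$corridor_length
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  bins <- profile_bins(timeline$position_cm, L, bin_cm)
  nbins <- as.integer(round(L / bin_cm))
  K <- circular_smoother(nbins, sd_cm / bin_cm)
  occ <- tabulate(bins[keep], nbins)
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  statfn <- function(ix) {
    r <- rate_map(tabulate(bins[ix[keep[ix]]], nbins), occ, 1 / fs, K)
    max(r) - mean(r)
  }
  obs <- statfn(idx)
  null <- time_shift_null(idx, n, n_shuffle, round(min_shift_s * fs), statfn,
                          seed)
  thr <- null_threshold(null, alpha)
  list(observed = obs, p_value = perm_p(obs, null),
       significant = obs > thr, threshold = thr)
}

# z-scored circular cross-correlation: correlation of `a` with `b` rotated
# forward by j bins, for j = 0 .. n-1, via FFT.
circ_xcorr <- function(a, b) {
  n <- length(a)
  za <- (a - mean(a)); zb <- (b - mean(b))
  sa <- sqrt(sum(za^2)); sb <- sqrt(sum(zb^2))
  if (sa < 1e-12 || sb < 1e-12) return(rep(NA_real_, n))
  Re(stats::fft(stats::fft(za) * Conj(stats::fft(zb)), inverse = TRUE)) /
    (n * sa * sb)
}

# offsets (cm) corresponding to rotation j = 0..n-1, mapped to (-L/2, L/2]
offsets_cm <- function(nbins, bin_cm) {
  s <- (seq_len(nbins) - 1L) * bin_cm
  L <- nbins * bin_cm
  ifelse(s > L / 2, s - L, s)
}

# argmax with ties broken toward smaller |offset|, then negative offset
best_offset <- function(corr, offs) {
  mx <- max(corr)
  cand <- which(corr >= mx - 1e-12)
  cand <- cand[order(abs(offs[cand]), offs[cand])]
  cand[1]
}

#' Gain-shift estimation between response profiles
#'
#' Finds the circular spatial offset by which the medium-gain profile must be
#' shifted to maximize its Pearson correlation with the profile measured at
#' another gain. Also reports the amplitude-scaling variance decomposition:
#' the fraction of variance in `profile_gain` explained by the (optimally
#' scaled) medium profile, static and after applying the shift.
#'
#' @param profile_gain,profile_medium `response_profile` objects on identical
#'   bins.
#' @return List of class `gain_shift_result`: `shift_cm`, `correlation`,
#'   `alpha_scale`, `var_explained_static`, `var_explained_with_shift`,
#'   `degenerate` (TRUE when a profile is constant).
#' @export
estimate_gain_shift <- function(profile_gain, profile_medium) {
  stopifnot(length(profile_gain$rate_hz) == length(profile_medium$rate_hz),
            isTRUE(all.equal(profile_gain$bin_cm, profile_medium$bin_cm)))
  rg <- profile_gain$rate_hz; rm_ <- profile_medium$rate_hz
  n <- length(rg)
  offs <- offsets_cm(n, profile_gain$bin_cm)
  corr <- circ_xcorr(rg, rm_)
  if (anyNA(corr)) {
    return(structure(list(shift_cm = NA_real_, correlation = NA_real_,
                          alpha_scale = NA_real_,
                          var_explained_static = NA_real_,
                          var_explained_with_shift = NA_real_,
                          degenerate = TRUE), class = "gain_shift_result"))
  }
  j <- best_offset(corr, offs)
  ve <- variance_explained(rg, rm_, offs[j], profile_gain$bin_cm)
  structure(list(shift_cm = offs[j], correlation = corr[j],
                 alpha_scale = ve$alpha,
                 var_explained_static = ve$static,
                 var_explained_with_shift = ve$with_shift,
                 degenerate = FALSE), class = "gain_shift_result")
}

#' Variance explained by an amplitude-scaled (and shifted) reference profile
#'
#' Fits `Rg ~ alpha * Rm` by least squares and evaluates
#' `1 - sum((Rg - alpha*Rm)^2) / sum((Rg - mean(Rg))^2)`, both for the static
#' reference and for the reference circularly shifted by `shift_cm`. The raw
#' residual/total ratio is also returned.
#'
#' @param Rg,Rm Rate vectors on identical circular bins.
#' @param shift_cm Shift applied to `Rm` for the second value.
#' @param bin_cm Bin width in cm.
#' @return List with `alpha`, `static`, `with_shift`, `ratio_static`,
#'   `ratio_with_shift`.
#' @export
variance_explained <- function(Rg, Rm, shift_cm, bin_cm = 2) {
  tot <- sum((Rg - mean(Rg))^2)
  if (tot < 1e-12) stop("zero-variance target profile")
  fit1 <- function(Rref) {
    den <- sum(Rref^2)
    a <- if (den < 1e-12) 0 else sum(Rg * Rref) / den
    list(alpha = a, ratio = sum((Rg - a * Rref)^2) / tot)
  }
  st <- fit1(Rm)
  sh <- fit1(rotate_bins(Rm, as.integer(round(shift_cm / bin_cm))))
  list(alpha = st$alpha, static = 1 - st$ratio, with_shift = 1 - sh$ratio,
       ratio_static = st$ratio, ratio_with_shift = sh$ratio)
}

# Per-trial smoothed count / occupancy matrices for label-permutation tests.
trial_maps <- function(spike_times, timeline, trials, mask, bin_cm, sd_cm) {
  L <- attr(timeline, "geometry")$corridor_length
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  bins <- profile_bins(timeline$position_cm, L, bin_cm)
  nbins <- as.integer(round(L / bin_cm))
  K <- circular_smoother(nbins, sd_cm / bin_cm)
  sample_trial <- attr(trials, "sample_trial")
  if (is.null(sample_trial)) sample_trial <- timeline$trial_id
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  idx <- idx[keep[idx]]
  ids <- trials$trial_id
  C <- matrix(0, nbins, length(ids))
  O <- matrix(0, nbins, length(ids))
  st_keep <- sample_trial[keep]; bin_keep <- bins[keep]
  st_sp <- sample_trial[idx]; bin_sp <- bins[idx]
  for (k in seq_along(ids)) {
    C[, k] <- tabulate(bin_sp[st_sp == ids[k]], nbins)
    O[, k] <- tabulate(bin_keep[st_keep == ids[k]], nbins)
  }
  list(sC = K %*% C, sO = (K %*% O) / fs, nbins = nbins, bin_cm = bin_cm)
}

rate_from_maps <- function(maps, sel) {
  sc <- drop(maps$sC %*% sel)
  so <- drop(maps$sO %*% sel)
  ifelse(so > 1e-12, sc / pmax(so, 1e-12), 0)
}

# Shift statistic for the permutation test. Unlike the reported estimator
# (which stays on the 2-cm grid), the test statistic refines the
# correlation argmax to sub-bin resolution by a parabolic fit; a continuous
# statistic avoids the tie-induced conservativeness of a gridded one.
shift_from_maps <- function(maps, lab_g, offs) {
  rg <- rate_from_maps(maps, lab_g)
  rm_ <- rate_from_maps(maps, !lab_g)
  corr <- circ_xcorr(rg, rm_)
  if (anyNA(corr)) return(NA_real_)
  n <- length(offs)
  bw <- abs(offs[2] - offs[1])
  j <- best_offset(corr, offs)
  jm <- ((j - 2) %% n) + 1L; jp <- (j %% n) + 1L
  den <- corr[jm] - 2 * corr[j] + corr[jp]
  frac <- if (abs(den) < 1e-12) 0 else
    min(max(0.5 * (corr[jm] - corr[jp]) / den, -0.5), 0.5)
  d <- offs[j] + frac * bw
  L <- n * bw
  if (d > L / 2) d - L else d
}

#' Permutation test for a gain-dependent spatial shift
#'
#' The observed shift (test vs. medium gain) is compared against a null built
#' by permuting the per-trial gain labels among the trials of the two
#' conditions and re-estimating the shift. Significant when `|shift|`
#' exceeds the `(1 - alpha)` quantile of the null `|shift|` distribution.
#'
#' @inheritParams spatial_profile
#' @param trials Trial table from [segment_trials()].
#' @param gain Test gain condition.
#' @param medium_gain Reference gain (default 1).
#' @param outcomes Optional outcome table from [classify_trials()]; when
#'   given, only `correct` trials enter the profiles.
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return List with `shift_cm`, `p_value`, `significant`, `threshold`.
#' @export
gain_shift_significance <- function(spike_times, timeline, trials,
                                    gain, medium_gain = 1, mask = NULL,
                                    outcomes = NULL, n_shuffle = 500,
                                    alpha = 0.05, bin_cm = 2, sd_cm = 8,
                                    seed = 1) {
  if (n_shuffle <= 0) stop("n_shuffle must be positive")
  use <- trials$gain %in% c(gain, medium_gain)
  if (!is.null(outcomes))
    use <- use & outcomes$outcome[match(trials$trial_id, outcomes$trial_id)] == "correct"
  if (length(unique(trials$gain[use])) < 2)
    stop("need trials at both gain conditions")
  sub <- trials[use, , drop = FALSE]
  attr(sub, "sample_trial") <- attr(trials, "sample_trial")
  maps <- trial_maps(spike_times, timeline, sub, mask, bin_cm, sd_cm)
  offs <- offsets_cm(maps$nbins, maps$bin_cm)
  lab <- sub$gain == gain
  obs <- shift_from_maps(maps, lab, offs)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) {
    abs(shift_from_maps(maps, sample(lab), offs))
  }, numeric(1))
  null[is.na(null)] <- 0
  thr <- null_threshold(null, alpha)
  list(shift_cm = obs, p_value = perm_p(abs(obs), null),
       significant = is.finite(obs) && abs(obs) > thr, threshold = thr)
}

#' Permutation test for gain-dependent mean-rate changes
#'
#' Statistic: absolute difference in mean firing rate between two gain
#' conditions (masked samples). The null circularly shifts the spike train
#' in time, which moves spikes across conditions while preserving the
#' train's autostructure.
#'
#' @inheritParams gain_shift_significance
#' @param gain_a,gain_b The two gain conditions.
#' @return List with `observed` (Hz), `p_value`, `significant`, `threshold`.
#' @export
rate_change_test <- function(spike_times, timeline, gain_a, gain_b,
                             mask = NULL, n_shuffle = 500, alpha = 0.01,
                             min_shift_s = 5, seed = 1) {
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  in_a <- keep & timeline$gain == gain_a
  in_b <- keep & timeline$gain == gain_b
  ta <- sum(in_a) / fs; tb <- sum(in_b) / fs
  if (ta == 0 || tb == 0) stop("empty gain condition")
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  statfn <- function(ix) abs(sum(in_a[ix]) / ta - sum(in_b[ix]) / tb)
  obs <- statfn(idx)
  null <- time_shift_null(idx, n, n_shuffle, round(min_shift_s * fs), statfn,
                          seed)
  thr <- null_threshold(null, alpha)
  list(observed = obs, p_value = perm_p(obs, null),
       significant = obs > thr, threshold = thr)
}

#' Permutation test for corridor-identity selectivity
#'
#' The 400-cm loop consists of two visually identical semicircular corridors.
#' The statistic is the absolute difference in firing rate between the two
#' corridors at the position of the pooled-profile peak (matching positions
#' 200 cm apart on the loop); the null permutes the per-trial corridor
#' identity.
#'
#' @inheritParams gain_shift_significance
#' @return List with `observed` (Hz), `p_value`, `significant`, `threshold`.
#' @export
corridor_difference_test <- function(spike_times, timeline, trials,
                                     mask = NULL, n_shuffle = 500,
                                     alpha = 0.01, bin_cm = 2, sd_cm = 8,
                                     seed = 1) {
  if (length(unique(trials$corridor_id)) < 2)
    stop("both corridors must be traversed")
  maps <- trial_maps(spike_times, timeline, trials, mask, bin_cm, sd_cm)
  lab <- trials$corridor_id == 0
  statfn <- function(sel) {
    r0 <- rate_from_maps(maps, sel)
    r1 <- rate_from_maps(maps, !sel)
    p <- which.max(r0 + r1)
    abs(r0[p] - r1[p])
  }
  obs <- statfn(lab)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) statfn(sample(lab)),
                 numeric(1))
  thr <- null_threshold(null, alpha)
  list(observed = obs, p_value = perm_p(obs, null),
       significant = obs > thr, threshold = thr)
}

#' Median gain shift by preferred position
#'
#' Groups neurons by the position of their peak response and reports the
#' median spatial shift per position bin, together with each bin center's
#' distance to the nearest landmark — exposing the between-landmark versus
#' at-landmark contrast.
#'
#' @param shifts_cm Per-neuron shifts (cm).
#' @param preferred_cm Per-neuron preferred positions (cm).
#' @param geometry A [track_geometry()].
#' @param n_bins Number of position bins.
#' @return `data.frame(bin_center_cm, median_shift_cm, n,
#'   dist_to_landmark_cm)`.
#' @export
shift_vs_position_summary <- function(shifts_cm, preferred_cm, geometry,
                                      n_bins = 10) {
  if (length(shifts_cm) == 0) stop("no neurons")
  L <- geometry$corridor_length
  bw <- L / n_bins
  b <- pmin(floor(wrap_position(preferred_cm, L) / bw) + 1L, n_bins)
  centers <- (seq_len(n_bins) - 0.5) * bw
  med <- vapply(seq_len(n_bins), function(k) {
    if (any(b == k)) stats::median(shifts_cm[b == k]) else NA_real_
  }, numeric(1))
  nn <- tabulate(b, n_bins)
  dl <- vapply(centers, function(p) {
    min(abs(circular_distance(p, geometry$landmarks, L)))
  }, numeric(1))
  data.frame(bin_center_cm = centers, median_shift_cm = med, n = nn,
             dist_to_landmark_cm = dl)
}
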
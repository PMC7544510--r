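# Theta phase extraction and phase-resolved statistics: modulation index,
# pairwise phase consistency, phase x position profiles, cross-correlogram
# drift and sinusoid fits, layer-stratified permutation tests, circular
# median comparison, and linear-circular correlation.

# FFT band-pass with hard edges; adequate for the synthetic narrowband LFP.
bandpass_fft <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

# local maxima indices with a minimum prominence (in SD units of the trace)
find_peaks <- function(x, prominence_sd = 0.5) {
  n <- length(x)
  if (n < 3) return(integer(0))
  up <- x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]
  pk <- which(up) + 1L
  dn <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  thr <- prominence_sd * stats::sd(x)
  keep <- vapply(pk, function(i) {
    lt <- dn[dn < i]; rt <- dn[dn > i]
    lo <- max(c(if (length(lt)) x[lt[length(lt)]] else min(x),
                if (length(rt)) x[rt[1]] else min(x)))
    (x[i] - lo) >= thr
  }, logical(1))
  pk[keep]
}

#' Discard theta peaks that follow too closely
#'
#' Greedy forward pass keeping a peak only when it occurs at least
#' `min_interval` after the previously retained one.
#'
#' @param peak_times Peak times in seconds (sorted).
#' @param min_interval Minimum inter-peak interval in seconds (default 60 ms).
#' @return Retained peak times.
#' @export
filter_theta_peaks <- function(peak_times, min_interval = 0.06) {
  if (length(peak_times) == 0) return(peak_times)
  keep <- peak_times[1]
  for (t in peak_times[-1]) {
    if (t - keep[length(keep)] >= min_interval) keep <- c(keep, t)
  }
  keep
}

#' Extract instantaneous theta phase from an LFP trace
#'
#' Band-passes the LFP to the theta band, detects peaks (local maxima with a
#' minimum prominence of `prominence_sd` SD), discards peaks arriving less
#' than 60 ms after the previously retained one, and interpolates phase
#' linearly between retained peaks (peaks = 0/360 deg). When CA1 spike data
#' are supplied, a global offset is applied so the CA1 population firing
#' rate peaks at 180 deg.
#'
#' @param lfp `data.frame(time_s, value)`.
#' @param fs LFP sample rate, Hz.
#' @param band Theta band, Hz.
#' @param out_times Times at which to report phase (default: LFP times).
#' @param prominence_sd Peak prominence threshold in SD units.
#' @param min_interval Minimum inter-peak interval, s.
#' @param ca1_spike_times Optional vector of pooled CA1 pyramidal spike times
#'   used for the 180-deg centering.
#' @return List with `phase_deg` (at `out_times`), `cycle_id`, `valid`
#'   (FALSE outside the first/last retained peak), `peaks_s` and
#'   `offset_deg` (the applied centering offset).
#' @export
extract_theta_phase <- function(lfp, fs, band = c(6, 9), out_times = NULL,
                                prominence_sd = 0.5, min_interval = 0.06,
                                ca1_spike_times = NULL) {
  stopifnot(fs > 2 * band[2])
  bp <- bandpass_fft(lfp$value, fs, band)
  pk <- find_peaks(bp, prominence_sd)
  if (length(pk) < 2) stop("no theta peaks detected")
  peaks <- filter_theta_peaks(lfp$time_s[pk], min_interval)
  if (is.null(out_times)) out_times <- lfp$time_s
  ph <- stats::approx(peaks, (seq_along(peaks) - 1L) * 360, xout = out_times,
                      rule = 2)$y
  valid <- out_times >= peaks[1] & out_times <= peaks[length(peaks)]
  cyc <- findInterval(out_times, peaks)
  offset <- 0
  if (!is.null(ca1_spike_times) && length(ca1_spike_times) > 0) {
    sp_ph <- stats::approx(out_times, ph, xout = ca1_spike_times, rule = 2)$y
    prof <- phase_rate_curve(wrap_deg(sp_ph), wrap_deg(ph[valid]))
    offset <- 180 - prof$pref_deg
  }
  list(phase_deg = wrap_deg(ph + offset), cycle_id = cyc, valid = valid,
       peaks_s = peaks, offset_deg = offset)
}

# smoothed rate over 20-deg phase bins from spike phases + occupancy phases
phase_rate_curve <- function(spike_phase_deg, occ_phase_deg, dt = 1,
                             bin_deg = 20, sd_deg = 40) {
  nb <- as.integer(round(360 / bin_deg))
  K <- circular_smoother(nb, sd_deg / bin_deg)
  bsp <- pmin(floor(spike_phase_deg / bin_deg) + 1L, nb)
  boc <- pmin(floor(occ_phase_deg / bin_deg) + 1L, nb)
  occ <- tabulate(boc, nb)
  if (all(occ == 0)) stop("zero phase occupancy")
  rate <- rate_map(tabulate(bsp, nb), occ, dt, K)
  centers <- (seq_len(nb) - 0.5) * bin_deg
  list(centers_deg = centers, rate_hz = as.numeric(rate),
       pref_deg = centers[which.max(rate)])
}

#' Theta-phase firing-rate profile and modulation index
#'
#' Smoothed spike-count over occupancy ratio across 20-deg theta-phase bins
#' (40-deg s.d. circular Gaussian). The modulation index is
#' `(F_max - F_min) / F_mean` across phase bins.
#'
#' @param spike_times Spike times (s).
#' @param timeline Session timeline.
#' @param phase_deg Theta phase per timeline sample.
#' @param mask Logical sample mask.
#' @param bin_deg,sd_deg Phase binning and smoothing (deg).
#' @return Object of class `theta_profile`: `centers_deg`, `rate_hz`,
#'   `index`, `pref_deg`, `F_max`, `F_min`, `F_mean`.
#' @export
theta_rate_profile <- function(spike_times, timeline, phase_deg, mask = NULL,
                               bin_deg = 20, sd_deg = 40) {
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  idx <- idx[keep[idx]]
  if (length(idx) < 1) stop("no spikes in masked samples")
  pr <- phase_rate_curve(phase_deg[idx], phase_deg[keep], dt = 1 / fs,
                         bin_deg = bin_deg, sd_deg = sd_deg)
  r <- pr$rate_hz
  structure(list(centers_deg = pr$centers_deg, rate_hz = r,
                 index = (max(r) - min(r)) / mean(r),
                 pref_deg = pr$pref_deg,
                 F_max = max(r), F_min = min(r), F_mean = mean(r)),
            class = "theta_profile")
}

#' Permutation test for theta modulation of firing rate
#'
#' Same circular time-shift null as [profile_significance()] but with the
#' theta modulation index as the statistic and a 95th-percentile criterion.
#'
#' @inheritParams theta_rate_profile
#' @param n_shuffle,min_shift_s,alpha,seed Permutation parameters.
#' @return List with `observed`, `p_value`, `significant`, `threshold`.
#' @export
theta_significance <- function(spike_times, timeline, phase_deg, mask = NULL,
                               n_shuffle = 500, min_shift_s = 5,
                               alpha = 0.05, bin_deg = 20, sd_deg = 40,
                               seed = 1) {
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    warning("no spikes; not significant")
    return(list(observed = NA_real_, p_value = 1, significant = FALSE,
                threshold = NA_real_))
  }
  nb <- as.integer(round(360 / bin_deg))
  K <- circular_smoother(nb, sd_deg / bin_deg)
  pbin <- pmin(floor(phase_deg / bin_deg) + 1L, nb)
  occ <- tabulate(pbin[keep], nb)
  statfn <- function(ix) {
    ix <- ix[keep[ix]]
    r <- rate_map(tabulate(pbin[ix], nb), occ, 1 / fs, K)
    (max(r) - min(r)) / mean(r)
  }
  obs <- statfn(idx)
  null <- time_shift_null(idx, n, n_shuffle, round(min_shift_s * fs), statfn,
                          seed)
  thr <- null_threshold(null, alpha)
  list(observed = obs, p_value = perm_p(obs, null),
       significant = obs > thr, threshold = thr)
}

#' Pairwise phase consistency
#'
#' Mean cosine of all pairwise phase differences,
#' `2/(N(N-1)) * sum_{i<j} cos(theta_i - theta_j)`, computed in O(N) via the
#' resultant identity (equal to the pairwise sum to numerical precision).
#'
#' @param phase_deg Spike phases in degrees (N >= 2).
#' @return PPC value in `[-1, 1]`.
#' @export
ppc <- function(phase_deg) {
  n <- length(phase_deg)
  if (n < 2) stop("PPC requires at least 2 spikes")
  th <- deg2rad(phase_deg)
  R2 <- sum(cos(th))^2 + sum(sin(th))^2
  (R2 - n) / (n * (n - 1))
}

# ---- phase x position profiles and drift ----------------------------------

pp_counts <- function(pbin, xbin, nphase, npos) {
  matrix(tabulate(pbin + nphase * (xbin - 1L), nphase * npos), nphase, npos)
}

# drift curve (cm per phase bin) from a phase x position rate matrix;
# the cross-correlogram argmax is refined to sub-bin resolution by a
# parabolic fit through the peak and its circular neighbors
drift_from_rate <- function(rate, offs) {
  meanp <- colMeans(rate)
  n <- length(offs)
  bw <- abs(offs[2] - offs[1])
  L <- n * bw
  vapply(seq_len(nrow(rate)), function(i) {
    co <- circ_xcorr(rate[i, ], meanp)
    if (anyNA(co)) return(NA_real_)
    j <- best_offset(co, offs)
    jm <- ((j - 2) %% n) + 1L; jp <- (j %% n) + 1L
    den <- co[jm] - 2 * co[j] + co[jp]
    frac <- if (abs(den) < 1e-12) 0 else
      min(max(0.5 * (co[jm] - co[jp]) / den, -0.5), 0.5)
    d <- offs[j] + frac * bw
    if (d > L / 2) d - L else d
  }, numeric(1))
}

#' Phase-by-position response profile and theta drift curve
#'
#' 2D firing-rate profile over 20-deg x 2-cm bins (40-deg x 8-cm s.d.
#' circular smoothing), the per-phase spatial drift (position of the maximum
#' of the spatial cross-correlogram between each phase's profile and the
#' phase-averaged profile), and the best-fitting sinusoid to the drift
#' curve.
#'
#' @inheritParams theta_rate_profile
#' @param bin_cm,sd_cm Spatial binning/smoothing (cm).
#' @param smooth_phase Smooth along the phase dimension (disabled inside the
#'   significance test).
#' @return Object of class `phase_position_profile`: `rate` (phase x
#'   position matrix), `phase_centers_deg`, `pos_centers_cm`, `drift_cm`,
#'   and `fit` (see [fit_drift_sinusoid()]).
#' @export
phase_position_profile <- function(spike_times, timeline, phase_deg,
                                   mask = NULL, bin_deg = 20, bin_cm = 2,
                                   sd_deg = 40, sd_cm = 8,
                                   smooth_phase = TRUE) {
  L <- attr(timeline, "geometry")$corridor_length
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  nphase <- as.integer(round(360 / bin_deg))
  npos <- as.integer(round(L / bin_cm))
  pbin <- pmin(floor(phase_deg / bin_deg) + 1L, nphase)
  xbin <- profile_bins(timeline$position_cm, L, bin_cm)
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  idx <- idx[keep[idx]]
  if (length(idx) < 1) stop("no spikes in masked samples")
  cnt <- pp_counts(pbin[idx], xbin[idx], nphase, npos)
  occ <- pp_counts(pbin[keep], xbin[keep], nphase, npos) / fs
  Kp <- circular_smoother(nphase, sd_deg / bin_deg)
  Kx <- circular_smoother(npos, sd_cm / bin_cm)
  sm <- function(M) {
    M <- M %*% t(Kx)
    if (smooth_phase) M <- Kp %*% M
    M
  }
  scnt <- sm(cnt); socc <- sm(occ)
  rate <- ifelse(socc > 1e-12, scnt / pmax(socc, 1e-12), 0)
  offs <- offsets_cm(npos, bin_cm)
  drift <- drift_from_rate(rate, offs)
  centers_p <- (seq_len(nphase) - 0.5) * bin_deg
  structure(list(rate = rate, phase_centers_deg = centers_p,
                 pos_centers_cm = (seq_len(npos) - 0.5) * bin_cm,
                 drift_cm = drift,
                 fit = fit_drift_sinusoid(drift, centers_p)),
            class = "phase_position_profile")
}

#' Fit a sinusoid to a drift curve
#'
#' Closed-form least squares of `a*sin(theta) + b*cos(theta) + c`, reported
#' as amplitude `A = sqrt(a^2+b^2)` and offset `phi` such that the fit is
#' `A*sin(theta - phi) + c`; `phi` is the ascending zero-crossing of the
#' sinusoid. A flat curve yields amplitude 0 and an undefined (NA) offset.
#'
#' @param drift_cm Drift values per phase bin (cm); NAs are ignored.
#' @param centers_deg Phase-bin centers (deg), length >= 4 non-NA.
#' @return List with `amplitude_cm`, `offset_deg`, `intercept_cm`,
#'   `degenerate`.
#' @export
fit_drift_sinusoid <- function(drift_cm, centers_deg) {
  ok <- is.finite(drift_cm)
  if (sum(ok) < 4) stop("need at least 4 finite phase bins")
  y <- drift_cm[ok]
  th <- deg2rad(centers_deg[ok])
  if (diff(range(y)) < 1e-12)
    return(list(amplitude_cm = 0, offset_deg = NA_real_,
                intercept_cm = mean(y), degenerate = TRUE))
  X <- cbind(sin(th), cos(th), 1)
  cf <- solve(crossprod(X), crossprod(X, y))
  a <- cf[1]; b <- cf[2]
  list(amplitude_cm = sqrt(a^2 + b^2),
       offset_deg = wrap_deg(rad2deg(atan2(-b, a))),
       intercept_cm = cf[3], degenerate = FALSE)
}

#' Permutation test for theta phase precession
#'
#' Statistic: amplitude of the sinusoid fitted to the drift curve, computed
#' without smoothing along the phase dimension (position smoothing kept).
#' The null permutes the theta phases of the spikes. Significant when the
#' observed amplitude exceeds the `(1 - alpha)` null quantile.
#'
#' @inheritParams phase_position_profile
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return List with `observed` (cm), `p_value`, `significant`, `threshold`.
#' @export
precession_significance <- function(spike_times, timeline, phase_deg,
                                    mask = NULL, n_shuffle = 500,
                                    alpha = 0.05, bin_deg = 20, bin_cm = 2,
                                    sd_cm = 8, seed = 1) {
  if (n_shuffle <= 0) stop("n_shuffle must be positive")
  L <- attr(timeline, "geometry")$corridor_length
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  nphase <- as.integer(round(360 / bin_deg))
  npos <- as.integer(round(L / bin_cm))
  pbin <- pmin(floor(phase_deg / bin_deg) + 1L, nphase)
  xbin <- profile_bins(timeline$position_cm, L, bin_cm)
  idx <- spike_samples(spike_times, timeline)
  idx <- idx[!is.na(idx)]
  idx <- idx[keep[idx]]
  sp_p <- pbin[idx]; sp_x <- xbin[idx]
  if (length(unique(sp_p)) < 2) {
    warning("all spikes in one phase bin; precession undefined")
    return(list(observed = NA_real_, p_value = 1, significant = FALSE,
                threshold = NA_real_))
  }
  occ <- pp_counts(pbin[keep], xbin[keep], nphase, npos) / fs
  Kx <- circular_smoother(npos, sd_cm / bin_cm)
  socc <- occ %*% t(Kx)
  offs <- offsets_cm(npos, bin_cm)
  centers_p <- (seq_len(nphase) - 0.5) * bin_deg
  statfn <- function(pp) {
    scnt <- pp_counts(pp, sp_x, nphase, npos) %*% t(Kx)
    rate <- ifelse(socc > 1e-12, scnt / pmax(socc, 1e-12), 0)
    d <- drift_from_rate(rate, offs)
    if (sum(is.finite(d)) < 4) return(0)
    f <- fit_drift_sinusoid(d, centers_p)
    f$amplitude_cm
  }
  obs <- statfn(sp_p)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) statfn(sample(sp_p)),
                 numeric(1))
  thr <- null_threshold(null, alpha)
  list(observed = obs, p_value = perm_p(obs, null),
       significant = obs > thr, threshold = thr)
}

#' Field extent around the profile peak
#'
#' Contiguous circular region around the peak where the rate stays above
#' half the peak rate; used to select in-field spikes for the
#' linear-circular comparison.
#'
#' @param profile A `response_profile`.
#' @param frac Fraction of peak defining the extent (default 0.5).
#' @return Logical vector over position bins.
#' @export
field_extent <- function(profile, frac = 0.5) {
  r <- profile$rate_hz
  n <- length(r)
  pk <- which.max(r)
  thr <- frac * r[pk]
  inf <- logical(n)
  i <- pk
  while (r[i] >= thr && !inf[i]) { inf[i] <- TRUE; i <- ((i - 2) %% n) + 1 }
  i <- (pk %% n) + 1
  while (r[i] >= thr && !inf[i]) { inf[i] <- TRUE; i <- (i %% n) + 1 }
  inf
}

#' Linear-circular correlation between spike phase and position
#'
#' Circular-linear correlation coefficient between spike theta phases and
#' in-field positions, with significance from a spike-phase permutation
#' null on `|r|`.
#'
#' @param phase_deg Spike phases (deg).
#' @param x Spike positions (same length, >= 10).
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return List with `r`, `p_value`, `significant`, `threshold`.
#' @export
linear_circular_correlation <- function(phase_deg, x, n_shuffle = 500,
                                        alpha = 0.05, seed = 1) {
  n <- length(x)
  stopifnot(length(phase_deg) == n)
  if (n < 10) stop("need at least 10 spikes")
  if (stats::sd(x) < 1e-12) stop("degenerate position spread")
  th <- deg2rad(phase_deg)
  rfun <- function(th) {
    rxc <- stats::cor(x, cos(th)); rxs <- stats::cor(x, sin(th))
    rcs <- stats::cor(cos(th), sin(th))
    sqrt(max((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2), 0))
  }
  obs <- rfun(th)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) rfun(sample(th)), numeric(1))
  thr <- null_threshold(null, alpha)
  list(r = obs, p_value = perm_p(obs, null), significant = obs > thr,
       threshold = thr)
}

# ---- layer-stratified tests -----------------------------------------------

# permute depths within animals, returning the permuted depth vector
permute_depths_within <- function(depth, animal) {
  out <- depth
  for (a in unique(animal)) {
    i <- which(animal == a)
    out[i] <- sample(depth[i])
  }
  out
}

#' Layer-fraction permutation test
#'
#' Pairwise comparison of the fraction of flagged (e.g. theta-modulated)
#' neurons between cortical layers. The null permutes recording depths
#' within animals, guarding against per-animal sampling biases.
#'
#' @param flags Logical per-neuron flags.
#' @param depth_um Recording depths (um).
#' @param animal Animal (or session) identifier per neuron.
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return `data.frame(layer_a, layer_b, frac_a, frac_b, observed, p_value,
#'   significant)`.
#' @export
layer_fraction_test <- function(flags, depth_um, animal = NULL,
                                n_shuffle = 500, alpha = 0.05, seed = 1) {
  if (is.null(animal)) animal <- rep(1L, length(flags))
  layer <- assign_layer(depth_um)
  lv <- intersect(c("L2-4", "L5", "L6"), unique(layer))
  if (length(lv) < 2) stop("need neurons in at least two layers")
  frac <- function(lay) vapply(lv, function(l) mean(flags[lay == l]), numeric(1))
  pairs <- utils::combn(lv, 2)
  statfn <- function(lay) {
    f <- frac(lay)
    abs(f[pairs[1, ]] - f[pairs[2, ]])
  }
  obs <- statfn(layer)
  set.seed(seed)
  null <- t(vapply(seq_len(n_shuffle), function(i) {
    statfn(assign_layer(permute_depths_within(depth_um, animal)))
  }, numeric(ncol(pairs))))
  null <- matrix(null, ncol = ncol(pairs))
  f0 <- frac(layer)
  data.frame(layer_a = pairs[1, ], layer_b = pairs[2, ],
             frac_a = f0[pairs[1, ]], frac_b = f0[pairs[2, ]],
             observed = obs,
             p_value = vapply(seq_along(obs), function(k)
               perm_p(obs[k], null[, k]), numeric(1)),
             significant = vapply(seq_along(obs), function(k)
               obs[k] > null_threshold(null[, k], alpha), logical(1)),
             row.names = NULL)
}

# Fisher-style multi-sample equal-circular-medians statistic (count-based)
common_median_stat <- function(deg, group) {
  M <- circ_median_deg(deg)
  if (is.na(M)) return(NA_real_)
  side <- circular_distance(deg, M, 360) > 0
  N <- length(deg)
  gi <- split(side, group)
  m <- vapply(gi, sum, numeric(1))
  nn <- vapply(gi, length, numeric(1))
  Mtot <- sum(m)
  if (Mtot == 0 || Mtot == N) return(0)
  N^2 / (Mtot * (N - Mtot)) * sum(m^2 / nn) - N * Mtot / (N - Mtot)
}

#' Multi-sample test for equal circular medians
#'
#' Circular analog of the Kruskal-Wallis test: a count-based statistic from
#' how many observations per group fall on each side of the pooled circular
#' median, with the p-value taken from a permutation null (group labels
#' permuted within animals) rather than the asymptotic distribution.
#'
#' @param deg Angles in degrees.
#' @param group Group label per observation (>= 2 groups, each n >= 5).
#' @param animal Optional animal identifier per observation.
#' @param n_shuffle,alpha,seed Permutation parameters.
#' @return List with `statistic`, `p_value`, `significant`, `degenerate`.
#' @export
circular_median_test <- function(deg, group, animal = NULL, n_shuffle = 500,
                                 alpha = 0.05, seed = 1) {
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 5))
    stop("need >= 2 groups with >= 5 observations each")
  if (is.null(animal)) animal <- rep(1L, length(deg))
  obs <- common_median_stat(deg, group)
  if (is.na(obs)) {
    warning("pooled circular median undefined")
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, degenerate = TRUE))
  }
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) {
    g <- group
    for (a in unique(animal)) {
      j <- which(animal == a)
      g[j] <- group[sample(j)]
    }
    s <- common_median_stat(deg, g)
    if (is.na(s)) 0 else s
  }, numeric(1))
  list(statistic = obs, p_value = perm_p(obs, null),
       significant = obs > null_threshold(null, alpha), degenerate = FALSE)
}
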
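# Two-step orthogonalized ridge regression: spike counts are first
# attributed to position (100 x 2-cm indicator bins), then the residual to
# behavioral covariates (speed, acceleration, pupil size/azimuth/elevation,
# licks: 10 quantile bins each; reward: binary), each replicated at 9 lags
# from -1 to +1 s. A delayed-position variant scans response latencies.

#' Build the GLM window table
#'
#' Aligns spike-count windows (250 ms default) to the timeline, carrying the
#' position bin (optionally at a response delay), boxcar-smoothed behavioral
#' covariates sampled at the window center, gain and trial.
#'
#' @param timeline Session timeline.
#' @param mask Speed mask over samples.
#' @param window_s Window length (s).
#' @param bin_cm Position bin width (cm).
#' @param delay_s Response delay: position is read at `t - delay_s`.
#' @return `data.frame` of windows with covariates and `pos_bin`.
#' @export
glm_windows <- function(timeline, mask = NULL, window_s = 0.25, bin_cm = 2,
                        delay_s = 0) {
  fs <- attr(timeline, "sample_rate")
  L <- attr(timeline, "geometry")$corridor_length
  n <- nrow(timeline)
  wlen <- max(1L, round(window_s * fs))
  nW <- floor(n / wlen)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask
  k <- max(1L, round(0.25 * fs))
  smooth_box <- function(x) {
    pad <- c(rep(x[1], k), x, rep(x[length(x)], k))
    as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2)[(k + 1):(k + n)])
  }
  sp <- smooth_box(timeline$speed_cm_s)
  acc <- c(diff(sp) * fs, 0)
  ps <- smooth_box(timeline$pupil_size)
  pa <- smooth_box(timeline$pupil_az)
  pe <- smooth_box(timeline$pupil_el)
  xbin <- profile_bins(timeline$position_cm, L, bin_cm)
  dsamp <- round(delay_s * fs)
  ctr <- (seq_len(nW) - 1L) * wlen + ceiling(wlen / 2)
  ctr_del <- pmax(ctr - dsamp, 1L)
  i0 <- (seq_len(nW) - 1L) * wlen + 1L
  frac_masked <- vapply(seq_len(nW), function(w)
    mean(keep[i0[w]:(i0[w] + wlen - 1L)]), numeric(1))
  lick_ct <- vapply(seq_len(nW), function(w)
    sum(timeline$lick[i0[w]:(i0[w] + wlen - 1L)]), numeric(1))
  rew <- vapply(seq_len(nW), function(w)
    as.numeric(any(timeline$reward[i0[w]:(i0[w] + wlen - 1L)])), numeric(1))
  out <- data.frame(window = seq_len(nW), t_start = timeline$time_s[i0],
                    pos_bin = xbin[ctr_del], pos_bin0 = xbin[ctr],
                    gain = timeline$gain[ctr],
                    trial_id = timeline$trial_id[ctr],
                    speed = sp[ctr], accel = acc[ctr], pupil_size = ps[ctr],
                    pupil_az = pa[ctr], pupil_el = pe[ctr],
                    licks = lick_ct, reward = rew, usable = frac_masked > 0.5)
  attr(out, "window_s") <- window_s
  attr(out, "n_pos_bins") <- as.integer(round(L / bin_cm))
  out
}

#' Spike counts per GLM window
#' @param spike_times Spike times (s).
#' @param windows Window table from [glm_windows()].
#' @return Integer counts per window.
#' @export
glm_spike_counts <- function(spike_times, windows) {
  window_s <- attr(windows, "window_s")
  w <- findInterval(spike_times, windows$t_start)
  sel <- w >= 1 & w <= nrow(windows) &
    spike_times < windows$t_start[pmax(w, 1)] + window_s
  tabulate(w[sel], nrow(windows))
}

#' Position indicator design (step 1)
#' @param windows Window table.
#' @return Windows x 100 one-hot matrix.
#' @export
position_design <- function(windows) {
  nb <- attr(windows, "n_pos_bins")
  X <- matrix(0, nrow(windows), nb)
  X[cbind(seq_len(nrow(windows)), windows$pos_bin)] <- 1
  X
}

quantile_bins <- function(v, edges) {
  pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
       length(edges) - 1L)
}

#' Behavioral indicator design (step 2)
#'
#' Six covariates (speed, acceleration, pupil size/azimuth/elevation, licks)
#' binned into `n_quant` quantile bins (edges from the reference windows)
#' and a binary reward regressor, each replicated at `lags` (seconds,
#' multiples of the window). Degenerate covariates collapse to fewer bins
#' with a warning; the design keeps its full column layout (empty columns
#' stay zero) so the column count is `6 * n_quant * n_lags + n_lags`.
#'
#' @param windows Window table.
#' @param ref_sel Logical: windows whose values define the quantile edges
#'   (typically usable medium-gain windows).
#' @param lags Lag grid in seconds.
#' @param n_quant Number of quantile bins.
#' @return Design matrix with attribute `layout`.
#' @export
behavior_design <- function(windows, ref_sel = NULL,
                            lags = seq(-1, 1, by = 0.25), n_quant = 10) {
  window_s <- attr(windows, "window_s")
  if (is.null(ref_sel)) ref_sel <- rep(TRUE, nrow(windows))
  vars <- c("speed", "accel", "pupil_size", "pupil_az", "pupil_el", "licks")
  W <- nrow(windows)
  nlag <- length(lags)
  X <- matrix(0, W, length(vars) * n_quant * nlag + nlag)
  col <- 0L
  bins <- lapply(vars, function(v) {
    edges <- unique(stats::quantile(windows[[v]][ref_sel],
                                    probs = seq(0, 1, length.out = n_quant + 1),
                                    names = FALSE))
    if (length(edges) < n_quant + 1)
      warning("degenerate covariate '", v, "': ", length(edges) - 1,
              " distinct bins")
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    quantile_bins(windows[[v]], edges)
  })
  for (vi in seq_along(vars)) {
    for (li in seq_len(nlag)) {
      shift <- as.integer(round(lags[li] / window_s))
      src <- seq_len(W) - shift   # value at t - lag
      ok <- src >= 1 & src <= W
      b <- bins[[vi]][src[ok]]
      X[cbind(which(ok), col + b)] <- 1
      col <- col + n_quant
    }
  }
  for (li in seq_len(nlag)) {
    shift <- as.integer(round(lags[li] / window_s))
    src <- seq_len(W) - shift
    ok <- src >= 1 & src <= W
    X[which(ok), col + li] <- windows$reward[src[ok]]
  }
  attr(X, "layout") <- list(vars = vars, n_quant = n_quant, lags = lags)
  X
}

#' Closed-form ridge solution
#'
#' `beta = (X'X + lambda I)^{-1} X'y`.
#'
#' @param X Design matrix.
#' @param y Response.
#' @param lambda Ridge penalty (>= 0).
#' @return Coefficient vector.
#' @export
ridge_solve <- function(X, y, lambda) {
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda
  drop(solve(A, crossprod(X, y)))
}

#' Two-step orthogonalized ridge fit
#'
#' Step 1 regresses mean-centered spike counts on position indicators (ridge,
#' reference-gain windows); step 2 regresses the cross-validated step-1
#' residual on the behavioral design. Reference-gain predictions use
#' `folds`-fold cross-validation over contiguous trial blocks; other gains
#' are predicted from the full reference fit.
#'
#' @param y Spike counts per window (from [glm_spike_counts()]).
#' @param windows Window table.
#' @param X_pos,X_beh Design matrices.
#' @param medium_gain Reference gain.
#' @param lambda_pos,lambda_beh Ridge penalties.
#' @param folds Number of CV folds.
#' @return Object of class `glm_fit`: coefficients, per-window `yhat_pos`,
#'   `yhat_beh`, `yhat` (including the training mean), and bookkeeping.
#' @export
fit_two_step <- function(y, windows, X_pos, X_beh, medium_gain = 1,
                         lambda_pos = 1, lambda_beh = 1, folds = 20) {
  use <- windows$usable
  med <- use & windows$gain == medium_gain
  if (!any(med)) stop("no usable reference-gain windows")
  mu <- mean(y[med])
  yc <- y - mu
  # step 1: position
  b_pos <- ridge_solve(X_pos[med, , drop = FALSE], yc[med], lambda_pos)
  yhat_pos <- drop(X_pos %*% b_pos)
  med_trials <- sort(unique(windows$trial_id[med]))
  nf <- min(folds, length(med_trials))
  fsets <- fold_trials(med_trials, nf)
  fold_id <- rep(NA_integer_, nrow(windows))
  for (fi in seq_along(fsets)) {
    hold <- med & windows$trial_id %in% fsets[[fi]]
    if (!any(hold)) next
    tr <- med & !windows$trial_id %in% fsets[[fi]]
    b <- ridge_solve(X_pos[tr, , drop = FALSE], yc[tr], lambda_pos)
    yhat_pos[hold] <- drop(X_pos[hold, , drop = FALSE] %*% b)
    fold_id[hold] <- fi
  }
  # step 2: behavior on the residual
  resid <- yc - yhat_pos
  b_beh <- ridge_solve(X_beh[med, , drop = FALSE], resid[med], lambda_beh)
  yhat_beh <- drop(X_beh %*% b_beh)
  for (fi in seq_along(fsets)) {
    hold <- med & windows$trial_id %in% fsets[[fi]]
    if (!any(hold)) next
    tr <- med & !windows$trial_id %in% fsets[[fi]]
    b <- ridge_solve(X_beh[tr, , drop = FALSE], resid[tr], lambda_beh)
    yhat_beh[hold] <- drop(X_beh[hold, , drop = FALSE] %*% b)
  }
  structure(list(beta_pos = b_pos, beta_beh = b_beh, mean_y = mu,
                 yhat_pos = yhat_pos, yhat_beh = yhat_beh,
                 yhat = yhat_pos + yhat_beh + mu,
                 fold = fold_id, windows = windows,
                 medium_gain = medium_gain,
                 lambda_pos = lambda_pos, lambda_beh = lambda_beh),
            class = "glm_fit")
}

# rate profile from per-window predicted counts (or any window weights)
profile_from_windows <- function(values, windows, sel, L, bin_cm = 2,
                                 sd_cm = 8) {
  window_s <- attr(windows, "window_s")
  nb <- as.integer(round(L / bin_cm))
  K <- circular_smoother(nb, sd_cm / bin_cm)
  num <- numeric(nb); den <- numeric(nb)
  # profiles are always built against the true (undelayed) position
  b <- (if ("pos_bin0" %in% names(windows)) windows$pos_bin0
        else windows$pos_bin)[sel]
  v <- values[sel]
  for (k in seq_len(nb)) {
    num[k] <- sum(v[b == k])
    den[k] <- sum(b == k) * window_s
  }
  snum <- drop(K %*% num); sden <- drop(K %*% den)
  rate <- ifelse(sden > 1e-12, snum / pmax(sden, 1e-12), 0)
  structure(list(centers_cm = (seq_len(nb) - 0.5) * bin_cm, rate_hz = rate,
                 counts = num, occupancy_s = den, bin_cm = bin_cm,
                 sd_cm = sd_cm, flagged = sden <= 1e-12),
            class = "response_profile")
}

#' Gain shifts predicted by a GLM fit
#'
#' Builds per-gain response profiles from the model prediction (position +
#' behavior components plus the training mean, or a single component) and
#' estimates the spatial shift of each non-reference gain against the
#' reference exactly as for spike-derived profiles.
#'
#' @param fit A `glm_fit`.
#' @param L Corridor length (cm).
#' @param component `"full"`, `"position"`, or `"behavior"`.
#' @param bin_cm,sd_cm Profile binning/smoothing.
#' @return `data.frame(gain, shift_cm, correlation)` (reference gain has
#'   shift 0), with the profiles in `attr(, "profiles")`.
#' @export
predicted_gain_shifts <- function(fit, L, component = c("full", "position",
                                                        "behavior"),
                                  bin_cm = 2, sd_cm = 8) {
  component <- match.arg(component)
  w <- fit$windows
  vals <- switch(component,
                 full = fit$yhat,
                 position = fit$yhat_pos + fit$mean_y,
                 behavior = fit$yhat_beh + fit$mean_y)
  gains <- sort(unique(w$gain[w$usable]))
  profs <- lapply(gains, function(g)
    profile_from_windows(vals, w, w$usable & w$gain == g, L, bin_cm, sd_cm))
  names(profs) <- as.character(gains)
  ref <- profs[[as.character(fit$medium_gain)]]
  res <- lapply(gains, function(g) {
    if (g == fit$medium_gain)
      return(data.frame(gain = g, shift_cm = 0, correlation = 1))
    gs <- estimate_gain_shift(profs[[as.character(g)]], ref)
    data.frame(gain = g, shift_cm = gs$shift_cm, correlation = gs$correlation)
  })
  out <- do.call(rbind, res)
  attr(out, "profiles") <- profs
  out
}

#' Scan response delays in the position model
#'
#' Refits the two-step model with the position design read at `t - delay`
#' for each delay on the grid, and scores each delay by the mean Pearson
#' correlation between the model-predicted and the measured response
#' profiles at the non-reference gains (at the reference gain the two agree
#' for any delay, so only the manipulated gains identify the latency). The
#' optimal delay is the argmax (ties toward the smaller delay).
#'
#' @param y Spike counts per window.
#' @param timeline Session timeline.
#' @param mask Sample mask.
#' @param delays_s Delay grid (s), default 0 to 1 s in 100-ms steps.
#' @param window_s Window length.
#' @param medium_gain Reference gain.
#' @param lambda_pos,lambda_beh,folds Fit parameters.
#' @param lags,n_quant Behavioral design parameters.
#' @return List with `delays_s`, `score` (per delay), `optimal_delay_s`, and
#'   `shifts` (per-delay `data.frame` of predicted gain shifts).
#' @export
fit_delay_models <- function(y, timeline, mask = NULL,
                             delays_s = seq(0, 1, by = 0.1),
                             window_s = 0.25, medium_gain = 1,
                             lambda_pos = 1, lambda_beh = 1, folds = 20,
                             lags = seq(-1, 1, by = 0.25), n_quant = 10) {
  L <- attr(timeline, "geometry")$corridor_length
  score <- numeric(length(delays_s))
  shifts <- vector("list", length(delays_s))
  w0 <- glm_windows(timeline, mask, window_s, delay_s = 0)
  Xb <- behavior_design(w0, ref_sel = w0$usable & w0$gain == medium_gain,
                        lags = lags, n_quant = n_quant)
  gains_other <- setdiff(sort(unique(w0$gain[w0$usable])), medium_gain)
  measured <- lapply(gains_other, function(g)
    profile_from_windows(y, w0, w0$usable & w0$gain == g, L))
  names(measured) <- as.character(gains_other)
  for (di in seq_along(delays_s)) {
    w <- glm_windows(timeline, mask, window_s, delay_s = delays_s[di])
    Xp <- position_design(w)
    fit <- fit_two_step(y, w, Xp, Xb, medium_gain, lambda_pos, lambda_beh,
                        folds)
    ps <- predicted_gain_shifts(fit, L)
    profs <- attr(ps, "profiles")
    score[di] <- mean(vapply(as.character(gains_other), function(g)
      stats::cor(profs[[g]]$rate_hz, measured[[g]]$rate_hz), numeric(1)))
    shifts[[di]] <- cbind(delay_s = delays_s[di], ps)
  }
  best <- which(score >= max(score) - 1e-12)[1]  # ties toward smaller delay
  list(delays_s = delays_s, score = score,
       optimal_delay_s = delays_s[best],
       shifts = do.call(rbind, shifts))
}
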
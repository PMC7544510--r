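# Synthetic virtual-navigation sessions with full ground truth.
#
# The generator emulates a head-fixed mouse running on a wheel through a
# circular 200-cm corridor (two identical semicircular corridors forming a
# 400-cm loop), with per-trial gain coupling wheel displacement to virtual
# displacement, 6-9 Hz theta, and place cells whose anchoring interpolates
# between visual position (w = 0) and wheel distance from the anchoring
# landmark (w = 1): on a gain-g trial the field sits at
# landmark + D * (1 + w*(g - 1)), a visual-coordinate shift of w*(g-1)*D.

SCHEMA_VERSION <- "1.0"

#' Generator configuration
#'
#' Parameters of the synthetic session generator. Defaults follow the task
#' geometry: a 200-cm corridor with landmarks at 0, 83 and 117 cm, a reward
#' zone of +/-12 cm around landmark L1, gains {0.8, 1, 1.2} changed in blocks
#' of 5-10 trials, and a 60-Hz behavioral sample rate.
#'
#' @param corridor_length Corridor length in cm.
#' @param landmarks Landmark center positions in cm.
#' @param reward_halfwidth Reward-zone half width in cm around landmark L1.
#' @param gains Gain values; `gain_probs` gives the per-block sampling
#'   probability of each (defaults put ~36% of trials at non-unity gain).
#' @param gain_probs Block-level sampling probabilities for `gains`.
#' @param gain_block_range Block length range (trials) for gain changes.
#' @param n_trials Number of trials (laps) to simulate.
#' @param sample_rate Behavioral sample rate, Hz.
#' @param lfp_rate LFP sample rate, Hz.
#' @param theta_freq Center theta frequency, Hz.
#' @param theta_band Theta band limits, Hz; instantaneous frequency is kept
#'   inside this band.
#' @param speed_mean,speed_sd,speed_tau Ornstein-Uhlenbeck parameters of the
#'   wheel speed process (cm/s, cm/s, s).
#' @param lick_rate In-zone lick rate, Hz.
#' @param lick_shift_cm Behavioral shift of the licking zone per gain, cm
#'   (same order as `gains`); negative = licks earlier on the virtual track.
#' @param pupil_speed_coupling Coupling of pupil size to running speed.
#' @param error_sd_common,error_sd_independent SD (cm) of the common and the
#'   per-region position-error processes fed to all neurons; 0 disables.
#' @param error_tau Time constant (s) of the position-error processes.
#' @param n_ca1,n_v1 Number of neurons per region.
#' @param seed Master seed.
#' @return Object of class `generator_config` (a named list).
#' @export
generator_config <- function(corridor_length = 200,
                             landmarks = c(0, 83, 117),
                             reward_halfwidth = 12,
                             gains = c(0.8, 1, 1.2),
                             gain_probs = c(0.18, 0.64, 0.18),
                             gain_block_range = c(5, 10),
                             n_trials = 40,
                             sample_rate = 60,
                             lfp_rate = 600,
                             theta_freq = 8,
                             theta_band = c(6, 9),
                             speed_mean = 22,
                             speed_sd = 8,
                             speed_tau = 2,
                             lick_rate = 8,
                             lick_shift_cm = c(-2.4, 0, 2.5),
                             pupil_speed_coupling = 0.3,
                             error_sd_common = 0,
                             error_sd_independent = 0,
                             error_tau = 0.5,
                             n_ca1 = 20,
                             n_v1 = 20,
                             seed = 1) {
  stopifnot(corridor_length > 0,
            all(landmarks >= 0), all(landmarks < corridor_length),
            all(gains > 0), length(gains) >= 1,
            length(gain_probs) == length(gains),
            sample_rate > 0, n_trials > 0,
            gain_block_range[1] >= 1,
            gain_block_range[2] >= gain_block_range[1])
  cfg <- list(corridor_length = corridor_length, landmarks = landmarks,
              reward_halfwidth = reward_halfwidth, gains = gains,
              gain_probs = gain_probs, gain_block_range = gain_block_range,
              n_trials = n_trials, sample_rate = sample_rate,
              lfp_rate = lfp_rate, theta_freq = theta_freq,
              theta_band = theta_band, speed_mean = speed_mean,
              speed_sd = speed_sd, speed_tau = speed_tau,
              lick_rate = lick_rate, lick_shift_cm = lick_shift_cm,
              pupil_speed_coupling = pupil_speed_coupling,
              error_sd_common = error_sd_common,
              error_sd_independent = error_sd_independent,
              error_tau = error_tau,
              n_ca1 = n_ca1, n_v1 = n_v1, seed = seed)
  class(cfg) <- "generator_config"
  cfg
}

# deterministic sub-seed; stays below 2^31
derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)

# Ornstein-Uhlenbeck sample path on a fixed grid
ou_path <- function(n, dt, mean, sd, tau, x0 = mean) {
  x <- numeric(n)
  x[1] <- x0
  if (n == 1L) return(x)
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  eps <- stats::rnorm(n - 1L, 0, innov_sd)
  for (i in 2:n) x[i] <- mean + a * (x[i - 1L] - mean) + eps[i - 1L]
  x
}

# Block schedule of per-trial gains.
gain_schedule <- function(config) {
  g <- numeric(0)
  while (length(g) < config$n_trials) {
    len <- sample(seq(config$gain_block_range[1], config$gain_block_range[2]), 1)
    gi <- sample(seq_along(config$gains), 1, prob = config$gain_probs)
    g <- c(g, rep(config$gains[gi], len))
  }
  g[seq_len(config$n_trials)]
}

#' Generate a behavioral trajectory
#'
#' Simulates wheel running with an Ornstein-Uhlenbeck speed profile, applies
#' the per-trial gain to convert wheel displacement into virtual displacement,
#' and emits licks concentrated in the (gain-shifted) reward-approach zone
#' plus reward delivery on in-zone licks.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param trial_gains Optional explicit per-trial gain vector overriding the
#'   random block schedule (length `n_trials`).
#' @return A `data.frame` timeline (time_s, position_cm, corridor_id,
#'   wheel_cm, speed_cm_s, gain, trial_id, lick, reward, pupil_size,
#'   pupil_az, pupil_el) with the track geometry in `attr(, "geometry")`.
#' @export
generate_trajectory <- function(config, seed = config$seed, trial_gains = NULL) {
  if (config$n_trials <= 0) stop("n_trials must be positive")
  if (length(config$gains) == 0) stop("empty gain list")
  set.seed(derive_seed(seed, 1L))
  L <- config$corridor_length
  dt <- 1 / config$sample_rate
  schedule <- if (is.null(trial_gains)) gain_schedule(config) else {
    stopifnot(length(trial_gains) == config$n_trials)
    trial_gains
  }
  # generous speed horizon, extended on demand
  horizon <- ceiling(config$n_trials * L / (min(config$gains) *
                                              max(config$speed_mean / 2, 5) * dt))
  v <- pmax(ou_path(horizon, dt, config$speed_mean, config$speed_sd,
                    config$speed_tau), 0)

  pos <- numeric(0); trial <- integer(0); used_v <- numeric(0)
  x <- 0; i <- 1L
  for (k in seq_len(config$n_trials)) {
    g <- schedule[k]
    repeat {
      seg <- v[i:length(v)]
      adv <- x + cumsum(g * seg * dt)
      ci <- which(adv >= L)[1]
      if (!is.na(ci)) break
      v <- c(v, pmax(ou_path(horizon, dt, config$speed_mean, config$speed_sd,
                             config$speed_tau, x0 = v[length(v)]), 0))
    }
    pos <- c(pos, c(x, adv[seq_len(ci - 1L)]))
    trial <- c(trial, rep.int(k, ci))
    used_v <- c(used_v, seg[seq_len(ci)])
    x <- adv[ci] - L
    i <- i + ci
  }
  n <- length(pos)
  time <- (seq_len(n) - 1L) * dt
  gain <- schedule[trial]
  wheel <- cumsum(c(0, used_v[-n] * dt))
  corridor <- (trial - 1L) %% 2L

  # licks: high rate while approaching the (behaviorally shifted) reward zone
  shift <- config$lick_shift_cm[match(gain, config$gains)]
  dzone <- circular_distance(pos, wrap_position(shift, L), L)
  in_zone <- dzone > -(config$reward_halfwidth + 6) & dzone < config$reward_halfwidth
  lick_rate <- ifelse(in_zone, config$lick_rate, 0.05)
  lick <- stats::rpois(n, lick_rate * dt)
  # reward: first lick of each trial within the true reward zone
  reward <- logical(n)
  in_rz <- abs(circular_distance(pos, 0, L)) <= config$reward_halfwidth & lick > 0
  for (k in seq_len(config$n_trials)) {
    idx <- which(in_rz & trial == k)
    if (length(idx)) reward[idx[1]] <- TRUE
  }

  pupil_size <- ou_path(n, dt, 0, 1, 1) + config$pupil_speed_coupling *
    (used_v - mean(used_v)) / max(stats::sd(used_v), 1e-9)
  pupil_az <- ou_path(n, dt, 0, 1, 0.8)
  pupil_el <- ou_path(n, dt, 0, 1, 0.8)

  tl <- data.frame(time_s = time, position_cm = pos, corridor_id = corridor,
                   wheel_cm = wheel, speed_cm_s = used_v, gain = gain,
                   trial_id = trial, lick = lick, reward = reward,
                   pupil_size = pupil_size, pupil_az = pupil_az,
                   pupil_el = pupil_el)
  attr(tl, "geometry") <- track_geometry(L, config$landmarks, 0,
                                         config$reward_halfwidth)
  attr(tl, "sample_rate") <- config$sample_rate
  tl
}

#' Generate theta phase and a synthetic LFP
#'
#' Instantaneous theta frequency follows an Ornstein-Uhlenbeck process
#' clipped to the theta band; phase is its integral, and the LFP is a cosine
#' of the phase (peaks at phase 0) plus white noise, sampled at `lfp_rate`.
#'
#' @param config A [generator_config()].
#' @param timeline Timeline from [generate_trajectory()].
#' @param seed Integer seed.
#' @param noise_sd LFP additive noise SD (signal amplitude is 1).
#' @return List with `phase_deg` (per timeline sample, `[0, 360)`),
#'   `lfp` (`data.frame(time_s, value)`), and `freq_hz` on the LFP grid.
#' @export
generate_theta <- function(config, timeline, seed = config$seed, noise_sd = 0.1) {
  set.seed(derive_seed(seed, 2L))
  t_end <- timeline$time_s[nrow(timeline)]
  dt <- 1 / config$lfp_rate
  nf <- ceiling(t_end / dt) + 1L
  tf <- (seq_len(nf) - 1L) * dt
  freq <- ou_path(nf, dt, config$theta_freq, 0.5, 1)
  freq <- pmin(pmax(freq, config$theta_band[1]), config$theta_band[2])
  phase <- cumsum(c(0, 360 * freq[-nf] * dt))
  lfp <- cos(deg2rad(phase)) + stats::rnorm(nf, 0, noise_sd)
  phase_tl <- wrap_deg(stats::approx(tf, phase, xout = timeline$time_s,
                                     rule = 2)$y)
  list(phase_deg = phase_tl,
       lfp = data.frame(time_s = tf, value = lfp),
       freq_hz = freq)
}

#' Draw a population of ground-truth neurons
#'
#' Samples per-neuron generative parameters. CA1 cells are strongly
#' theta-modulated (preferred phases concentrated near 180 deg) and a large
#' fraction precess (phase offset near 180 deg); V1 cells are more weakly
#' and less often modulated, with deep (putative L6) cells preferring ~80 deg
#' and superficial (L2-4) cells ~210 deg, and the rare precessing V1 cells
#' carry the opposite offset regime (270-360 deg).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return `data.frame` with one row per neuron: neuron_id, region, anchor_cm,
#'   anchor_D_cm, field_center_cm, field_width_cm, peak_rate_hz,
#'   baseline_rate_hz, distance_weight, theta_pref_deg, theta_mod_depth,
#'   precession_amp_cm, precession_offset_deg, depth_um, waveform_us.
#' @export
make_neurons <- function(config, seed = config$seed) {
  set.seed(derive_seed(seed, 3L))
  L <- config$corridor_length
  n <- config$n_ca1 + config$n_v1
  region <- rep(c("CA1", "V1"), c(config$n_ca1, config$n_v1))
  lm <- sort(wrap_position(config$landmarks, L))
  gaps <- diff(c(lm, lm[1] + L))
  ai <- sample(seq_along(lm), n, replace = TRUE)
  D <- stats::runif(n, 5, pmax(gaps[ai] - 5, 6))
  center <- wrap_position(lm[ai] + D, L)
  is_ca1 <- region == "CA1"
  w <- ifelse(is_ca1, stats::runif(n, 0, 1), stats::runif(n, 0, 0.5))
  m <- ifelse(is_ca1, stats::runif(n, 0.2, 0.6),
              stats::runif(n, 0, 0.4) * stats::rbinom(n, 1, 0.35))
  pref <- ifelse(is_ca1, wrap_deg(180 + stats::rnorm(n, 0, 40)), NA)
  depth <- ifelse(is_ca1, stats::runif(n, 1100, 1400), stats::runif(n, 150, 950))
  deep <- !is_ca1 & depth >= 700
  pref[!is_ca1] <- wrap_deg(ifelse(deep[!is_ca1], 80, 210) +
                              stats::rnorm(sum(!is_ca1), 0, 40))
  prec <- ifelse(is_ca1, stats::rbinom(n, 1, 0.4), stats::rbinom(n, 1, 0.1))
  A <- prec * ifelse(is_ca1, stats::runif(n, 2, 8), stats::runif(n, 1, 3))
  off <- ifelse(is_ca1, wrap_deg(180 + stats::rnorm(n, 0, 30)),
                stats::runif(n, 270, 360))
  inter <- stats::rbinom(n, 1, ifelse(is_ca1, 0.1, 0.2)) == 1
  width <- ifelse(inter, stats::runif(n, 300, 550), stats::runif(n, 650, 900))
  data.frame(neuron_id = seq_len(n), region = region,
             anchor_cm = lm[ai], anchor_D_cm = D, field_center_cm = center,
             field_width_cm = stats::runif(n, 8, 20),
             peak_rate_hz = stats::runif(n, 4, 12),
             baseline_rate_hz = stats::runif(n, 0.1, 0.5),
             distance_weight = w, theta_pref_deg = pref,
             theta_mod_depth = m, precession_amp_cm = A,
             precession_offset_deg = off, depth_um = depth,
             waveform_us = width, stringsAsFactors = FALSE)
}

# intensity of one neuron on the timeline grid (Hz)
neuron_intensity <- function(nr, timeline, phase_deg, L, pos_err = 0) {
  g <- timeline$gain
  center_g <- nr$anchor_cm + nr$anchor_D_cm * (1 + nr$distance_weight * (g - 1))
  shift <- nr$precession_amp_cm *
    sin(deg2rad(phase_deg - nr$precession_offset_deg))
  d <- circular_distance(timeline$position_cm + pos_err - shift, center_g, L)
  bump <- exp(-d^2 / (2 * nr$field_width_cm^2))
  modf <- if (is.finite(nr$theta_mod_depth) && nr$theta_mod_depth > 0 &&
              is.finite(nr$theta_pref_deg)) {
    1 + nr$theta_mod_depth * cos(deg2rad(phase_deg - nr$theta_pref_deg))
  } else 1
  lam <- (nr$baseline_rate_hz + nr$peak_rate_hz * bump) * modf
  stopifnot(all(lam >= 0))
  lam
}

#' Simulate spike trains by thinning
#'
#' Inhomogeneous-Poisson spikes with intensity
#' `lambda(t) = [b + p * field(x(t) - A sin(theta - theta0))] *
#' (1 + m cos(theta - theta_pref))`, where `field` is a wrapped Gaussian bump
#' and the field center on a gain-g trial is
#' `anchor + D * (1 + w * (g - 1))`. Sampling uses thinning against the
#' analytic bound `(b + p) * (1 + m)`, with the intensity defined by linear
#' interpolation of its values on the timeline grid.
#'
#' @param timeline Timeline from [generate_trajectory()].
#' @param phase_deg Theta phase per timeline sample (deg).
#' @param neurons Ground-truth table from [make_neurons()].
#' @param seed Integer seed.
#' @param position_error Optional named list of per-region position-error
#'   series (cm, one value per timeline sample), e.g.
#'   `list(CA1 = e1, V1 = e2)`; used to inject shared or independent coding
#'   noise for the error-coupling analyses.
#' @return `data.frame(neuron_id, time_s)` of spikes, sorted by neuron/time.
#' @export
simulate_spikes <- function(timeline, phase_deg, neurons, seed = 1,
                            position_error = NULL) {
  stopifnot(nrow(neurons) > 0)
  set.seed(derive_seed(seed, 4L))
  L <- attr(timeline, "geometry")$corridor_length
  t_end <- timeline$time_s[nrow(timeline)]
  out <- vector("list", nrow(neurons))
  for (j in seq_len(nrow(neurons))) {
    nr <- neurons[j, ]
    pe <- if (!is.null(position_error) && nr$region %in% names(position_error))
      position_error[[nr$region]] else 0
    lam <- neuron_intensity(nr, timeline, phase_deg, L, pe)
    m <- if (is.finite(nr$theta_mod_depth)) nr$theta_mod_depth else 0
    lmax <- (nr$baseline_rate_hz + nr$peak_rate_hz) * (1 + m) + 1e-9
    ncand <- stats::rpois(1, lmax * t_end)
    if (ncand == 0) { out[[j]] <- numeric(0); next }
    tc <- sort(stats::runif(ncand, 0, t_end))
    lam_c <- stats::approx(timeline$time_s, lam, xout = tc, rule = 2)$y
    keep <- stats::runif(ncand) < lam_c / lmax
    out[[j]] <- tc[keep]
  }
  data.frame(neuron_id = rep(neurons$neuron_id, lengths(out)),
             time_s = unlist(out))
}

#' Simulate a complete session
#'
#' Orchestrates trajectory, theta, neurons and spikes under one master seed,
#' optionally injecting common and per-region position-error processes.
#'
#' @param config A [generator_config()].
#' @param neurons Optional explicit ground-truth table (else drawn by
#'   [make_neurons()]).
#' @param trial_gains Optional explicit per-trial gains.
#' @return Object of class `vr_session`: list with `timeline`, `theta`
#'   (phase + LFP), `spikes`, `neurons`, `config`, and the injected
#'   `position_error` (NULL when disabled).
#' @export
simulate_session <- function(config, neurons = NULL, trial_gains = NULL) {
  timeline <- generate_trajectory(config, config$seed, trial_gains)
  theta <- generate_theta(config, timeline, config$seed)
  if (is.null(neurons)) neurons <- make_neurons(config, config$seed)
  pe <- NULL
  if (config$error_sd_common > 0 || config$error_sd_independent > 0) {
    set.seed(derive_seed(config$seed, 5L))
    n <- nrow(timeline); dt <- 1 / config$sample_rate
    common <- if (config$error_sd_common > 0)
      ou_path(n, dt, 0, config$error_sd_common, config$error_tau, 0) else 0
    ind <- function() if (config$error_sd_independent > 0)
      ou_path(n, dt, 0, config$error_sd_independent, config$error_tau, 0) else 0
    pe <- list(CA1 = common + ind(), V1 = common + ind())
  }
  spikes <- simulate_spikes(timeline, theta$phase_deg, neurons,
                            seed = config$seed, position_error = pe)
  structure(list(timeline = timeline, theta = theta, spikes = spikes,
                 neurons = neurons, config = config, position_error = pe),
            class = "vr_session")
}

#' @export
print.vr_session <- function(x, ...) {
  cat(sprintf("vr_session: %d samples (%.1f s), %d trials, %d neurons, %d spikes\n",
              nrow(x$timeline), x$timeline$time_s[nrow(x$timeline)],
              max(x$timeline$trial_id), nrow(x$neurons), nrow(x$spikes)))
  invisible(x)
}

# ---- on-disk container -----------------------------------------------------

fmt_table <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(fmt_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write / read a session container
#'
#' A session is stored as a directory of plain TSV tables (`timeline`,
#' `spikes`, `neurons`, `lfp`, `ground_truth` parameters are carried in
#' `neurons`) plus a `meta.json` holding the generator configuration, the
#' per-timeline-sample theta phase and a schema version. Numeric columns are
#' written with 17 significant digits so the round trip is exact.
#'
#' @param session A `vr_session`.
#' @param path Directory to create/fill.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed `vr_session`.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv(session$timeline, file.path(path, "timeline.tsv"))
  write_tsv(session$spikes, file.path(path, "spikes.tsv"))
  write_tsv(session$neurons, file.path(path, "neurons.tsv"))
  lfp <- session$theta$lfp
  lfp$freq_hz <- session$theta$freq_hz
  write_tsv(lfp, file.path(path, "lfp.tsv"))
  ph <- data.frame(phase_deg = session$theta$phase_deg)
  if (!is.null(session$position_error)) {
    ph$err_ca1_cm <- session$position_error$CA1
    ph$err_v1_cm <- session$position_error$V1
  }
  write_tsv(ph, file.path(path, "phase.tsv"))
  meta <- list(schema_version = SCHEMA_VERSION,
               config = unclass(session$config),
               geometry = unclass(attr(session$timeline, "geometry")),
               sample_rate = attr(session$timeline, "sample_rate"),
               has_position_error = !is.null(session$position_error))
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

read_num_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  need <- c("timeline.tsv", "spikes.tsv", "neurons.tsv", "lfp.tsv",
            "phase.tsv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session container is missing: ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION))
    stop("schema version mismatch: found ", meta$schema_version,
         ", expected ", SCHEMA_VERSION)
  timeline <- read_num_tsv(file.path(path, "timeline.tsv"))
  timeline$reward <- as.logical(timeline$reward)
  timeline$gain <- as.numeric(timeline$gain)
  cfg <- meta$config
  class(cfg) <- "generator_config"
  geom <- meta$geometry
  attr(timeline, "geometry") <- track_geometry(as.numeric(geom$corridor_length),
                                               as.numeric(geom$landmarks),
                                               as.numeric(geom$reward_center),
                                               as.numeric(geom$reward_halfwidth))
  attr(timeline, "sample_rate") <- as.numeric(meta$sample_rate)
  spikes <- read_num_tsv(file.path(path, "spikes.tsv"))
  if (nrow(spikes) == 0)
    spikes <- data.frame(neuron_id = integer(0), time_s = numeric(0))
  ph <- read_num_tsv(file.path(path, "phase.tsv"))
  pe <- if (isTRUE(meta$has_position_error))
    list(CA1 = ph$err_ca1_cm, V1 = ph$err_v1_cm) else NULL
  lfp <- read_num_tsv(file.path(path, "lfp.tsv"))
  freq <- lfp$freq_hz
  lfp$freq_hz <- NULL
  structure(list(timeline = timeline,
                 theta = list(phase_deg = ph$phase_deg, lfp = lfp,
                              freq_hz = freq),
                 spikes = spikes,
                 neurons = read_num_tsv(file.path(path, "neurons.tsv")),
                 config = cfg, position_error = pe),
            class = "vr_session")
}
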
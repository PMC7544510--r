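# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# minimal hand-built timeline for direct oracles
mk_timeline <- function(position_cm, fs = 60, L = 200, gain = 1, speed = 20,
                        landmarks = c(0), trial_id = 1L, corridor_id = 0L,
                        lick = 0L, reward = FALSE) {
  n <- length(position_cm)
  if (n == 0) {
    tl <- data.frame(time_s = numeric(0), position_cm = numeric(0),
                     corridor_id = integer(0), wheel_cm = numeric(0),
                     speed_cm_s = numeric(0), gain = numeric(0),
                     trial_id = integer(0), lick = integer(0),
                     reward = logical(0), pupil_size = numeric(0),
                     pupil_az = numeric(0), pupil_el = numeric(0))
    attr(tl, "geometry") <- track_geometry(L, landmarks, 0, 12)
    attr(tl, "sample_rate") <- fs
    return(tl)
  }
  tl <- data.frame(time_s = (seq_len(n) - 1) / fs, position_cm = position_cm,
                   corridor_id = rep(corridor_id, length.out = n),
                   wheel_cm = cumsum(rep(speed / fs, length.out = n)),
                   speed_cm_s = rep(speed, length.out = n),
                   gain = rep(gain, length.out = n),
                   trial_id = rep(trial_id, length.out = n),
                   lick = rep(lick, length.out = n),
                   reward = rep(reward, length.out = n),
                   pupil_size = 0, pupil_az = 0, pupil_el = 0)
  attr(tl, "geometry") <- track_geometry(L, landmarks, 0, 12)
  attr(tl, "sample_rate") <- fs
  tl
}

# ~940-s behavioral session shared by the calibration-style tests; the
# recorded sessions the generator emulates are of this order of duration
# (short sessions leave residual lap-periodic correlation among circular
# time shifts, visibly inflating permutation levels)
calib_traj <- function() {
  if (is.null(.fixtures$calib)) {
    cfg <- generator_config(n_trials = 100, seed = 21)
    tl <- generate_trajectory(cfg)
    th <- generate_theta(cfg, tl)
    .fixtures$calib <- list(cfg = cfg, tl = tl, th = th,
                            mask = speed_mask(tl$speed_cm_s),
                            trials = segment_trials(tl),
                            duration = tl$time_s[nrow(tl)])
  }
  .fixtures$calib
}

# homogeneous Poisson spike train over [0, duration]
null_spikes <- function(duration, rate, seed) {
  set.seed(seed)
  sort(stats::runif(stats::rpois(1, rate * duration), 0, duration))
}

# a response_profile-shaped object from a raw rate vector
mk_profile <- function(rate, bin_cm = 2) {
  structure(list(centers_cm = (seq_along(rate) - 0.5) * bin_cm,
                 rate_hz = rate, counts = rate, occupancy_s = rep(1, length(rate)),
                 bin_cm = bin_cm, sd_cm = 0, flagged = rep(FALSE, length(rate))),
            class = "response_profile")
}

# small decodable session shared by decoder/coupling tests
decode_fixture <- function() {
  if (is.null(.fixtures$decode)) {
    cfg <- generator_config(n_trials = 30, n_ca1 = 16, n_v1 = 0, seed = 33)
    s <- simulate_session(cfg)
    .fixtures$decode <- list(
      s = s, tr = segment_trials(s$timeline),
      mask = speed_mask(s$timeline$speed_cm_s))
  }
  .fixtures$decode
}

# binomial 95% acceptance band for an empirical type-I count
binom_band <- function(n, alpha) {
  c(stats::qbinom(0.025, n, alpha), stats::qbinom(0.975, n, alpha))
}
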
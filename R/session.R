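# Behavioral preprocessing: track geometry, trial segmentation, lick bouts,
# trial outcome classification, cell-type and layer assignment, speed gating.

#' Track geometry
#'
#' @param corridor_length Corridor length in cm.
#' @param landmarks Landmark positions in cm.
#' @param reward_center Reward-zone center in cm (landmark L1).
#' @param reward_halfwidth Reward-zone half width in cm.
#' @return A `track_geometry` list.
#' @export
track_geometry <- function(corridor_length = 200, landmarks = c(0, 83, 117),
                           reward_center = 0, reward_halfwidth = 12) {
  stopifnot(corridor_length > 0, all(landmarks >= 0),
            all(landmarks < corridor_length))
  structure(list(corridor_length = corridor_length, landmarks = landmarks,
                 reward_center = reward_center,
                 reward_halfwidth = reward_halfwidth),
            class = "track_geometry")
}

#' Physical distance run per lap
#'
#' Wheel distance needed to traverse one corridor lap at a given gain:
#' `corridor_length / gain` (e.g. 250 cm at gain 0.8 on a 200-cm corridor).
#'
#' @param corridor_length Corridor length in cm.
#' @param gain Gain (> 0).
#' @return Distance in cm.
#' @export
physical_lap_distance <- function(corridor_length, gain) {
  if (any(gain <= 0)) stop("gain must be positive")
  corridor_length / gain
}

#' Speed gating mask
#'
#' TRUE where run speed exceeds the threshold (strict inequality). All rate
#' and decoding analyses consume only masked samples; lick-position analyses
#' ignore the mask.
#'
#' @param speed Speed series, cm/s.
#' @param threshold Threshold in cm/s (default 5).
#' @return Logical vector.
#' @export
speed_mask <- function(speed, threshold = 5) speed > threshold

#' Estimate run speed from wheel displacement
#'
#' First difference of the cumulative wheel trace divided by the sample step,
#' smoothed with a centered 250-ms boxcar.
#'
#' @param wheel_cm Cumulative wheel distance, cm.
#' @param sample_rate Sampling rate, Hz.
#' @param boxcar_s Boxcar width in seconds.
#' @return Speed in cm/s, same length as input.
#' @export
estimate_speed <- function(wheel_cm, sample_rate, boxcar_s = 0.25) {
  dt <- 1 / sample_rate
  raw <- c(diff(wheel_cm) / dt, NA)
  raw[length(raw)] <- raw[length(raw) - 1L]
  k <- max(1L, round(boxcar_s * sample_rate))
  pad <- c(rep(raw[1], k), raw, rep(raw[length(raw)], k))
  sm <- stats::filter(pad, rep(1 / k, k), sides = 2)
  as.numeric(sm[(k + 1):(k + length(raw))])
}

#' Segment a timeline into trials
#'
#' One trial per corridor traversal, with boundaries where the (unwrapped)
#' position crosses multiples of the corridor length. Brief backward jitter
#' across the boundary does not double-count: a crossing is only accepted
#' after at least `hysteresis_cm` of net forward progress since the previous
#' boundary.
#'
#' @param timeline Session timeline (`data.frame` with `position_cm`, `gain`,
#'   `time_s`, optionally `corridor_id`).
#' @param geometry A [track_geometry()]; defaults to the timeline attribute.
#' @param hysteresis_cm Minimum forward progress between boundaries.
#' @return `data.frame(trial_id, gain, t_start, t_end, corridor_id)`; the
#'   per-sample trial assignment is in `attr(, "sample_trial")`.
#' @export
segment_trials <- function(timeline, geometry = attr(timeline, "geometry"),
                           hysteresis_cm = 50) {
  empty <- data.frame(trial_id = integer(0), gain = numeric(0),
                      t_start = numeric(0), t_end = numeric(0),
                      corridor_id = integer(0))
  if (is.null(timeline) || nrow(timeline) == 0) {
    attr(empty, "sample_trial") <- integer(0)
    return(empty)
  }
  L <- geometry$corridor_length
  inc <- circular_distance(timeline$position_cm[-1],
                           timeline$position_cm[-nrow(timeline)], L)
  u <- cumsum(c(timeline$position_cm[1], inc))
  # Crossings are detected on the unwrapped coordinate, so jitter around a
  # boundary cannot double-count: the next boundary sits a full lap (>= the
  # hysteresis distance) further along.
  stopifnot(hysteresis_cm <= L)
  trial <- integer(nrow(timeline))
  cur <- 1L
  level <- L       # next boundary in unwrapped coordinates
  for (i in seq_along(u)) {
    if (u[i] >= level) {
      cur <- cur + 1L
      level <- level + L
    }
    trial[i] <- cur
  }
  ids <- sort(unique(trial))
  gain <- vapply(ids, function(k) {
    g <- unique(timeline$gain[trial == k])
    if (length(g) > 1) stop("gain not constant within trial ", k)
    g
  }, numeric(1))
  corridor <- if ("corridor_id" %in% names(timeline)) {
    vapply(ids, function(k) {
      as.integer(round(mean(timeline$corridor_id[trial == k])))
    }, integer(1))
  } else (ids - 1L) %% 2L
  out <- data.frame(trial_id = ids, gain = gain,
                    t_start = vapply(ids, function(k) min(timeline$time_s[trial == k]), numeric(1)),
                    t_end = vapply(ids, function(k) max(timeline$time_s[trial == k]), numeric(1)),
                    corridor_id = corridor)
  attr(out, "sample_trial") <- trial
  out
}

#' Extract lick events from a timeline
#'
#' @param timeline Session timeline with `lick` counts per sample.
#' @return `data.frame(time_s, position_cm, trial_id, rewarded)` with one row
#'   per lick (samples with several licks are repeated).
#' @export
lick_events <- function(timeline) {
  idx <- rep(which(timeline$lick > 0), timeline$lick[timeline$lick > 0])
  data.frame(time_s = timeline$time_s[idx],
             position_cm = timeline$position_cm[idx],
             trial_id = timeline$trial_id[idx],
             rewarded = timeline$reward[idx])
}

#' Group licks into bouts
#'
#' Consecutive licks of the same trial separated by less than `max_gap_cm`
#' (circular distance) share a bout; bouts never span trials. A bout is
#' `correct` when it overlaps the reward zone and contains a rewarded lick.
#'
#' @param licks Lick table from [lick_events()].
#' @param geometry A [track_geometry()].
#' @param max_gap_cm Chaining distance in cm (default 20).
#' @return `data.frame(bout_id, trial_id, t_start, position_cm, n_licks,
#'   in_zone, correct)`; `position_cm` is the first-lick position.
#' @export
detect_lick_bouts <- function(licks, geometry, max_gap_cm = 20) {
  if (nrow(licks) == 0)
    return(data.frame(bout_id = integer(0), trial_id = integer(0),
                      t_start = numeric(0), position_cm = numeric(0),
                      n_licks = integer(0), in_zone = logical(0),
                      correct = logical(0)))
  L <- geometry$corridor_length
  o <- order(licks$time_s)
  licks <- licks[o, ]
  n <- nrow(licks)
  new_bout <- c(TRUE, abs(circular_distance(licks$position_cm[-1],
                                            licks$position_cm[-n], L)) >= max_gap_cm |
                  licks$trial_id[-1] != licks$trial_id[-n])
  bout <- cumsum(new_bout)
  ids <- unique(bout)
  in_zone <- function(p) abs(circular_distance(p, geometry$reward_center, L)) <=
    geometry$reward_halfwidth
  res <- lapply(ids, function(b) {
    s <- licks[bout == b, ]
    data.frame(bout_id = b, trial_id = s$trial_id[1], t_start = s$time_s[1],
               position_cm = s$position_cm[1], n_licks = nrow(s),
               in_zone = any(in_zone(s$position_cm)),
               correct = any(in_zone(s$position_cm)) && any(s$rewarded))
  })
  do.call(rbind, res)
}

#' Classify trial outcomes
#'
#' A trial is `correct` when the animal obtained the reward and made at most
#' 5 incorrect licks (licks outside correct bouts); trials with more than 5
#' incorrect licks are `early` when the previous trial was correct and
#' `late` otherwise; unrewarded trials with few licks are `late` (missed).
#' The first trial, lacking a predecessor, treats the previous trial as
#' correct.
#'
#' @param bouts Bout table from [detect_lick_bouts()].
#' @param trials Trial table from [segment_trials()].
#' @return `data.frame(trial_id, rewarded, n_incorrect, outcome)`.
#' @export
classify_trials <- function(bouts, trials) {
  ids <- trials$trial_id
  rewarded <- vapply(ids, function(k) any(bouts$correct[bouts$trial_id == k]),
                     logical(1))
  n_inc <- vapply(ids, function(k) {
    sum(bouts$n_licks[bouts$trial_id == k & !bouts$correct])
  }, numeric(1))
  outcome <- character(length(ids))
  prev_correct <- TRUE
  for (i in seq_along(ids)) {
    outcome[i] <- if (rewarded[i] && n_inc[i] <= 5) "correct"
    else if (n_inc[i] > 5) (if (prev_correct) "early" else "late")
    else "late"
    prev_correct <- outcome[i] == "correct"
  }
  data.frame(trial_id = ids, rewarded = rewarded, n_incorrect = n_inc,
             outcome = outcome)
}

#' Classify cell type from waveform width
#'
#' Putative interneurons have trough-to-peak waveform widths strictly below
#' 600 microseconds; all others are putative pyramidal cells.
#'
#' @param width_us Trough-to-peak width(s) in microseconds.
#' @return Character vector, `"interneuron"` or `"pyramidal"`.
#' @export
classify_cell_type <- function(width_us) {
  if (any(width_us <= 0)) stop("waveform width must be positive")
  ifelse(width_us < 600, "interneuron", "pyramidal")
}

#' Assign putative cortical layer from recording depth
#'
#' Half-open depth bins below the cortical surface: L2-4 = \[250, 500),
#' L5 = \[500, 700), L6 = \[700, 950) micrometers; anything else is `"none"`.
#'
#' @param depth_um Depth(s) in micrometers.
#' @return Character vector in `{"L2-4", "L5", "L6", "none"}`.
#' @export
assign_layer <- function(depth_um) {
  out <- rep("none", length(depth_um))
  out[depth_um >= 250 & depth_um < 500] <- "L2-4"
  out[depth_um >= 500 & depth_um < 700] <- "L5"
  out[depth_um >= 700 & depth_um < 950] <- "L6"
  out
}

#' Spike times of one neuron
#' @param spikes Spike table (`neuron_id`, `time_s`).
#' @param id Neuron id.
#' @return Numeric vector of spike times.
#' @export
spike_times <- function(spikes, id) spikes$time_s[spikes$neuron_id == id]

# Map spike times to the nearest timeline sample (NA outside the session).
# Nearest-sample resampling keeps the timing error symmetric (+/- half a
# sample), avoiding a systematic phase lag at theta frequencies.
spike_samples <- function(times, timeline) {
  fs <- attr(timeline, "sample_rate")
  n <- nrow(timeline)
  idx <- as.integer(round((times - timeline$time_s[1]) * fs)) + 1L
  idx[idx < 1L | idx > n] <- NA_integer_
  idx
}
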
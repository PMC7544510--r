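test_that("trial segmentation finds clean lap boundaries", {
  # 3 monotone laps, 2 cm per sample
  pos <- rep(seq(0, 198, by = 2), 3)
  tl <- mk_timeline(pos)
  tr <- segment_trials(tl)
  expect_equal(nrow(tr), 3)
  st <- attr(tr, "sample_trial")
  expect_equal(unname(table(st)), rep(100, 3), ignore_attr = TRUE)
  # every sample belongs to exactly one trial
  expect_equal(length(st), length(pos))
  expect_false(anyNA(st))
})

test_that("backward jitter across zero yields a single boundary", {
  # manual oracle: one lap end with jitter -> exactly 2 trials, boundary at
  # the first crossing (sample 11 of the fixture)
  pos <- c(180, 185, 190, 195, 198, 1, 197, 2, 199, 3, 6, 10, 15, 20, 30,
           40, 50, 60, 70, 80)
  tl <- mk_timeline(pos)
  tr <- segment_trials(tl)
  expect_equal(nrow(tr), 2)
  st <- attr(tr, "sample_trial")
  expect_equal(which(st == 2)[1], 6)  # first forward crossing of 0
  expect_true(all(diff(st) >= 0))
})

test_that("empty and inconsistent-gain sessions are handled", {
  empty <- segment_trials(mk_timeline(numeric(0)))
  expect_equal(nrow(empty), 0)
  tl <- mk_timeline(rep(seq(0, 198, by = 2), 2))
  tl$gain <- c(rep(1, 50), rep(0.8, 150))  # gain flips inside trial 1
  expect_error(segment_trials(tl), "gain not constant")
})

test_that("lick bouts chain by circular distance within trials", {
  geom <- track_geometry()
  licks <- data.frame(time_s = c(1, 2, 3), position_cm = c(10, 25, 50),
                      trial_id = 1L, rewarded = FALSE)
  b <- detect_lick_bouts(licks, geom)
  expect_equal(nrow(b), 2)                # {10,25} and {50}: 15 < 20 <= 25
  expect_equal(b$position_cm, c(10, 50))  # bout position = first lick
  expect_equal(b$n_licks, c(2, 1))
  # single lick
  b1 <- detect_lick_bouts(licks[1, ], geom)
  expect_equal(nrow(b1), 1)
  # circular wrap: 198 -> 6 is an 8-cm gap, one bout
  lw <- data.frame(time_s = c(1, 2), position_cm = c(198, 6),
                   trial_id = 1L, rewarded = c(FALSE, TRUE))
  bw <- detect_lick_bouts(lw, geom)
  expect_equal(nrow(bw), 1)
  expect_true(bw$correct)  # overlaps reward zone and triggered reward
  # but bouts never span trials
  lw$trial_id <- c(1L, 2L)
  expect_equal(nrow(detect_lick_bouts(lw, geom)), 2)
})

test_that("trial outcomes follow the lick-count rules", {
  trials <- data.frame(trial_id = 1:4, gain = 1, t_start = 0:3,
                       t_end = 1:4, corridor_id = 0L)
  mkbout <- function(trial, n, correct) {
    data.frame(bout_id = 1, trial_id = trial, t_start = 0, position_cm = 0,
               n_licks = n, in_zone = correct, correct = correct)
  }
  # t1 rewarded clean -> correct; t2: 7 incorrect, prev correct -> early;
  # t3: 7 incorrect, prev (t2) not correct -> late; t4: rewarded with
  # exactly 5 incorrect -> correct (boundary case)
  bouts <- rbind(mkbout(1, 3, TRUE),
                 mkbout(2, 7, FALSE),
                 mkbout(3, 7, FALSE),
                 mkbout(4, 5, FALSE), mkbout(4, 2, TRUE))
  out <- classify_trials(bouts, trials)
  expect_equal(out$outcome, c("correct", "early", "late", "correct"))
  expect_equal(out$n_incorrect, c(0, 7, 7, 5))
})

test_that("cell type and layer assignment follow the stated bins", {
  expect_equal(classify_cell_type(c(500, 700, 600, 599.9)),
               c("interneuron", "pyramidal", "pyramidal", "interneuron"))
  expect_error(classify_cell_type(0), "positive")
  expect_equal(assign_layer(c(400, 800, 1000, 250, 500, 700, 949.9, 100)),
               c("L2-4", "L6", "none", "L2-4", "L5", "L6", "L6", "none"))
})

test_that("speed gating is strict and the estimator is consistent", {
  expect_equal(speed_mask(c(10, 10)), c(TRUE, TRUE))
  expect_false(speed_mask(5))
  expect_equal(speed_mask(c(0, 10, 0, 10)), c(FALSE, TRUE, FALSE, TRUE))
  # constant wheel speed recovers that speed
  wheel <- cumsum(rep(20 / 60, 300))
  v <- estimate_speed(wheel, 60)
  expect_equal(mean(v[30:270]), 20, tolerance = 1e-6)
})

test_that("physical lap distance matches the stated gain geometry", {
  expect_equal(physical_lap_distance(200, 0.8), 250)
  expect_equal(physical_lap_distance(200, 1.0), 200)
  expect_equal(physical_lap_distance(200, 1.2), 166.6667, tolerance = 1e-4)
  expect_error(physical_lap_distance(200, 0), "positive")
})
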
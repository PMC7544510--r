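test_that("spatial profile equals the direct count/occupancy ratio", {
  # 3-bin toy (L = 6 cm): occupancy 1/2/1 s, 6 spikes in the middle bin,
  # no smoothing -> rates 0/3/0 Hz (direct division oracle)
  fs <- 60
  pos <- c(rep(1, 60), rep(3, 120), rep(5, 60))
  tl <- mk_timeline(pos, fs = fs, L = 6, landmarks = 0)
  spikes <- 1 + (1:6) / 60  # inside the middle-bin epoch
  p <- spatial_profile(spikes, tl, bin_cm = 2, sd_cm = 0)
  expect_equal(p$rate_hz, c(0, 3, 0))
  expect_equal(p$occupancy_s, c(1, 2, 1))
})

test_that("profiles preserve constants and handle zero spikes", {
  cal <- calib_traj()
  p0 <- spatial_profile(numeric(0), cal$tl, cal$mask)
  expect_equal(p0$rate_hz, rep(0, 100))
  # homogeneous Poisson: profile ~ flat at the true rate
  sp <- null_spikes(cal$duration, 8, seed = 5)
  p <- spatial_profile(sp, cal$tl, cal$mask)
  expect_lt(max(abs(p$rate_hz - 8)) / 8, 0.35)
  expect_lt(abs(mean(p$rate_hz) - 8) / 8, 0.1)
  expect_error(spatial_profile(sp, cal$tl, rep(FALSE, nrow(cal$tl))),
               "empty")
})

test_that("smoothed count map conserves the total spike count", {
  cal <- calib_traj()
  sp <- null_spikes(cal$duration, 5, seed = 6)
  p <- spatial_profile(sp, cal$tl, mask = NULL, sd_cm = 8)
  expect_equal(sum(smooth_circular(p$counts, 4)), sum(p$counts),
               tolerance = 1e-9)
})

test_that("gain-shift estimation inverts circular shifts exactly", {
  set.seed(7)
  base <- smooth_circular(rpois(100, 4) + 3, 3)
  pm <- mk_profile(base)
  expect_equal(estimate_gain_shift(pm, pm)$shift_cm, 0)
  # brute-force oracle over all circular offsets for several shifts
  for (k in c(3, -5, 17, 50, -49)) {
    pg <- mk_profile(rotate_bins(base, k))
    est <- estimate_gain_shift(pg, pm)
    oracle <- sapply(0:99, function(j) cor(pg$rate_hz, rotate_bins(base, j)))
    joracle <- which.max(oracle) - 1
    s_oracle <- if (joracle * 2 > 100) joracle * 2 - 200 else joracle * 2
    expect_equal(est$shift_cm, s_oracle)
    exp_s <- k * 2
    if (exp_s > 100) exp_s <- exp_s - 200
    if (exp_s <= -100) exp_s <- exp_s + 200
    expect_equal(est$shift_cm, exp_s)
    expect_gt(est$correlation, 0.999)
  }
  # constant profile flagged
  expect_true(estimate_gain_shift(mk_profile(rep(2, 100)), pm)$degenerate)
})

test_that("variance explained follows the scaled-residual definition", {
  set.seed(8)
  Rm <- smooth_circular(rpois(100, 5) + 2, 3)
  ve <- variance_explained(2 * Rm, Rm, 0)
  expect_equal(ve$static, 1, tolerance = 1e-12)
  expect_equal(ve$alpha, 2, tolerance = 1e-12)
  # orthogonal zero-mean target -> 0% explained
  Rg <- sin(2 * pi * (1:100) / 100)
  Rm2 <- cos(2 * pi * (1:100) / 100)
  expect_equal(variance_explained(Rg, Rm2, 0)$static, 0, tolerance = 1e-10)
  # shifted copy: with-shift ~ 100%, static below; brute-force SS oracle
  Rg3 <- rotate_bins(Rm, 3)
  ve3 <- variance_explained(Rg3, Rm, 6)
  a <- sum(Rg3 * Rm) / sum(Rm^2)
  ratio_oracle <- sum((Rg3 - a * Rm)^2) / sum((Rg3 - mean(Rg3))^2)
  expect_equal(ve3$static, 1 - ratio_oracle, tolerance = 1e-12)
  expect_equal(ve3$with_shift, 1, tolerance = 1e-10)
  expect_lt(ve3$static, ve3$with_shift)
  expect_error(variance_explained(rep(1, 100), Rm, 0), "zero-variance")
})

test_that("profile permutation test flags a strong place cell", {
  cal <- calib_traj()
  nr <- data.frame(neuron_id = 1, region = "CA1", anchor_cm = 0,
                   anchor_D_cm = 60, field_center_cm = 60,
                   field_width_cm = 10, peak_rate_hz = 10,
                   baseline_rate_hz = 1, distance_weight = 0,
                   theta_pref_deg = 0, theta_mod_depth = 0,
                   precession_amp_cm = 0, precession_offset_deg = 0,
                   depth_um = 1200, waveform_us = 700)
  sp <- simulate_spikes(cal$tl, cal$th$phase_deg, nr, seed = 13)
  res <- profile_significance(sp$time_s, cal$tl, cal$mask, n_shuffle = 100,
                              seed = 2)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.05)
  expect_error(profile_significance(sp$time_s, cal$tl, cal$mask,
                                    n_shuffle = 0), "positive")
  short <- mk_timeline(rep(1, 120))  # 2 s < 2 * min_shift
  expect_error(profile_significance(c(0.5, 1), short, NULL, 10), "short")
})

test_that("rate-change test reacts to a doubled rate and not to silence", {
  cal <- calib_traj()
  tl <- cal$tl
  # spikes at 12 Hz during low gain, 6 Hz otherwise
  lowt <- tl$time_s[tl$gain == 0.8]
  sp <- sort(c(null_spikes(cal$duration, 6, 14),
               lowt[runif(length(lowt)) < 0.1] + 1e-4))
  r <- rate_change_test(sp, tl, 0.8, 1, cal$mask, n_shuffle = 100, seed = 3)
  expect_true(r$significant)
  r0 <- rate_change_test(numeric(0), tl, 0.8, 1, cal$mask, n_shuffle = 50,
                         seed = 3)
  expect_equal(r0$observed, 0)
  expect_false(r0$significant)
  expect_error(rate_change_test(sp, tl, 0.7, 1, cal$mask, 50), "empty")
})

test_that("corridor-identity test flags corridor-selective cells only", {
  cal <- calib_traj()
  tl <- cal$tl; tr <- cal$trials
  st <- attr(tr, "sample_trial")
  in_c0 <- tl$corridor_id == 0
  # corridor-selective: field at 100 cm, doubled peak in corridor 0
  d <- abs(circular_distance(tl$position_cm, 100, 200))
  lam <- (1 + 9 * exp(-d^2 / 50)) * ifelse(in_c0, 2, 1)
  set.seed(15)
  nsp <- rpois(nrow(tl), lam / 60)
  sp <- rep(tl$time_s, nsp)
  r <- corridor_difference_test(sp, tl, tr, cal$mask, n_shuffle = 100,
                                seed = 4)
  expect_true(r$significant)
  # constant-rate neuron: small observed difference
  sp0 <- null_spikes(cal$duration, 5, 16)
  r0 <- corridor_difference_test(sp0, tl, tr, cal$mask, n_shuffle = 100,
                                 seed = 4)
  expect_lt(r0$observed, r$observed)
  tr1 <- tr[tr$corridor_id == 0, ]
  expect_error(corridor_difference_test(sp0, tl, tr1, cal$mask, 50),
               "corridors")
})

test_that("shift-vs-position summary groups by preferred position", {
  geom <- track_geometry()
  s <- shift_vs_position_summary(rep(0, 20), seq(5, 195, length.out = 20),
                                 geom)
  expect_true(all(s$median_shift_cm[s$n > 0] == 0))
  s1 <- shift_vs_position_summary(-7, 55, geom, n_bins = 10)
  expect_equal(s1$median_shift_cm[3], -7)  # 55 cm -> bin 3 of 20-cm bins
  expect_equal(sum(s1$n), 1)
  expect_error(shift_vs_position_summary(numeric(0), numeric(0), geom),
               "no neurons")
})
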
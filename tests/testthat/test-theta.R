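test_that("PPC matches the exhaustive pairwise definition", {
  expect_equal(ppc(rep(37, 10)), 1, tolerance = 1e-12)
  expect_equal(ppc(c(0, 180)), -1, tolerance = 1e-12)
  expect_error(ppc(45), "2 spikes")
  ppc_pairwise <- function(deg) {
    th <- deg * pi / 180
    n <- length(th)
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + cos(th[i]) * cos(th[j]) + sin(th[i]) * sin(th[j])
    2 * s / (n * (n - 1))
  }
  set.seed(20)
  for (n in c(5, 50, 500)) {
    deg <- runif(n, 0, 360)
    expect_equal(ppc(deg), ppc_pairwise(deg), tolerance = 1e-10)
  }
})

test_that("theta index converges to the analytic sinusoid limit", {
  # occupancy uniform in phase; spike density ~ 1 + m cos(theta)
  m <- 0.5
  fs <- 60
  nsamp <- 60000
  set.seed(21)
  phase <- runif(nsamp, 0, 360)
  tl <- mk_timeline(rep(1, nsamp), fs = fs)
  accept <- runif(nsamp) < (1 + m * cos(phase * pi / 180)) / (1 + m)
  idx <- which(accept)[1:5000]
  spikes <- tl$time_s[idx] + 1e-5
  # unsmoothed estimator: index -> 2m (Monte-Carlo tolerance)
  tp0 <- theta_rate_profile(spikes, tl, phase, sd_deg = 0)
  expect_lt(abs(tp0$index - 2 * m), 0.25)
  # smoothed (40-deg s.d.) estimator: attenuated by exp(-sigma^2/2)
  atten <- exp(-(2 * pi * 40 / 360)^2 / 2)
  tp <- theta_rate_profile(spikes, tl, phase)
  expect_lt(abs(tp$index - 2 * m * atten), 0.12)
  # PPC of the same spikes -> (m/2)^2
  expect_lt(abs(ppc(phase[idx]) - (m / 2)^2), 0.02)
})

test_that("drift sinusoid fit is exact on noiseless input", {
  th <- seq(10, 350, by = 20)
  f <- fit_drift_sinusoid(4 * sin((th - 180) * pi / 180), th)
  expect_equal(f$amplitude_cm, 4, tolerance = 1e-10)
  expect_equal(f$offset_deg, 180, tolerance = 1e-8)
  fc <- fit_drift_sinusoid(rep(2, 18), th)
  expect_equal(fc$amplitude_cm, 0)
  expect_true(fc$degenerate)
  expect_error(fit_drift_sinusoid(c(1, 2, 3), c(10, 30, 50)), "4 finite")
  # noisy sinusoid: amplitude within +/-0.5
  set.seed(22)
  fn <- sapply(1:20, function(i)
    fit_drift_sinusoid(3 * sin((th - 90) * pi / 180) + rnorm(18, 0, 0.5),
                       th)$amplitude_cm)
  expect_lt(max(abs(fn - 3)), 0.5 * 3)
  expect_lt(abs(mean(fn) - 3), 0.5)
})

test_that("theta peaks closer than 60 ms are discarded", {
  pk <- c(0, 0.05, 0.125, 0.25, 0.3, 0.31, 0.42)
  kept <- filter_theta_peaks(pk)
  expect_equal(kept, c(0, 0.125, 0.25, 0.31, 0.42))
  expect_equal(filter_theta_peaks(c(1, 1.05)), 1)
})

test_that("phase-position drift recovers injected per-phase shifts", {
  # deterministic fixture: at phase bin p the field sits at 100 + shift(p)
  fs <- 60
  set.seed(23)
  nsamp <- 36000
  pos <- runif(nsamp, 0, 200)
  phase <- runif(nsamp, 0, 360)
  tl <- mk_timeline(pos, fs = fs)
  shift <- 6 * sin((phase - 200) * pi / 180)
  d <- circular_distance(pos, 100 + shift, 200)
  lam <- 0.5 + 12 * exp(-d^2 / (2 * 36))
  accept <- runif(nsamp) < lam / max(lam)
  spikes <- tl$time_s[accept] + 1e-5
  pp <- phase_position_profile(spikes, tl, phase)
  expect_equal(pp$fit$amplitude_cm, 6, tolerance = 0.25)
  expect_lt(abs(circular_distance(pp$fit$offset_deg, 200, 360)), 15)
  # A = 0: drift curve ~ flat
  d0 <- circular_distance(pos, 100, 200)
  lam0 <- 0.5 + 12 * exp(-d0^2 / (2 * 36))
  sp0 <- tl$time_s[runif(nsamp) < lam0 / max(lam0)] + 1e-5
  pp0 <- phase_position_profile(sp0, tl, phase)
  expect_lt(pp0$fit$amplitude_cm, 1)
})

test_that("precession permutation test has power and a degenerate path", {
  cal <- calib_traj()
  nr <- data.frame(neuron_id = 1, region = "CA1", anchor_cm = 0,
                   anchor_D_cm = 60, field_center_cm = 60,
                   field_width_cm = 10, peak_rate_hz = 12,
                   baseline_rate_hz = 0.3, distance_weight = 0,
                   theta_pref_deg = 180, theta_mod_depth = 0.3,
                   precession_amp_cm = 6, precession_offset_deg = 180,
                   depth_um = 1200, waveform_us = 700)
  sp <- simulate_spikes(cal$tl, cal$th$phase_deg, nr, seed = 24)
  r <- precession_significance(sp$time_s, cal$tl, cal$th$phase_deg,
                               cal$mask, n_shuffle = 100, seed = 5)
  expect_true(r$significant)
  # all spikes in one phase bin -> warning, not flagged
  ph1 <- rep(10, nrow(cal$tl))
  expect_warning(
    r1 <- precession_significance(sp$time_s, cal$tl, ph1, cal$mask,
                                  n_shuffle = 10),
    "one phase bin")
  expect_false(r1$significant)
})

test_that("linear-circular correlation separates coupling from noise", {
  set.seed(25)
  x <- runif(200, 40, 80)
  # noiseless linear phase-position relation over half a cycle
  ph <- wrap_deg((x - 40) * 4.5)
  r1 <- linear_circular_correlation(ph, x, n_shuffle = 100, seed = 1)
  expect_gt(r1$r, 0.9)
  expect_true(r1$significant)
  r0 <- linear_circular_correlation(runif(200, 0, 360), x, n_shuffle = 100,
                                    seed = 1)
  expect_lt(r0$r, 0.25)
  expect_error(linear_circular_correlation(ph[1:5], x[1:5]), "10 spikes")
  expect_error(linear_circular_correlation(ph, rep(1, 200)), "degenerate")
})

test_that("field extent is the contiguous half-peak region", {
  rate <- 1 + 9 * exp(-circular_distance((1:100) * 2 - 1, 100, 200)^2 / 200)
  p <- mk_profile(rate)
  ext <- field_extent(p)
  expect_true(ext[50])
  expect_true(all(rate[ext] >= 0.5 * max(rate)))
  # contiguity on the circle: one run of TRUE
  runs <- rle(ext[c(which.min(ext):100, 1:(which.min(ext) - 1))])
  expect_lte(sum(runs$values), 1 + 1)
})

test_that("circular-median test rejects separated groups and not clones", {
  set.seed(26)
  g1 <- wrap_deg(80 + rnorm(100, 0, 30)); g2 <- wrap_deg(210 + rnorm(100, 0, 30))
  r <- circular_median_test(c(g1, g2), rep(c("deep", "sup"), each = 100),
                            n_shuffle = 200, seed = 2)
  expect_true(r$significant)
  expect_gt(r$statistic, 0)
  # identical groups -> statistic exactly 0
  r0 <- circular_median_test(c(g1, g1), rep(c("a", "b"), each = 100),
                             n_shuffle = 50, seed = 2)
  expect_equal(r0$statistic, 0)
  expect_false(r0$significant)
  expect_error(circular_median_test(g1[1:8], rep(c("a", "b"), 4), 50),
               ">= 2 groups")
})

test_that("layer-fraction test detects large differences across layers", {
  set.seed(27)
  n_per <- 120
  depth <- c(runif(n_per, 250, 500), runif(n_per, 700, 950))
  flags <- c(runif(n_per) < 0.05, runif(n_per) < 0.35)
  animal <- rep(rep(1:3, length.out = n_per), 2)
  r <- layer_fraction_test(flags, depth, animal, n_shuffle = 200, seed = 3)
  row <- r[r$layer_a == "L2-4" & r$layer_b == "L6", ]
  expect_true(row$significant)
  expect_error(layer_fraction_test(flags[1:n_per], depth[1:n_per]),
               "two layers")
})
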
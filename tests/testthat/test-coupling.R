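shared_noise_errors <- function(n, sd_common, sd_ind, seed) {
  set.seed(seed)
  common <- rnorm(n, 0, sd_common)
  list(v1 = common + rnorm(n, 0, sd_ind),
       ca1 = common + rnorm(n, 0, sd_ind),
       pos = runif(n, 0, 200), speed = runif(n, 5, 40))
}

test_that("joint error map normalizes and the shuffle preserves marginals", {
  d <- shared_noise_errors(3000, 5, 3, seed = 40)
  jem <- joint_error_map(d$v1, d$ca1, d$pos, d$speed, 200)
  expect_equal(sum(jem$map), 1, tolerance = 1e-9)
  sh <- shuffle_within_bins(jem, n_rep = 20, seed = 1)
  expect_equal(sum(sh$map), 1, tolerance = 1e-9)
  expect_equal(sum(sh$difference), 0, tolerance = 1e-9)
  # shuffling within cells preserves both error marginals
  expect_equal(rowSums(sh$map), rowSums(jem$map), tolerance = 1e-9)
  expect_equal(colSums(sh$map), colSums(jem$map), tolerance = 0.02)
  expect_error(joint_error_map(1, 1, 1, 1, 200), "2 simultaneous")
  expect_error(shuffle_within_bins(jem, n_rep = 0), "positive")
})

test_that("common error components produce a diagonal excess; independent do not", {
  dC <- shared_noise_errors(3000, 5, 3, seed = 41)
  jemC <- joint_error_map(dC$v1, dC$ca1, dC$pos, dC$speed, 200)
  shC <- shuffle_within_bins(jemC, n_rep = 30, seed = 2)
  exC <- diagonal_excess(shC$difference, jemC$centers_cm)
  dI <- shared_noise_errors(3000, 0, sqrt(25 + 9), seed = 42)
  jemI <- joint_error_map(dI$v1, dI$ca1, dI$pos, dI$speed, 200)
  shI <- shuffle_within_bins(jemI, n_rep = 30, seed = 2)
  exI <- diagonal_excess(shI$difference, jemI$centers_cm)
  expect_gt(exC, 0.02)
  expect_lt(abs(exI), 0.02)
  expect_gt(exC, 3 * abs(exI))
})

test_that("mismatch distributions peak at zero for coupled decoders", {
  set.seed(43)
  n <- 2000
  pos <- runif(n, 0, 200); speed <- runif(n, 5, 40)
  # identical decoders: all mass in the zero-mismatch bin
  dec <- wrap_position(pos + rnorm(n, 0, 6), 200)
  mm <- mismatch_distribution(dec, dec, pos, speed, 200, n_rep = 10, seed = 3)
  expect_lte(abs(mm$centers_cm[which.max(mm$measured)]), 2)  # zero-mismatch bin
  # coupled vs independent decoders
  common <- rnorm(n, 0, 8)
  d1 <- wrap_position(pos + common + rnorm(n, 0, 3), 200)
  d2 <- wrap_position(pos + common + rnorm(n, 0, 3), 200)
  mmC <- mismatch_distribution(d1, d2, pos, speed, 200, n_rep = 20, seed = 3)
  i0 <- which.min(abs(mmC$centers_cm))
  expect_gt(mmC$measured[i0], mmC$shuffled[i0])
})

test_that("cycle-by-cycle amplitude coupling is detected against the shuffle", {
  set.seed(44)
  ncyc <- 150; per_cyc <- 5
  n <- ncyc * per_cyc
  cyc <- rep(seq_len(ncyc), each = per_cyc)
  ph <- rep(seq(36, 324, length.out = per_cyc), ncyc) + rnorm(n, 0, 10)
  amp_shared <- rexp(ncyc, 1 / 4)
  mk_err <- function(amp)
    amp[cyc] * sin((ph - 180) * pi / 180) + rnorm(n, 0, 1)
  pos <- runif(n, 0, 200); speed <- runif(n, 5, 40)
  rC <- cycle_modulation_correlation(mk_err(amp_shared), mk_err(amp_shared),
                                     ph, cyc, pos, speed, 200,
                                     n_shuffle = 100, seed = 4)
  expect_true(rC$significant)
  expect_gt(rC$r, 0.5)
  rI <- cycle_modulation_correlation(mk_err(rexp(ncyc, 1 / 4)),
                                     mk_err(rexp(ncyc, 1 / 4)),
                                     ph, cyc, pos, speed, 200,
                                     n_shuffle = 100, seed = 4)
  expect_lt(abs(rI$r), 0.25)
  # constant errors -> degenerate flag
  rD <- cycle_modulation_correlation(rep(1, n), rep(1, n), ph, cyc, pos,
                                     speed, 200, n_shuffle = 10, seed = 4)
  expect_true(rD$degenerate)
  # short cycles are skipped and counted
  cyc2 <- cyc; cyc2[1:2] <- 9999
  r2 <- cycle_modulation_correlation(mk_err(amp_shared), mk_err(amp_shared),
                                     ph, cyc2, pos, speed, 200,
                                     n_shuffle = 20, seed = 4)
  expect_gte(r2$n_skipped, 1)
})

test_that("split-thirds control rejects overlapping or tiny inputs", {
  fx <- decode_fixture()
  tr2 <- fx$tr[fx$tr$trial_id <= 2, ]
  attr(tr2, "sample_trial") <- attr(fx$tr, "sample_trial")
  expect_error(split_thirds_control(fx$s$spikes, fx$s$timeline, tr2,
                                    1:8, 9:16, mask = fx$mask),
               "3 usable trials")
})
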
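toy_model <- function(f, prior = NULL, bin_cm = 2) {
  nb <- ncol(f)
  if (is.null(prior)) prior <- rep(1 / nb, nb)
  structure(list(f = f, neuron_ids = seq_len(nrow(f)), prior = prior,
                 centers_cm = (seq_len(nb) - 0.5) * bin_cm, bin_cm = bin_cm,
                 rate_floor = 0.01), class = "encoding_model")
}

test_that("posterior matches a hand-computed two-position instance", {
  m <- toy_model(matrix(c(1, 10), 1, 2))
  p <- decode_posterior(2, m, 0.25)
  # direct evaluation: P(x) * f^r * exp(-t f)
  l <- c(1^2 * exp(-0.25 * 1), 10^2 * exp(-0.25 * 10))
  expect_equal(p[2], l[2] / sum(l), tolerance = 1e-6)
  expect_equal(p[2], 0.913344, tolerance = 1e-4)
})

test_that("posterior normalizes, respects the prior, and matches the linear domain", {
  set.seed(30)
  f <- matrix(rexp(5 * 20, 1 / 4), 5, 20)
  prior <- rexp(20) + 0.1; prior <- prior / sum(prior)
  m <- toy_model(f, prior)
  cnt <- matrix(rpois(3 * 5, 1), 3, 5)
  p <- decode_posterior(cnt, m, 0.25)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  # linear-domain oracle
  for (w in 1:3) {
    lin <- prior * apply(pmax(f, 0.01)^cnt[w, ], 2, prod) *
      exp(-0.25 * colSums(pmax(f, 0.01)))
    expect_equal(p[w, ], lin / sum(lin), tolerance = 1e-9)
  }
  # zero counts with uniform rates reduce to the prior
  mu <- toy_model(matrix(2, 4, 20), prior)
  p0 <- decode_posterior(rep(0, 4), mu, 0.25)
  expect_equal(drop(p0), prior, tolerance = 1e-9)
})

test_that("session decoding tracks position and refuses small populations", {
  fx <- decode_fixture()
  res <- decode_session(fx$s$spikes, fx$s$timeline, fx$tr,
                        fx$s$neurons$neuron_id, mask = fx$mask,
                        phase_deg = fx$s$theta$phase_deg)
  expect_true(all(abs(res$error_cm) <= 100 + 1e-9))
  expect_lt(median(abs(res$error_cm)), 12)
  # cross-validated reference windows carry fold ids
  expect_false(anyNA(res$fold[res$gain == 1]))
  expect_error(decode_session(fx$s$spikes, fx$s$timeline, fx$tr,
                              1:5, mask = fx$mask), "fewer than 10")
})

test_that("destroying the cell-position code pushes errors to chance", {
  fx <- decode_fixture()
  res <- decode_session(fx$s$spikes, fx$s$timeline, fx$tr,
                        fx$s$neurons$neuron_id, mask = fx$mask)
  model <- attr(res, "model")
  set.seed(31)
  shuf <- model
  shuf$f <- model$f[sample(nrow(model$f)), ]
  w <- res[res$gain == 1, ]
  cnt <- vrplace:::window_counts(fx$s$spikes, model$neuron_ids, w, 0.25)
  post <- decode_posterior(cnt, shuf, 0.25)
  dec <- shuf$centers_cm[max.col(post, ties.method = "first")]
  err <- circular_distance(dec, w$actual_cm, 200)
  expect_gt(median(abs(err)), 15)  # toward chance (L/4 = 50) from ~6 cm
  expect_gt(median(abs(err)), 3 * median(abs(res$error_cm)))
})

test_that("decoded-position distribution is column-normalized", {
  fx <- decode_fixture()
  res <- decode_session(fx$s$spikes, fx$s$timeline, fx$tr,
                        fx$s$neurons$neuron_id, mask = fx$mask)
  J <- decoded_distribution(res)
  cs <- colSums(J)
  ok <- !attr(J, "unvisited")
  expect_equal(unname(cs[ok]), rep(1, sum(ok)), tolerance = 1e-9)
  # mass concentrates near the diagonal for a working decoder
  nb <- nrow(J)
  diag_mass <- mean(sapply(which(ok), function(j) {
    band <- abs(circular_distance(attr(J, "centers_cm"),
                                  attr(J, "centers_cm")[j], 200)) <= 10
    sum(J[band, j])
  }))
  expect_gt(diag_mass, 0.5)
})

test_that("jackknife SE vanishes for duplicated folds", {
  # two identical folds of windows -> leave-one-out estimates identical
  w <- data.frame(window = 1:200, i_start = 1, i_end = 1, t_start = 0,
                  t_mid = 0, actual_cm = rep(seq(1, 199, by = 2), 2),
                  gain = 1, trial_id = rep(1:2, each = 100),
                  speed_cm_s = 20, phase_deg = 0,
                  decoded_cm = rep(seq(1, 199, by = 2), 2))
  w$error_cm <- circular_distance(w$decoded_cm, w$actual_cm, 200)
  w$fold <- rep(1:2, each = 100)
  attr(w, "L") <- 200
  class(w) <- c("decoding_result", "data.frame")
  es <- error_summaries(w)
  expect_equal(max(es[["1"]]$se_mean, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(max(es[["1"]]$se_bias, na.rm = TRUE), 0, tolerance = 1e-9)
  # zero errors land in the bin covering 0: summaries within half a bin
  expect_lt(max(abs(es[["1"]]$mean_error_cm), na.rm = TRUE), 1.01)
  expect_lt(max(abs(es[["1"]]$bias_cm), na.rm = TRUE), 1.01)
})

test_that("phase-resolved error modulation recovers an injected sinusoid", {
  set.seed(32)
  n <- 4000
  ph <- runif(n, 0, 360)
  err <- 5 * sin((ph - 90) * pi / 180) + rnorm(n, 0, 4)
  r <- phase_error_modulation(err, ph, 200, n_shuffle = 100, seed = 6)
  # smoothing attenuates the sinusoid by a known factor
  atten <- exp(-(2 * pi * 40 / 360)^2 / 2)
  expect_lt(abs(r$amplitude_cm - 5 * atten), 1.5)
  expect_lt(abs(circular_distance(r$offset_deg, 90, 360)), 25)
  expect_true(r$significant)
  # constant error -> amplitude 0
  r0 <- phase_error_modulation(rep(2, n), ph, 200, n_shuffle = 50, seed = 6)
  expect_equal(r0$amplitude_cm, 0, tolerance = 1e-9)
  expect_false(r0$significant)
})

test_that("licks mapped through a perfect decoder reduce to true positions", {
  fx <- decode_fixture()
  res <- decode_session(fx$s$spikes, fx$s$timeline, fx$tr,
                        fx$s$neurons$neuron_id, mask = fx$mask)
  res$decoded_cm <- res$actual_cm  # perfect decoder
  licks <- lick_events(fx$s$timeline)
  out <- licks_in_decoded_coordinates(licks, res)
  w <- findInterval(licks$time_s, res$t_start)
  inw <- w >= 1 & w <= nrow(res) & licks$time_s < res$t_start[pmax(w, 1)] + 0.25
  expect_equal(out$n_dropped, sum(!inw))
  # decoded-coordinate mean ~ window-quantized true lick position
  g1 <- res$gain[w[inw]] == 1
  true_mean <- circ_mean_pos(res$actual_cm[w[inw]][g1], 200)
  expect_lt(abs(circular_distance(out$mean_cm[["1"]], true_mean, 200)), 1e-9)
  # no licks -> empty output
  out0 <- licks_in_decoded_coordinates(licks[0, ], res)
  expect_equal(out0$n_dropped, 0)
  expect_null(out0$density)
})
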
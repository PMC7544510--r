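glm_fixture <- function() {
  if (is.null(.fixtures$glm)) {
    cfg <- generator_config(n_trials = 45, seed = 50)
    tl <- generate_trajectory(cfg, trial_gains = rep(c(0.8, 1, 1), 15))
    mask <- speed_mask(tl$speed_cm_s)
    w <- suppressWarnings(glm_windows(tl, mask))
    Xp <- position_design(w)
    Xb <- suppressWarnings(behavior_design(w, ref_sel = w$usable & w$gain == 1))
    .fixtures$glm <- list(tl = tl, mask = mask, w = w, Xp = Xp, Xb = Xb)
  }
  .fixtures$glm
}

test_that("design dimensions follow the stated layout", {
  fx <- glm_fixture()
  expect_equal(ncol(fx$Xp), 100)
  expect_equal(ncol(fx$Xb), 6 * 10 * 9 + 9)  # 549
  lay <- attr(fx$Xb, "layout")
  expect_equal(length(lay$lags), 9)
  expect_equal(lay$lags, seq(-1, 1, by = 0.25))
  # default delay grid has 11 values
  expect_equal(length(seq(0, 1, by = 0.1)), 11)
  # one-hot rows: each position row sums to 1
  expect_true(all(rowSums(fx$Xp) == 1))
})

test_that("quantile binning splits 100 distinct values into tens", {
  fx <- glm_fixture()
  w <- fx$w[1:100, ]
  attr(w, "window_s") <- attr(fx$w, "window_s")
  attr(w, "n_pos_bins") <- attr(fx$w, "n_pos_bins")
  w$speed <- sample(1:100)
  Xb <- suppressWarnings(behavior_design(w, ref_sel = rep(TRUE, 100),
                                         lags = 0, n_quant = 10))
  # speed block at lag 0 = first 10 columns; each bin holds 10 windows
  expect_equal(unname(colSums(Xb[, 1:10])), rep(10, 10))
})

test_that("ridge solution matches an independent SVD route", {
  set.seed(51)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rnorm(50)
  for (lam in c(0, 0.5, 3)) {
    b <- ridge_solve(X, y, lam)
    sv <- svd(X)
    b_svd <- sv$v %*% ((sv$d / (sv$d^2 + lam)) * crossprod(sv$u, y))
    expect_equal(b, drop(b_svd), tolerance = 1e-9)
  }
  # shrinkage: prediction norm decreases monotonically in lambda
  norms <- sapply(c(0, 1, 10, 100, 1e4), function(l)
    sum((X %*% ridge_solve(X, y, l))^2))
  expect_true(all(diff(norms) < 0))
})

test_that("two-step fit is orthogonal for position-only responses", {
  fx <- glm_fixture()
  # rate purely positional
  lam <- 1 + 10 * exp(-circular_distance((fx$w$pos_bin0 - 0.5) * 2, 80,
                                         200)^2 / (2 * 64))
  set.seed(52)
  y <- rpois(nrow(fx$w), lam * 0.25)
  fit <- fit_two_step(y, fx$w, fx$Xp, fx$Xb, lambda_pos = 0.01,
                      lambda_beh = 0.01)
  # the behavioral component stays uncorrelated with the positional one
  u <- fx$w$usable
  expect_lt(abs(cor(fit$yhat_beh[u], fit$yhat_pos[u])), 0.1)
  # y = 0 -> all coefficients 0
  fit0 <- fit_two_step(rep(0, nrow(fx$w)), fx$w, fx$Xp, fx$Xb)
  expect_equal(max(abs(fit0$beta_pos)), 0)
  expect_equal(max(abs(fit0$beta_beh)), 0)
  expect_equal(max(abs(fit0$yhat)), 0)
})

test_that("cross-validated medium predictions exclude their own fold", {
  fx <- glm_fixture()
  set.seed(53)
  y <- rpois(nrow(fx$w), 1 + fx$w$speed / 20)
  fit <- fit_two_step(y, fx$w, fx$Xp, fx$Xb, folds = 3)
  med <- fx$w$usable & fx$w$gain == 1
  expect_false(anyNA(fit$fold[med]))
  # manual oracle for fold 1 of the position step
  f1 <- med & fit$fold == 1
  tr <- med & fit$fold != 1
  mu <- mean(y[med])
  b1 <- ridge_solve(fx$Xp[tr, ], y[tr] - mu, 1)
  expect_equal(fit$yhat_pos[f1], drop(fx$Xp[f1, ] %*% b1), tolerance = 1e-9)
  # folds partition medium trials contiguously
  tf <- unique(data.frame(t = fx$w$trial_id[med], f = fit$fold[med]))
  expect_true(all(tapply(tf$t, tf$f, function(x) all(diff(sort(x)) >= 1))))
  expect_equal(anyDuplicated(tf$t), 0)
})

test_that("predicted profiles reproduce a positional gain shift", {
  fx <- glm_fixture()
  # neuron with a genuine distance-anchored shift: center moves -10 cm at 0.8
  ctr <- ifelse(fx$w$gain == 0.8, 90, 100)
  lam <- 0.5 + 12 * exp(-circular_distance((fx$w$pos_bin0 - 0.5) * 2, ctr,
                                           200)^2 / (2 * 64))
  set.seed(54)
  y <- rpois(nrow(fx$w), lam * 0.25)
  fit <- fit_two_step(y, fx$w, fx$Xp, fx$Xb)
  ps <- predicted_gain_shifts(fit, 200)
  # position model cannot produce a gain shift: prediction is gain-blind
  expect_equal(ps$shift_cm[ps$gain == 0.8], 0, tolerance = 2)
  # flat cell -> shift 0
  yf <- rep(2, nrow(fx$w))
  fitf <- fit_two_step(yf, fx$w, fx$Xp, fx$Xb)
  psf <- predicted_gain_shifts(fitf, 200)
  expect_true(psf$shift_cm[psf$gain == 0.8] == 0 ||
                is.na(psf$shift_cm[psf$gain == 0.8]))
})
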
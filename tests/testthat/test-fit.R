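test_that("noiseless series are recovered essentially exactly", {
  t <- c(0, 1800, 3600, 7200, 14400, 28800)
  for (k in c(1e-5, 1e-4, 1e-3)) {
    f <- fit_koff(noiseless_series(k, t), n_boot = 0)
    expect_lt(abs(coef(f)[["k_off"]] / k - 1), 1e-8)
    expect_true(f$converged)
    expect_lt(f$rss, 1e-15)
  }
})

test_that("a single informative point reproduces the slow-complex anchor", {
  # R = 0.14 at 8 h is the slow-complex benchmark behavior; with only the
  # t = 0 anchor alongside it, least squares reduces to single-point
  # inversion, giving ~1e-5 s^-1
  ser <- data.frame(t = c(0, hours(8)), R = c(0, 0.14))
  f <- fit_koff(ser, n_boot = 0)
  expect_equal(coef(f)[["k_off"]], invert_ratio(0.14, hours(8)),
               tolerance = 1e-6)
  expect_equal(coef(f)[["k_off"]], 1e-5, tolerance = 0.05)
})

test_that("fit is invariant to point order and to weight-halved duplication", {
  ser <- sample_series(1e-4, default_design(1e-5, 1e-3, 9),
                       noise_model(cv = 0.1, seed = 21))
  f1 <- fit_koff(ser, n_boot = 0)
  f2 <- fit_koff(ser[sample(nrow(ser)), ], n_boot = 0)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)

  # duplicating one point while doubling its variance (weight halved on
  # both copies) leaves the weighted objective, hence the fit, unchanged
  ser$sigma <- 0.05
  i <- 5
  dup <- ser[c(seq_len(nrow(ser)), i), ]
  dup$sigma[c(i, nrow(dup))] <- ser$sigma[i] * sqrt(2)
  fw1 <- fit_koff(ser, weighted = TRUE, n_boot = 0)
  fw2 <- fit_koff(dup, weighted = TRUE, n_boot = 0)
  expect_equal(coef(fw1), coef(fw2), tolerance = 1e-10)
})

test_that("polished optimum never regresses behind the initialization grid", {
  set.seed(13)
  for (i in 1:20) {
    k <- 10^runif(1, -5.5, -2.5)
    ser <- sample_series(k, default_design(k / 5, k * 5, 7),
                         noise_model(cv = 0.3, seed = i))
    f <- fit_koff(ser, n_boot = 0)
    obj <- function(l10k)
      sum((f$data$R - exchange_ratio(10^l10k, f$data$t))^2)
    grid_best <- min(vapply(seq(-8, -1, length.out = 21), obj, numeric(1)))
    expect_lte(obj(log10(coef(f)[["k_off"]])), grid_best + 1e-15)
  }
})

test_that("bootstrap interval brackets the estimate and is seed-stable", {
  ser <- sample_series(1e-4, default_design(1e-5, 1e-3, 9),
                       noise_model(cv = 0.1, seed = 5))
  f <- fit_koff(ser, n_boot = 200, seed = 9)
  expect_lte(f$ci_low, f$k_off_hat)
  expect_gte(f$ci_high, f$k_off_hat)
  g <- fit_koff(ser, n_boot = 200, seed = 9)
  expect_identical(coef(f), coef(g))
  expect_identical(f$boot, g$boot)
  ci <- confint(f)
  expect_equal(unname(ci[1, ]), c(f$ci_low, f$ci_high))
})

test_that("ratios at or above 1 are retained by the fit but rejected by inversion", {
  ser <- data.frame(t = c(0, 600, 1200, 2400, 4800),
                    R = c(0, 0.45, 0.78, 0.97, 1.04))
  f <- fit_koff(ser, n_boot = 0)
  expect_true(f$converged)
  expect_equal(f$n_used, 5)
  expect_error(invert_ratio(1.04, 4800), "equilibrium")
})

test_that("censored points are excluded with a message; degenerate input errors", {
  ser <- sample_series(1e-5, c(0, 300, 600, 7200, 28800),
                       noise_model(cv = 0.1, floor = 0.02, seed = 3))
  expect_message(f <- fit_koff(ser, n_boot = 0), "censored")
  expect_equal(f$n_used + f$n_censored, nrow(ser))

  expect_error(fit_koff(data.frame(t = 1, R = 0.1)), "at least 2")
  expect_error(fit_koff(data.frame(t = c(0, 0), R = c(0, 0))), "at least 2")
})

test_that("all-zero series yields a flagged detection upper bound", {
  ser <- data.frame(t = c(0, 3600, 7200, 28800), R = 0)
  expect_warning(f <- fit_koff(ser, n_boot = 0, detect_floor = 0.01),
                 "upper bound")
  expect_false(f$converged)
  expect_equal(f$k_off_hat, invert_ratio(0.01, 28800), tolerance = 1e-12)
  expect_error(predict(f), "non-converged")
})

test_that("prediction and its band behave like the model", {
  ser <- sample_series(1e-3, default_design(1e-4, 1e-2, 9, horizon = 7200),
                       noise_model(cv = 0.1, seed = 12))
  f <- fit_koff(ser, n_boot = 200, seed = 2)
  tg <- seq(0, hours(2), length.out = 25)
  p <- predict(f, t = tg)
  expect_identical(p$R[1], 0)
  expect_gte(p$R[25], 0.99)             # fast complex equilibrates in 2 h
  expect_true(all(p$lwr <= p$R & p$R <= p$upr))
  expect_true(all(diff(p$R) > 0))
})

test_that("fit object supports the standard modelling verbs", {
  ser <- sample_series(1e-4, default_design(1e-5, 1e-3, 9),
                       noise_model(cv = 0.1, seed = 31))
  f <- fit_koff(ser, n_boot = 100, seed = 3)
  expect_s3_class(f, "mase_fit")
  expect_named(coef(f), "k_off")
  expect_equal(nobs(f), 9)
  expect_length(residuals(f), 9)
  expect_equal(fitted(f) + residuals(f), f$data$R)
  expect_output(print(f), "k_off")
  expect_output(print(summary(f)), "half-exchange")
  sims <- simulate(f, nsim = 3, seed = 4)
  expect_length(sims, 3)
  expect_true(all(vapply(sims, function(s) all(s$R >= 0), logical(1))))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
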
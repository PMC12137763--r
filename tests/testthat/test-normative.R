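test_that("polynomial trends interpolate exact data", {
  ga <- seq(20, 40, length.out = 30)
  expect_equal(fit_trend(ga, 100 - 2 * ga, "linear"), c(100, -2),
               tolerance = 1e-10)
  expect_equal(fit_trend(ga, 300 - 5 * ga + 0.05 * ga^2, "quadratic"),
               c(300, -5, 0.05), tolerance = 1e-8)
})

test_that("trend fitting recovers a noisy slope within 3 standard errors", {
  set.seed(11)
  n <- 2000
  ga <- runif(n, 20, 40)
  y <- 100 - 2 * ga + rnorm(n, 0, 5)
  beta <- fit_trend(ga, y, "linear")
  se_slope <- 5 / sqrt(n * var(ga))
  expect_lt(abs(beta[2] - (-2)), 3 * se_slope)
})

test_that("degenerate trend inputs raise informative errors", {
  expect_error(fit_trend(1:5, 1:5, "linear"), "at least 10")
  expect_error(fit_trend(rep(30, 20), rnorm(20), "linear"), "degenerate")
  expect_error(fit_quantile_curve(rep(30, 20), rnorm(20), "linear", 0.05),
               "degenerate")
  expect_error(fit_quantile_curve(1:20, rnorm(20), "linear", 1.2), "tau")
})

test_that("median regression tracks the mean curve under symmetric noise", {
  set.seed(22)
  n <- 2000
  ga <- runif(n, 20, 40)
  y <- 100 - 2 * ga + rnorm(n, 0, 5)
  b_med <- fit_quantile_curve(ga, y, "linear", tau = 0.5)
  se_slope <- 5 / sqrt(n * var(ga)) * sqrt(pi / 2)  # median efficiency
  expect_lt(abs(b_med[2] - (-2)), 3 * se_slope)
})

test_that("the 5th centile matches the Gaussian closed form", {
  set.seed(33)
  n <- 2000
  sigma <- 5
  ga <- runif(n, 20, 40)
  y <- 100 - 2 * ga + rnorm(n, 0, sigma)
  b05 <- fit_quantile_curve(ga, y, "linear", tau = 0.05)
  target_intercept <- 100 + sigma * qnorm(0.05)  # 91.7757
  # asymptotic SEs: OLS SE times the Gaussian quantile inflation factor
  infl <- sqrt(0.05 * 0.95) / dnorm(qnorm(0.05))
  se_int <- sigma * sqrt(1 / n + mean(ga)^2 / (n * var(ga))) * infl
  se_slope <- sigma / sqrt(n * var(ga)) * infl
  expect_lt(abs(b05[1] - target_intercept), 3.5 * se_int)
  expect_lt(abs(b05[2] - (-2)), 3.5 * se_slope)
})

test_that("quantile fits beat the OLS coefficients on the check loss", {
  set.seed(44)
  n <- 500
  ga <- runif(n, 20, 40)
  y <- 100 - 2 * ga + rnorm(n, 0, 5) * (1 + 0.05 * (ga - 20))
  X <- cbind(1, ga)
  for (tau in c(0.05, 0.5, 0.95)) {
    b_q <- fit_quantile_curve(ga, y, "linear", tau = tau)
    b_ols <- fit_trend(ga, y, "linear")
    expect_lte(pinball_loss(y, X, b_q, tau),
               pinball_loss(y, X, b_ols, tau) + 1e-9)
  }
})

test_that("a control cohort yields four models with the stated trends", {
  tab <- generate_control_cohort(n = 88, seed = 7)
  models <- build_normative_models(tab)
  expect_length(models, 4)
  expect_equal(models[["fetal_brain.mean_t2star"]]$trend, "quadratic")
  expect_equal(models[["placenta.mean_t2star"]]$trend, "linear")
  expect_equal(models[["placenta.volume"]]$trend, "linear")
  expect_equal(models[["fetal_brain.volume"]]$trend, "linear")
  expect_equal(models[["placenta.mean_t2star"]]$n_train, 88)
  # quantile curves share the trend degree
  expect_length(models[["fetal_brain.mean_t2star"]]$q05_coeffs, 3)
  expect_length(models[["placenta.volume"]]$q95_coeffs, 2)
})

test_that("missing combinations are omitted with a warning", {
  tab <- generate_control_cohort(n = 88, seed = 7)
  tab <- tab[!(tab$organ == "placenta" & tab$measure == "volume"), ]
  expect_warning(models <- build_normative_models(tab),
                 "placenta.volume")
  expect_length(models, 3)
})

test_that("a zero-noise cohort collapses centiles onto the mean curve", {
  sds0 <- list(placenta = list(mean_t2star = 0, volume = 0),
               fetal_brain = list(mean_t2star = 0, volume = 0))
  tab <- generate_control_cohort(n = 88, noise_sd = sds0, seed = 3)
  models <- suppressWarnings(build_normative_models(tab))
  trends <- default_ga_trends()
  m <- models[["placenta.mean_t2star"]]
  expect_equal(m$mean_coeffs, trends$placenta$mean_t2star, tolerance = 1e-8)
  ga <- seq(21, 39, length.out = 50)
  expect_equal(predict(m, ga, "q05"), predict(m, ga, "mean"),
               tolerance = 1e-6)
  expect_equal(predict(m, ga, "q95"), predict(m, ga, "mean"),
               tolerance = 1e-6)
})

test_that("model JSON round trip preserves curve evaluations", {
  tab <- generate_control_cohort(n = 88, seed = 7)
  models <- build_normative_models(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_models(models, path)
  back <- read_normative_models(path)
  expect_setequal(names(back), names(models))
  ga <- seq(20, 40, length.out = 100)
  for (key in names(models))
    for (what in c("mean", "q05", "q95"))
      expect_equal(predict(back[[key]], ga, what),
                   predict(models[[key]], ga, what), tolerance = 1e-12)
  expect_error(read_normative_models(withr::local_tempfile(
    lines = "{\"foo\": 1}", fileext = ".json")), "not a normative")
})

test_that("classification bands use inclusive boundaries and flag extrapolation", {
  tab <- generate_control_cohort(n = 88, seed = 7)
  model <- build_normative_models(tab)[["placenta.mean_t2star"]]
  ga <- 33
  q05 <- predict(model, ga, "q05")
  q95 <- predict(model, ga, "q95")
  expect_equal(classify(model, ga, q05)$band, "normal")   # on the curve
  expect_equal(classify(model, ga, q95)$band, "normal")
  expect_equal(classify(model, ga, q05 - 1e-6)$band, "low")
  expect_equal(classify(model, ga, q95 + 1)$band, "high")
  expect_false(classify(model, ga, q05)$extrapolated)
  res <- classify(model, 44, 100)
  expect_true(res$extrapolated)
  expect_true(res$band %in% c("low", "normal", "high"))
})

test_that("held-out control points are classified low at about the 5% rate", {
  set.seed(55)
  n_train <- 2000
  n_test <- 1000
  ga <- runif(n_train + n_test, 20, 40)
  y <- 300 - 3 * ga + rnorm(n_train + n_test, 0, 12)
  b05 <- fit_quantile_curve(ga[1:n_train], y[1:n_train], "linear", 0.05)
  b95 <- fit_quantile_curve(ga[1:n_train], y[1:n_train], "linear", 0.95)
  model <- fetalT2star:::new_normative_model(
    "placenta", "mean_t2star", "linear",
    fit_trend(ga[1:n_train], y[1:n_train], "linear"), b05, b95,
    range(ga[1:n_train]), n_train)
  test_idx <- n_train + seq_len(n_test)
  bands <- vapply(test_idx, function(i)
    classify(model, ga[i], y[i])$band, "")
  frac_low <- mean(bands == "low")
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n_test)
  expect_gt(frac_low, ci[1])
  expect_lt(frac_low, ci[2])
})

test_that("classification is invariant to affine rescaling of the measure", {
  set.seed(66)
  n <- 300
  ga <- runif(n, 20, 40)
  y <- 280 - 2.5 * ga + rnorm(n, 0, 15)
  build_one <- function(vals) {
    fetalT2star:::new_normative_model(
      "placenta", "mean_t2star", "linear", fit_trend(ga, vals, "linear"),
      fit_quantile_curve(ga, vals, "linear", 0.05),
      fit_quantile_curve(ga, vals, "linear", 0.95), range(ga), n)
  }
  m1 <- build_one(y)
  scale_a <- 3.7; scale_b <- 40
  m2 <- build_one(scale_a * y + scale_b)
  for (q in c(50, 150, 220, 260))
    expect_equal(classify(m2, 30, scale_a * q + scale_b)$band,
                 classify(m1, 30, q)$band)
})

test_that("centile crossing within the GA range raises a warning", {
  # q05 above q95 at high GA: curves cross inside the range
  expect_warning(
    fetalT2star:::new_normative_model(
      "placenta", "mean_t2star", "linear", c(200, -2),
      q05_coeffs = c(150, 1), q95_coeffs = c(250, -2),
      ga_range = c(20, 40), n_train = 50),
    "crossing")
})
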
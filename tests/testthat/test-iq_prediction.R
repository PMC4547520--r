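test_that("the packaged regression models carry the published equations", {
  mini <- mini_nart_predictor()
  expect_identical(c(mini$intercept, mini$slope), c(64.94, 2.345))
  expect_identical(mini$slope_ci, c(2.13, 2.56))
  expect_equal(mini$max_score, 23)
  full <- nart_predictor()
  expect_identical(c(full$intercept, full$slope), c(55.97, 1.306))
  expect_identical(full$slope_ci, c(1.19, 1.42))
  expect_equal(full$max_score, 50)
})

test_that("point predictions and slope-CIs follow the published convention", {
  est <- predict_iq(mini_nart_predictor(), 20)
  expect_equal(est$point, 111.84)
  expect_equal(round(est$ci_low, 2), 107.54)
  expect_equal(round(est$ci_high, 2), 116.14)
  est45 <- predict_iq(nart_predictor(), 45)
  expect_equal(round(est45$point, 2), 114.74)
  expect_equal(round(est45$ci_low, 2), 109.52)
  expect_equal(round(est45$ci_high, 2), 119.87)
  # at score 0 everything collapses to the intercept
  est0 <- predict_iq(mini_nart_predictor(), 0)
  expect_equal(c(est0$point, est0$ci_low, est0$ci_high), rep(64.94, 3))
})

test_that("scores outside the scale range are refused by name", {
  expect_error(predict_iq(mini_nart_predictor(), 24), "23")
  expect_error(predict_iq(nart_predictor(), -1), "50")
})

test_that("predictions are linear in the score with linearly growing CI", {
  m <- mini_nart_predictor()
  s <- 0:23
  est <- predict_iq(m, s)
  expect_equal(diff(est$point), rep(m$slope, 23))
  expect_equal(diff(est$ci_high - est$ci_low),
               rep(diff(m$slope_ci), 23))
})

test_that("conversion tables round to the published ceilings", {
  tab <- conversion_table(mini_nart_predictor())
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$iq_rounded[tab$score == 23], 119)
  expect_equal(tab$predicted_iq[tab$score == 0], 64.94)
  full <- conversion_table(nart_predictor())
  expect_equal(full$iq_rounded[full$score == 50], 121)
})

test_that("ordinary least squares recovers known generating parameters", {
  set.seed(19)
  score <- sample(0:23, 500, replace = TRUE)
  iq <- 60 + 2.5 * score + rnorm(500, 0, 5)
  fit <- fit_predictor(score, iq, label = "sim")
  expect_true(fit$slope_ci[1] <= 2.5 && 2.5 <= fit$slope_ci[2])
  expect_equal(fit$r_squared, criterion_correlation(score, iq)^2)
  # the published-convention and prediction intervals both bracket the point
  est <- predict_iq(fit, 10)
  pred <- predict_iq(fit, 10, interval = "prediction")
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  expect_true(pred$ci_low < est$ci_low && pred$ci_high > est$ci_high)
  expect_error(predict_iq(mini_nart_predictor(), 10, "prediction"),
               "fit_predictor")
})

test_that("a noise-free line is recovered exactly", {
  score <- 0:23
  iq <- 64.94 + 2.345 * score
  fit <- suppressWarnings(fit_predictor(score, iq))  # perfect-fit warning
  expect_equal(fit$intercept, 64.94)
  expect_equal(fit$slope, 2.345)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_predictor(rep(3, 10), rnorm(10)), "constant")
})

test_that("criterion correlations behave like Pearson's r", {
  expect_equal(criterion_correlation(1:10, 3 + 2 * (1:10)), 1)
  set.seed(23)
  n <- 5000
  x <- rnorm(n)
  y <- 0.68 * x + sqrt(1 - 0.68^2) * rnorm(n)
  se <- (1 - 0.68^2) / sqrt(n)
  expect_lt(abs(criterion_correlation(x, y) - 0.68), 3 * se)
  z <- rnorm(n)
  expect_lt(abs(criterion_correlation(x, z)), 3 / sqrt(n))
  expect_warning(r <- criterion_correlation(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
})
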
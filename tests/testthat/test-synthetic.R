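test_that("the same spec and seed reproduce the draw bit for bit", {
  spec <- preset_rasch(300, 6, seed = 5)
  a <- generate(spec); b <- generate(spec)
  expect_identical(unclass(a$responses), unclass(b$responses))
  expect_identical(a$criterion, b$criterion)
  other <- generate(preset_rasch(300, 6, seed = 6))
  expect_false(identical(unclass(a$responses), unclass(other$responses)))
})

test_that("guttman_matrix builds the canonical scalogram", {
  g <- guttman_matrix(4, 3)
  expect_equal(unclass(g),
               matrix(c(1, 1, 1, 0, 1, 1, 0, 0, 1, 0, 0, 0), 4, 3,
                      dimnames = list(NULL, paste0("I", 1:3))),
               ignore_attr = FALSE)
  expect_equal(scale_scalability(guttman_matrix(20, 6))$h_scale, 1)
  expect_equal(nrow(check_iio(guttman_matrix(20, 6), minsize = 3)$pairs),
               0L)
})

test_that("step items produce a scalogram once persons are sorted by trait", {
  spec <- synthetic_spec(50, a = rep(Inf, 4), b = c(-1, -0.2, 0.4, 1.1),
                         seed = 31)
  sim <- generate(spec)
  X <- unclass(sim$responses)[order(sim$theta[, 1]), ]
  expect_equal(scale_scalability(item_response_matrix(X))$h_scale, 1)
})

test_that("empirical marginals match the quadrature oracle", {
  sim <- cached("rasch_2k", generate(preset_rasch(2000, 10, seed = 1)))
  spec <- sim$spec
  for (i in seq_along(spec$a)) {
    pm <- model_implied_marginal(spec$a[i], spec$b[i])
    se <- sqrt(pm * (1 - pm) / 2000)
    expect_lt(abs(mean(sim$responses[, i]) - pm), 3 * se)
  }
})

test_that("uncorrelated traits leave cross-block pairs unscalable", {
  sim <- cached("two_trait", generate(preset_two_trait(2000, 0, seed = 1)))
  h <- scale_scalability(sim$responses)$h_pair
  cross <- h[1:3, 4:6]
  expect_lt(abs(mean(cross)), 0.05)
})

test_that("invalid specs are rejected", {
  expect_error(preset_two_trait(500, rho = 1.5), "rho")
  expect_error(synthetic_spec(500, a = c(-1, 2), b = c(0, 0)))
  expect_error(synthetic_spec(500, a = c(1, 2), b = c(0, 0),
                              labels = c("A", "A")))
})

test_that("the NART-like preset is calibrated to the published marginals", {
  spec <- cached("nart_spec", nart_like_preset())
  fx <- load_nart_fixture()
  implied <- 100 * vapply(seq_along(spec$a), function(i)
    model_implied_marginal(spec$a[i], spec$b[i]), numeric(1))
  expect_lt(max(abs(implied - fx$all_items$pct_correct)), 0.5)
  roles <- attr(spec, "roles")
  expect_length(roles$mini, 23L)
  expect_length(roles$violators, 15L)
  expect_length(roles$second, 3L)
  expect_length(roles$unscalable, 9L)
  expect_setequal(roles$mini, fx$mini_items$item)
})

test_that("a RADIX-like flat item has discrimination near zero", {
  sim <- cached("nart_600", generate(cached("nart_spec", nart_like_preset())))
  expect_lt(abs(item_scalability(sim$responses, "RADIX")), 0.1)
})

test_that("the criterion tracks the latent trait as designed", {
  sim <- cached("rasch_2k", generate(preset_rasch(2000, 10, seed = 1)))
  fit <- fit_predictor(rowSums(sim$responses), sim$criterion)
  expect_gt(fit$slope_ci[1], 0)
  expect_gt(criterion_correlation(rowSums(sim$responses), sim$criterion),
            0.5)
})
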
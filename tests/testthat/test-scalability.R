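test_that("Guttman error counts match direct counting", {
  m <- item_response_matrix(cbind(i = c(1, 1, 1, 0), j = c(1, 1, 0, 0)))
  ge <- guttman_errors(m, "i", "j")
  expect_equal(ge$observed, 0)
  expect_equal(ge$expected, 0.5)
  expect_equal(ge$easier, "i")

  m2 <- item_response_matrix(cbind(i = c(1, 1, 1, 1, 0),
                                   j = c(1, 1, 0, 0, 1)))
  ge2 <- guttman_errors(m2, 1, 2)
  expect_equal(ge2$observed, 1)
  expect_equal(ge2$expected, 0.6)

  # nesting forbids the error pattern entirely
  g <- guttman_matrix(30, 5)
  for (i in 1:4)
    expect_equal(guttman_errors(g, i, i + 1)$observed, 0)

  degen <- item_response_matrix(cbind(a = c(1, 1, 1), b = c(1, 0, 0)))
  expect_true(guttman_errors(degen, 1, 2)$degenerate)
  expect_true(is.na(pair_scalability(degen, 1, 2)))
})

test_that("pairwise Hij matches its frozen hand-computed values", {
  m <- item_response_matrix(cbind(c(1, 1, 1, 0), c(1, 1, 0, 0)))
  expect_equal(pair_scalability(m, 1, 2), 1)
  opp <- item_response_matrix(cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(pair_scalability(opp, 1, 2), -1)
  m2 <- item_response_matrix(cbind(c(1, 1, 1, 1, 0), c(1, 1, 0, 0, 1)))
  expect_equal(pair_scalability(m2, 1, 2), 1 - 1 / 0.6)
  expect_equal(round(pair_scalability(m2, 1, 2), 3), -0.667)
})

test_that("error-ratio and covariance-ratio Hij agree on random matrices", {
  set.seed(42)
  for (rep in 1:100) {
    X <- matrix(rbinom(60, 1, runif(1, 0.2, 0.8)), 10, 6)
    p <- colMeans(X)
    if (any(p %in% c(0, 1))) next
    m <- item_response_matrix(X)
    i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
    expect_equal(pair_scalability(m, i, j), hij_cov_oracle(m, i, j))
  }
})

test_that("item scalability is a ratio of summed errors", {
  m <- item_response_matrix(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0),
                                  c(0, 0, 0)))
  expect_equal(item_scalability(m, 2), 1)
  g <- guttman_matrix(24, 5)
  for (i in 1:5) expect_equal(item_scalability(g, i), 1)
  # brute-force oracle: Hi = 1 - sum(F)/sum(E) over pairs
  set.seed(7)
  X <- matrix(rbinom(200, 1, 0.5), 20, 10)
  m <- item_response_matrix(X)
  Fs <- Es <- 0
  for (j in 2:10) {
    ge <- guttman_errors(m, 1, j)
    Fs <- Fs + ge$observed; Es <- Es + ge$expected
  }
  expect_equal(item_scalability(m, 1), 1 - Fs / Es)
})

test_that("a perfect scalogram attains H = Hi = Hij = 1", {
  sc <- scale_scalability(guttman_matrix(12, 3))
  expect_equal(sc$h_scale, 1)
  expect_equal(unname(sc$h_item), rep(1, 3))
  expect_equal(unique(sc$h_pair[upper.tri(sc$h_pair)]), 1)
  # single-pair reduction
  m <- item_response_matrix(cbind(c(1, 1, 1, 0), c(1, 1, 0, 0)))
  expect_equal(scale_scalability(m)$h_scale, 1)
})

test_that("independent items have H near zero within bootstrap error", {
  sim <- cached("indep2", {
    set.seed(11)
    item_response_matrix(cbind(A = rbinom(5000, 1, 0.6),
                               B = rbinom(5000, 1, 0.4)))
  })
  sc <- scale_scalability(sim, se = "bootstrap", n_boot = 200, seed = 3)
  expect_lt(abs(sc$h_scale), 3 * sc$se_scale)
  expect_lt(abs(sc$h_scale), 0.05)
})

test_that("coefficients are invariant to row order and track column order", {
  set.seed(5)
  X <- matrix(rbinom(180, 1, 0.5), 30, 6)
  m <- item_response_matrix(X)
  sc <- scale_scalability(m)
  perm_rows <- item_response_matrix(X[sample(30), ])
  expect_equal(scale_scalability(perm_rows), sc)
  cols <- sample(6)
  sc_cols <- scale_scalability(item_response_matrix(X[, cols],
                                                    colnames(m)[cols]))
  expect_equal(sc_cols$h_scale, sc$h_scale)
  expect_equal(sc_cols$h_item, sc$h_item[cols])
  expect_equal(sc_cols$h_pair, sc$h_pair[cols, cols])
})

test_that("scale strength bands follow the standard rule of thumb", {
  expect_equal(as.character(classify_strength(0.534)), "strong")
  expect_equal(as.character(classify_strength(0.471)), "medium")
  expect_equal(as.character(classify_strength(0.3)), "weak")
  expect_equal(as.character(classify_strength(0.29)), "unscalable")
  expect_equal(as.character(classify_strength(c(0.4, 0.5, 1))),
               c("medium", "strong", "strong"))
  expect_error(classify_strength(1.2))
})
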
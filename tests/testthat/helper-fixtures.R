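# small deterministic fixtures and cached simulations shared across tests

# two independent 3-item Guttman blocks, interleaved columns (A1 B1 A2 B2
# A3 B3): within-block structure is a perfect scalogram, cross-block
# covariance is exactly zero by the full factorial over score patterns.
two_block_matrix <- function(replicates = 5L) {
  pat <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  rows <- list()
  for (i in 1:4) for (j in 1:4)
    rows[[length(rows) + 1L]] <- c(pat[i, ], pat[j, ])[c(1, 4, 2, 5, 3, 6)]
  X <- do.call(rbind, rows)[rep(1:16, replicates), ]
  colnames(X) <- c("A1", "B1", "A2", "B2", "A3", "B3")
  item_response_matrix(X)
}

# rest-score groups built by hand: item 3's conditional proportion drops
# by exactly `drop` between rest-score groups 0 and 1 (50 persons each)
mono_drop_matrix <- function(drop) {
  k1 <- 25                        # P(item3 | rest 0) = 0.5
  k2 <- round(50 * (0.5 - drop))  # P(item3 | rest 1) = 0.5 - drop
  k3 <- 40                        # P(item3 | rest 2) = 0.8
  rows <- rbind(
    cbind(0, 0, rep(c(1, 0), c(k1, 50 - k1))),
    cbind(1, 0, rep(c(1, 0), c(k2, 50 - k2))),
    cbind(1, 1, rep(c(1, 0), c(k3, 50 - k3))))
  item_response_matrix(rows, c("I1", "I2", "I3"))
}

# 4-item matrix whose pair (I3, I4) reverses by exactly 0.25 in the top
# rest-score group (40 persons each) while I3 is easier overall
iio_reversal_matrix <- function() {
  g0 <- cbind(0, 0, rep(c(1, 0), c(24, 16)), rep(c(1, 0), c(10, 30)))
  g2 <- cbind(1, 1, rep(c(1, 0), c(16, 24)), rep(c(1, 0), c(26, 14)))
  item_response_matrix(rbind(g0, g2), paste0("I", 1:4))
}

.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# population-covariance oracle for Hij, independent of the error-count path
hij_cov_oracle <- function(m, i, j) {
  p <- colMeans(m)
  eh <- if (p[i] > p[j] || (p[i] == p[j] && i < j)) c(i, j) else c(j, i)
  covpop <- mean(m[, i] * m[, j]) - p[i] * p[j]
  covmax <- p[eh[2L]] * (1 - p[eh[1L]])
  unname(covpop / covmax)
}
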
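#' Molenaar-Sijtsma reliability of the total score
#'
#' Estimates test-score reliability for a dichotomous Mokken scale. Items
#' are ordered by decreasing popularity and the joint proportion matrix
#' `P[i, j] = P(Xi = 1, Xj = 1)` assembled; the unobservable diagonal
#' (the probability of passing the same item on two independent
#' replications) is approximated from neighbouring entries in the ordered
#' matrix: inner items use the two-neighbour ratio
#' `P[i, i-1] * P[i, i+1] / P[i-1, i+1]`, the first (most popular) item the
#' single-neighbour success ratio `P[1, 2] * p1 / p2`, and the last item
#' the mirrored single-neighbour failure ratio on the joint failure
#' proportion. Reliability is then
#' `MS = 1 - sum_i (p_i - p_hat_ii) / var(total score)`
#' (population variance). Both a perfect scalogram and perfectly coherent
#' all-0/all-1 response data give MS = 1; independent items give MS near 0.
#'
#' @param m response matrix with at least 3 non-degenerate items.
#' @return Object of class `reliability`: `ms`, `reliable_flag`
#'   (`ms > 0.7`), `degenerate_flag` (TRUE when MS falls outside [0, 1];
#'   the value is reported raw, never clamped), `n_persons`, `n_items`,
#'   `excluded` (zero-variance items left out).
#' @examples
#' ms_reliability(guttman_matrix(40, 4))$ms   # 1
#' @export
ms_reliability <- function(m) {
  m <- as_irm(m)
  p_all <- colMeans(m)
  degen <- p_all %in% c(0, 1)
  if (any(degen))
    warning("zero-variance item(s) excluded from MS: ",
            paste(colnames(m)[degen], collapse = ", "))
  use <- which(!degen)
  if (length(use) < 3L)
    stop("MS reliability needs at least 3 non-degenerate items")
  X <- unclass(m)[, use, drop = FALSE]
  n <- nrow(X)
  # popularity order, ties by column index
  ord <- order(-colMeans(X), seq_len(ncol(X)))
  X <- X[, ord, drop = FALSE]
  p <- colMeans(X)
  J <- ncol(X)
  P11 <- crossprod(X) / n
  P00 <- crossprod(1 - X) / n
  phat <- numeric(J)
  phat[1L] <- P11[1L, 2L] * p[1L] / p[2L]
  for (i in 2:(J - 1L)) {
    den <- P11[i - 1L, i + 1L]
    phat[i] <- if (den > 0) P11[i, i - 1L] * P11[i, i + 1L] / den
      else mean(c(P11[i, i - 1L] * p[i] / p[i - 1L],
                  P00[i, i + 1L] * (1 - p[i]) / (1 - p[i + 1L]) - 1 +
                    2 * p[i]))
  }
  # least popular item: mirror on failures, then convert back via
  # P(0,0) = 1 - 2p + P(1,1)
  phat[J] <- P00[J, J - 1L] * (1 - p[J]) / (1 - p[J - 1L]) - 1 + 2 * p[J]
  tot <- rowSums(X)
  v <- mean((tot - mean(tot))^2)
  if (v == 0) stop("total score has zero variance")
  ms <- 1 - sum(p - phat) / v
  structure(list(ms = ms, reliable_flag = ms > 0.7,
                 degenerate_flag = ms < 0 || ms > 1,
                 n_persons = n, n_items = J,
                 excluded = colnames(m)[degen]),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("Molenaar-Sijtsma reliability: MS = %.3f (%s)\n", x$ms,
              if (x$degenerate_flag) "degenerate"
              else if (x$reliable_flag) "reliable, MS > 0.7"
              else "below the 0.7 reliability threshold"))
  invisible(x)
}
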
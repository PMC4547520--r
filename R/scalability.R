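#' Guttman errors for an item pair
#'
#' For a pair of dichotomous items ordered by sample difficulty (the item
#' with the higher proportion correct is the "easier" one; ties are broken
#' by column order), a Guttman error is the response pattern "harder item
#' passed, easier item failed". The expected count is the one implied by
#' marginal independence, `E = N * P(easier = 0) * P(harder = 1)`.
#'
#' @param m response matrix.
#' @param i,j item indices or labels, `i != j`.
#' @return A list with `observed` (count F), `expected` (E), `easier` and
#'   `harder` (labels), and `degenerate` (TRUE when either item has
#'   proportion correct 0 or 1, in which case the expected count can vanish
#'   and the pair is excluded from coefficient sums downstream).
#' @export
guttman_errors <- function(m, i, j) {
  m <- as_irm(m)
  i <- item_index(m, i); j <- item_index(m, j)
  if (i == j) stop("'i' and 'j' must name different items")
  p <- colMeans(m)
  eh <- order_pair(p, i, j)
  n <- nrow(m)
  obs <- sum(m[, eh[1L]] == 0L & m[, eh[2L]] == 1L)
  exp_ <- n * (1 - p[eh[1L]]) * p[eh[2L]]
  list(observed = obs, expected = unname(exp_),
       easier = colnames(m)[eh[1L]], harder = colnames(m)[eh[2L]],
       degenerate = any(p[c(i, j)] %in% c(0, 1)))
}

# easier item first; difficulty ties broken by column order
order_pair <- function(p, i, j) {
  if (p[i] > p[j] || (p[i] == p[j] && i < j)) c(i, j) else c(j, i)
}

item_index <- function(m, i) {
  if (is.character(i)) {
    k <- match(i, colnames(m))
    if (is.na(k)) stop("unknown item: ", i)
    return(k)
  }
  as.integer(i)
}

#' Item-pair scalability coefficient Hij
#'
#' `Hij = 1 - observed/expected` Guttman errors; algebraically equal to
#' `cov(Xi, Xj) / covmax` with `covmax = P(harder = 1) * P(easier = 0)`.
#' Undefined (NA) when the expected count is zero (degenerate marginals).
#'
#' @inheritParams guttman_errors
#' @return Scalar Hij in (-Inf, 1], or NA for a degenerate pair.
#' @export
pair_scalability <- function(m, i, j) {
  ge <- guttman_errors(m, i, j)
  if (ge$expected == 0) return(NA_real_)
  1 - ge$observed / ge$expected
}

# Observed/expected Guttman error matrices for all ordered pairs.
# Fmat[i, j] and Emat[i, j] hold the counts for the unordered pair {i, j}
# (symmetric); diagonal NA. Pairs involving a degenerate item are NA.
guttman_error_matrices <- function(m) {
  n <- nrow(m); J <- ncol(m)
  p <- colMeans(m)
  X <- unclass(m)
  C01 <- crossprod(1 - X, X)           # C01[a, b] = #(Xa = 0 & Xb = 1)
  Fmat <- Emat <- matrix(NA_real_, J, J,
                         dimnames = list(colnames(m), colnames(m)))
  degen <- p %in% c(0, 1)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      if (degen[i] || degen[j]) next
      eh <- order_pair(p, i, j)
      Fmat[i, j] <- Fmat[j, i] <- C01[eh[1L], eh[2L]]
      Emat[i, j] <- Emat[j, i] <- n * (1 - p[eh[1L]]) * p[eh[2L]]
    }
  }
  list(F = Fmat, E = Emat, degenerate = degen, p = p, n = n)
}

#' Item scalability coefficient Hi
#'
#' Item discrimination in the Mokken sense: one minus the ratio of summed
#' observed to summed expected Guttman errors over all pairs involving the
#' item (a ratio of sums, not a mean of per-pair ratios).
#'
#' @inheritParams guttman_errors
#' @param i item index or label.
#' @export
item_scalability <- function(m, i) {
  m <- as_irm(m)
  i <- item_index(m, i)
  ge <- guttman_error_matrices(m)
  Fs <- sum(ge$F[i, ], na.rm = TRUE)
  Es <- sum(ge$E[i, ], na.rm = TRUE)
  if (Es == 0 || all(is.na(ge$E[i, ]))) return(NA_real_)
  1 - Fs / Es
}

#' Scalability coefficients of a dichotomous scale
#'
#' Computes the full set of Loevinger scalability coefficients: the pairwise
#' matrix Hij, per-item Hi, and the scale coefficient
#' `H = 1 - sum(F) / sum(E)` over all item pairs. `H = 1` exactly when the
#' data contain no Guttman errors (a perfect scalogram). Zero-variance
#' (degenerate) items are excluded from every sum and reported in
#' `$degenerate`.
#'
#' The standard error of H (and of each Hi) is estimated by a seeded
#' nonparametric bootstrap over persons when `se = "bootstrap"`.
#'
#' @param m response matrix.
#' @param se `"none"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap resampling.
#' @return An object of class `scalability`: list with `h_pair`, `h_item`,
#'   `h_scale`, `se_scale` (NA unless bootstrapped), `se_item`, `strength`
#'   (see [classify_strength()]), `degenerate`, `n_persons`.
#' @examples
#' m <- guttman_matrix(8, 4)
#' scale_scalability(m)$h_scale   # 1: a perfect scalogram
#' @export
scale_scalability <- function(m, se = c("none", "bootstrap"),
                              n_boot = 1000L, seed = 1L) {
  m <- as_irm(m)
  se <- match.arg(se)
  ge <- guttman_error_matrices(m)
  res <- h_from_error_matrices(ge)
  se_scale <- NA_real_
  se_item <- rep(NA_real_, ncol(m))
  if (se == "bootstrap") {
    hs <- matrix(NA_real_, n_boot, ncol(m) + 1L)
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(m), replace = TRUE)
        bres <- h_from_error_matrices(
          guttman_error_matrices(as_irm_quiet(unclass(m)[idx, , drop = FALSE])))
        hs[b, ] <- c(bres$h_scale, bres$h_item)
      }
    })
    se_scale <- stats::sd(hs[, 1L], na.rm = TRUE)
    se_item <- apply(hs[, -1L, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  }
  structure(list(h_pair = res$h_pair, h_item = res$h_item,
                 h_scale = res$h_scale, se_scale = se_scale,
                 se_item = se_item,
                 strength = classify_strength(res$h_scale),
                 degenerate = colnames(m)[ge$degenerate],
                 n_persons = nrow(m)),
            class = "scalability")
}

h_from_error_matrices <- function(ge) {
  Fm <- ge$F; Em <- ge$E
  h_pair <- 1 - Fm / Em
  h_pair[Em == 0] <- NA_real_
  Fi <- rowSums(Fm, na.rm = TRUE)
  Ei <- rowSums(Em, na.rm = TRUE)
  h_item <- ifelse(Ei > 0, 1 - Fi / Ei, NA_real_)
  h_item[ge$degenerate] <- NA_real_
  names(h_item) <- rownames(Fm)
  Etot <- sum(Em[upper.tri(Em)], na.rm = TRUE)
  h_scale <- if (Etot > 0)
    1 - sum(Fm[upper.tri(Fm)], na.rm = TRUE) / Etot else NA_real_
  list(h_pair = h_pair, h_item = h_item, h_scale = h_scale)
}

# irm coercion without label bookkeeping, for hot loops
as_irm_quiet <- function(x) {
  class(x) <- c("irm", "matrix", "array")
  x
}

#' Classify Mokken scale strength
#'
#' Standard rule of thumb for the scale coefficient H: below 0.3 the item
#' set is not considered unidimensional ("unscalable"); 0.3-0.4 weak;
#' 0.4-0.5 medium; 0.5 and above strong.
#'
#' @param h numeric vector of H (or HT) values, each at most 1.
#' @return Factor with levels unscalable < weak < medium < strong.
#' @examples
#' classify_strength(c(0.534, 0.471, 0.3, 0.1))
#' @export
classify_strength <- function(h) {
  stopifnot(all(h <= 1 | is.na(h)))
  cut(h, breaks = c(-Inf, 0.3, 0.4, 0.5, 1),
      labels = c("unscalable", "weak", "medium", "strong"),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' @export
print.scalability <- function(x, ...) {
  cat(sprintf("Scale H = %.3f%s (%s), %d persons\n", x$h_scale,
              if (is.na(x$se_scale)) "" else sprintf(" (SE = %.3f)",
                                                     x$se_scale),
              as.character(x$strength), x$n_persons))
  tab <- data.frame(item = names(x$h_item), Hi = round(x$h_item, 3),
                    row.names = NULL)
  print(tab)
  if (length(x$degenerate))
    cat("Degenerate (zero-variance) items excluded:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
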
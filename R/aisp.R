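#' Automated item selection procedure (AISP)
#'
#' Greedy bottom-up partitioning of dichotomous items into Mokken scales.
#' A scale is seeded with the pair of items having the largest Hij among
#' pairs whose Hij is at least `lowerbound` and significantly positive; it
#' then repeatedly admits the unselected item that (a) has a significantly
#' positive Hij with every selected item, (b) would leave every member's Hi
#' at or above `lowerbound` and every within-scale Hij positive, and (c)
#' maximizes the resulting scale H, ties going to the lower column index.
#' When no item qualifies the scale is closed and the procedure restarts on
#' the remainder; anything left over is unscalable.
#'
#' Significance of Hij > 0 uses the one-sided asymptotic normal test
#' `z = r * sqrt(n - 1)` on the phi coefficient of the 2x2 item table,
#' Bonferroni-corrected across the candidate tests of each selection step.
#'
#' @param m response matrix.
#' @param lowerbound scalability lower bound c (default 0.3).
#' @param alpha significance level for Hij > 0 (default 0.05).
#' @return An object of class `scale_partition`: list with `scales` (list
#'   of integer index vectors, labelled), `unscalable` (indices),
#'   `coefficients` (per-scale [scale_scalability()] results),
#'   `lowerbound`, `alpha`, `item_labels`, `popularity`.
#' @examples
#' p <- aisp(guttman_matrix(420, 6))
#' length(p$scales)   # one scale holding all six items
#' @export
aisp <- function(m, lowerbound = 0.3, alpha = 0.05) {
  m <- as_irm(m)
  J <- ncol(m)
  n <- nrow(m)
  p <- colMeans(m)
  degen <- which(p %in% c(0, 1))
  Z <- pair_z_matrix(m)
  H <- scale_scalability(m)$h_pair
  remaining <- setdiff(seq_len(J), degen)
  scales <- list()
  while (length(remaining) >= 2L) {
    sel <- seed_pair(H, Z, remaining, lowerbound, alpha)
    if (is.null(sel)) break
    repeat {
      cand <- grow_candidates(m, H, Z, sel, setdiff(remaining, sel),
                              lowerbound, alpha)
      if (is.null(cand)) break
      sel <- c(sel, cand)
    }
    scales[[length(scales) + 1L]] <- sort(sel)
    remaining <- setdiff(remaining, sel)
  }
  unscalable <- sort(c(remaining, degen))
  coefs <- lapply(scales, function(s)
    scale_scalability(m[, s, drop = FALSE]))
  scales <- lapply(scales, function(s) stats::setNames(s, colnames(m)[s]))
  structure(list(scales = scales,
                 unscalable = stats::setNames(unscalable,
                                              colnames(m)[unscalable]),
                 coefficients = coefs, lowerbound = lowerbound,
                 alpha = alpha, item_labels = colnames(m), popularity = p),
            class = "scale_partition")
}

# one-sided z statistics for Hij > 0 (phi coefficient scaled by sqrt(n - 1))
pair_z_matrix <- function(m) {
  X <- unclass(m)
  sds <- apply(X, 2L, stats::sd)
  ok <- sds > 0
  Z <- matrix(NA_real_, ncol(X), ncol(X))
  if (sum(ok) >= 2L) {
    r <- suppressWarnings(stats::cor(X[, ok, drop = FALSE]))
    Z[ok, ok] <- r * sqrt(nrow(X) - 1)
  }
  diag(Z) <- NA_real_
  Z
}

seed_pair <- function(H, Z, remaining, lowerbound, alpha) {
  k <- length(remaining)
  ntest <- k * (k - 1) / 2
  crit <- stats::qnorm(1 - alpha / ntest)
  best <- NULL; best_h <- -Inf
  for (ai in seq_len(k - 1L)) {
    for (bi in (ai + 1L):k) {
      i <- remaining[ai]; j <- remaining[bi]
      h <- H[i, j]; z <- Z[i, j]
      if (is.na(h) || is.na(z)) next
      if (h >= lowerbound && z > crit && h > best_h) {
        best <- c(i, j); best_h <- h
      }
    }
  }
  best
}

grow_candidates <- function(m, H, Z, sel, pool, lowerbound, alpha) {
  if (!length(pool)) return(NULL)
  ntest <- length(pool) * length(sel)
  crit <- stats::qnorm(1 - alpha / ntest)
  best <- NULL; best_h <- -Inf
  for (x in pool) {
    zx <- Z[x, sel]; hx <- H[x, sel]
    if (anyNA(zx) || anyNA(hx)) next
    if (any(zx <= crit) || any(hx <= 0)) next
    sc <- scale_scalability(m[, c(sel, x), drop = FALSE])
    if (any(is.na(sc$h_item)) || any(sc$h_item < lowerbound)) next
    if (any(sc$h_pair[upper.tri(sc$h_pair)] <= 0, na.rm = TRUE)) next
    if (sc$h_scale > best_h || (sc$h_scale == best_h && x < best)) {
      best <- x; best_h <- sc$h_scale
    }
  }
  best
}

#' Tabulate scale membership
#'
#' Human-readable assignment of every item to a scale id or "unscalable",
#' ordered by scale then by difficulty (easiest first).
#'
#' @param partition a [aisp()] result.
#' @param labels optional replacement item labels.
#' @return Data frame with columns `item`, `scale`, `pct_correct`.
#' @export
scale_membership_table <- function(partition, labels = NULL) {
  stopifnot(inherits(partition, "scale_partition"))
  labs <- if (is.null(labels)) partition$item_labels else labels
  rows <- list()
  for (s in seq_along(partition$scales)) {
    idx <- partition$scales[[s]]
    idx <- idx[order(-partition$popularity[idx], idx)]
    rows[[length(rows) + 1L]] <- data.frame(
      item = labs[idx], scale = as.character(s),
      pct_correct = 100 * partition$popularity[idx])
  }
  idx <- partition$unscalable
  if (length(idx)) {
    idx <- idx[order(-partition$popularity[idx], idx)]
    rows[[length(rows) + 1L]] <- data.frame(
      item = labs[idx], scale = "unscalable",
      pct_correct = 100 * partition$popularity[idx])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.scale_partition <- function(x, ...) {
  cat(sprintf("AISP partition (c = %.2f, alpha = %.2f): %d scale(s), %d unscalable item(s)\n",
              x$lowerbound, x$alpha, length(x$scales), length(x$unscalable)))
  for (s in seq_along(x$scales))
    cat(sprintf("  scale %d (H = %.3f): %s\n", s,
                x$coefficients[[s]]$h_scale,
                paste(names(x$scales[[s]]), collapse = ", ")))
  if (length(x$unscalable))
    cat("  unscalable:", paste(names(x$unscalable), collapse = ", "), "\n")
  invisible(x)
}
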
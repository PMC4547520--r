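#' Check invariant item ordering (manifest method)
#'
#' For every item pair, ordered so that the item with the higher overall
#' proportion correct is the "easier" one (ties by column order), persons
#' are grouped on the rest score over the remaining items (pair excluded)
#' and the conditional proportions compared within each group. Invariant
#' item ordering requires the easier item to stay at least as popular in
#' every group; a reversal exceeding `minvi` is a violation, screened for
#' significance with the same one-sided pooled two-proportion z statistic
#' as the monotonicity check.
#'
#' @param m response matrix with at least 3 items.
#' @param minvi minimum violation size (default 0.03).
#' @param minsize minimum rest-score group size ([default_minsize()]).
#' @param alpha significance level (default 0.05).
#' @return Object of class `iio_violations`: `pairs` data frame (one row
#'   per flagged reversal: `easier`, `harder`, `group`, `magnitude`, `z`,
#'   `significant`) and `item_counts` (per item: total and significant
#'   violations, max magnitude among significant reversals, and `beaten`,
#'   the number of distinct harder items that significantly outperform the
#'   item in some rest-score group — the hallmark of an item response
#'   function descending through the difficulty ordering).
#' @export
check_iio <- function(m, minvi = 0.03, minsize = NULL, alpha = 0.05) {
  m <- as_irm(m)
  if (ncol(m) < 3L) stop("IIO needs at least 3 items")
  n <- nrow(m)
  if (is.null(minsize)) minsize <- default_minsize(n)
  crit <- stats::qnorm(1 - alpha)
  labs <- colnames(m)
  p <- colMeans(m)
  degen <- p %in% c(0, 1)
  if (any(degen))
    warning("degenerate item(s) excluded from IIO: ",
            paste(labs[degen], collapse = ", "))
  use <- which(!degen)
  rows <- list()
  for (ai in seq_along(use)[-length(use)]) {
    for (bi in (ai + 1L):length(use)) {
      i <- use[ai]; j <- use[bi]
      eh <- order_pair(p, i, j)
      rest <- rowSums(m[, -c(i, j), drop = FALSE])
      gr <- rest_groups(rest, minsize)
      if (gr$n_groups < 1L) next
      for (g in seq_len(gr$n_groups)) {
        in_g <- gr$gid == g
        ng <- sum(in_g)
        xe <- sum(m[in_g, eh[1L]])
        xh <- sum(m[in_g, eh[2L]])
        d <- (xh - xe) / ng
        if (d > minvi) {
          z <- two_prop_z(xh, ng, xe, ng)
          rows[[length(rows) + 1L]] <- data.frame(
            easier = labs[eh[1L]], harder = labs[eh[2L]], group = g,
            magnitude = d, z = as.numeric(z),
            significant = z > crit)
        }
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(easier = character(0), harder = character(0),
               group = integer(0), magnitude = numeric(0),
               z = numeric(0), significant = logical(0))
  rownames(pairs) <- NULL
  counts <- data.frame(item = labs,
                       violations = 0L, significant = 0L,
                       max_magnitude = 0, beaten = 0L)
  for (k in seq_len(nrow(pairs))) {
    for (it in c(pairs$easier[k], pairs$harder[k])) {
      w <- match(it, counts$item)
      counts$violations[w] <- counts$violations[w] + 1L
      counts$significant[w] <- counts$significant[w] + pairs$significant[k]
      if (pairs$significant[k])
        counts$max_magnitude[w] <- max(counts$max_magnitude[w],
                                       pairs$magnitude[k])
    }
  }
  sigp <- pairs[pairs$significant, , drop = FALSE]
  counts$beaten <- vapply(counts$item, function(it)
    length(unique(sigp$harder[sigp$easier == it])), integer(1))
  structure(list(pairs = pairs, item_counts = counts, minvi = minvi,
                 minsize = minsize, alpha = alpha),
            class = "iio_violations")
}

#' Backward item elimination for invariant item ordering
#'
#' Iteratively removes the item carrying the largest significant IIO
#' violation, recomputing all pairwise checks on the reduced item set
#' after each removal, until no significant violation remains. A reversal
#' belongs to both items of its pair, so the two members of the worst pair
#' tie on the largest violation; the tie goes to the item that is
#' significantly outperformed by more distinct harder items (its IRF is
#' the one descending through the difficulty ordering), then to the lower
#' column index.
#'
#' @inheritParams check_iio
#' @return Object of class `iio_result`: `retained` (labels), `removed`
#'   (labels in removal order), `removal_trace` data frame (`item`,
#'   `max_violation`, `n_significant` at removal), `ht` (HT coefficient of
#'   the retained set, see [ht_coefficient()]), `final_check` (the last
#'   [check_iio()] result), `minvi`.
#' @examples
#' backward_select_iio(guttman_matrix(40, 4), minsize = 5)
#' @export
backward_select_iio <- function(m, minvi = 0.03, minsize = NULL,
                                alpha = 0.05) {
  m <- as_irm(m)
  keep <- seq_len(ncol(m))
  trace <- list()
  repeat {
    if (length(keep) < 3L) {
      chk <- NULL
      break
    }
    chk <- check_iio(m[, keep, drop = FALSE], minvi = minvi,
                     minsize = minsize, alpha = alpha)
    cnt <- chk$item_counts
    sig <- cnt$significant > 0
    if (!any(sig)) break
    cand <- which(sig)
    cand <- cand[order(-cnt$max_magnitude[cand], -cnt$beaten[cand], cand)]
    worst <- cand[1L]
    trace[[length(trace) + 1L]] <- data.frame(
      item = cnt$item[worst], max_violation = cnt$max_magnitude[worst],
      n_significant = cnt$significant[worst])
    keep <- keep[-match(cnt$item[worst], colnames(m)[keep])]
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(item = character(0), max_violation = numeric(0),
               n_significant = integer(0))
  rownames(trace) <- NULL
  retained <- colnames(m)[keep]
  ht <- if (length(keep) >= 2L)
    ht_coefficient(m[, keep, drop = FALSE]) else NA_real_
  structure(list(retained = retained, removed = trace$item,
                 removal_trace = trace, ht = ht, final_check = chk,
                 minvi = minvi),
            class = "iio_result")
}

#' HT coefficient: accuracy of the item ordering
#'
#' Scalability of the transposed response matrix: persons act as "items"
#' and items as "respondents", so HT quantifies how consistently the item
#' difficulty ordering holds across persons. Persons with all-0 or all-1
#' response vectors carry no ordering information (zero variance after
#' transposition) and are excluded. Interpreted with the same rule of
#' thumb as H ([classify_strength()]).
#'
#' @param m response matrix restricted to the item set of interest.
#' @return Scalar HT (at most 1), or NA when fewer than 2 non-extreme
#'   persons remain.
#' @examples
#' ht_coefficient(guttman_matrix(40, 4))   # 1: perfectly ordered
#' @export
ht_coefficient <- function(m) {
  m <- as_irm(m)
  s <- rowSums(m)
  keep <- s > 0 & s < ncol(m)
  if (sum(keep) < 2L) return(NA_real_)
  tm <- t(unclass(m)[keep, , drop = FALSE])
  colnames(tm) <- paste0("P", seq_len(ncol(tm)))
  scale_scalability(item_response_matrix(tm))$h_scale
}

#' @export
print.iio_result <- function(x, ...) {
  cat(sprintf("IIO backward selection (minvi = %.2f): %d removed, %d retained, HT = %.3f\n",
              x$minvi, length(x$removed), length(x$retained), x$ht))
  if (nrow(x$removal_trace)) print(x$removal_trace)
  invisible(x)
}

#' @export
print.iio_violations <- function(x, ...) {
  cat(sprintf("IIO check (minvi = %.2f): %d flagged reversal(s), %d significant\n",
              x$minvi, nrow(x$pairs), sum(x$pairs$significant)))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}
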
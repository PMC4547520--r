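#' Default minimum rest-score group size
#'
#' Sample-size-dependent convention for the smallest admissible rest-score
#' group: n/10 when n >= 500, n/5 when 250 <= n < 500, otherwise
#' max(n/3, 50) (all floored).
#'
#' @param n number of persons.
#' @export
default_minsize <- function(n) {
  if (n >= 500) floor(n / 10)
  else if (n >= 250) floor(n / 5)
  else max(floor(n / 3), 50)
}

# Merge adjacent rest-score values (ascending) until every group reaches
# minsize; a trailing undersized group is folded into its predecessor.
# Returns per-person group ids (1 = lowest rest scores) and the score
# range of each group.
rest_groups <- function(r, minsize) {
  vals <- sort(unique(r))
  gid <- integer(length(r))
  lo <- hi <- numeric(0)
  g <- 0L; members <- integer(0); start <- NA_real_
  for (v in vals) {
    if (is.na(start)) start <- v
    members <- c(members, which(r == v))
    if (length(members) >= minsize) {
      g <- g + 1L
      gid[members] <- g
      lo <- c(lo, start); hi <- c(hi, v)
      members <- integer(0); start <- NA_real_
    }
  }
  if (length(members)) {
    if (g == 0L) {
      g <- 1L; gid[members] <- 1L
      lo <- start; hi <- max(vals)
    } else {
      gid[members] <- g
      hi[g] <- max(vals)
    }
  }
  list(gid = gid, lo = lo, hi = hi, n_groups = g)
}

# one-sided pooled two-proportion z for a decrease p1 -> p2
two_prop_z <- function(x1, n1, x2, n2) {
  pb <- (x1 + x2) / (n1 + n2)
  d <- x1 / n1 - x2 / n2
  v <- pb * (1 - pb) * (1 / n1 + 1 / n2)
  if (v <= 0) return(0)
  d / sqrt(v)
}

#' Check manifest monotonicity against rest-score groups
#'
#' For each item, persons are grouped by their rest score (total over the
#' other items, adjacent values merged until each group holds at least
#' `minsize` persons) and the conditional proportion correct is compared
#' between every ordered pair of groups. A decrease larger than `minvi`
#' is a violation; each flagged decrease carries a one-sided pooled
#' two-proportion z statistic, deemed significant at `alpha`.
#'
#' @param m response matrix with at least 3 items.
#' @param minvi minimum violation size (default 0.03).
#' @param minsize minimum group size; defaults to [default_minsize()].
#' @param alpha significance level for the z screen (default 0.05).
#' @return Object of class `monotonicity`: `summary` data frame (one row
#'   per item: `item`, `n_groups`, `active` comparisons, `violations`,
#'   `max_violation`, `n_significant`), `violations` data frame (one row
#'   per flagged decrease: `item`, `group_lo`, `group_hi`, `magnitude`,
#'   `z`, `significant`), and `irf` (per-item empirical IRF tables:
#'   rest-score range, group size, proportion correct).
#' @examples
#' check_monotonicity(guttman_matrix(40, 4), minsize = 5)
#' @export
check_monotonicity <- function(m, minvi = 0.03, minsize = NULL,
                               alpha = 0.05) {
  m <- as_irm(m)
  if (ncol(m) < 3L) stop("monotonicity needs at least 3 items")
  n <- nrow(m)
  if (is.null(minsize)) minsize <- default_minsize(n)
  crit <- stats::qnorm(1 - alpha)
  labs <- colnames(m)
  summ <- list(); viol <- list(); irf <- list()
  for (i in seq_len(ncol(m))) {
    r <- rowSums(m[, -i, drop = FALSE])
    gr <- rest_groups(r, minsize)
    if (gr$n_groups < 2L) {
      warning("item ", labs[i], " skipped: fewer than 2 rest-score groups")
      next
    }
    ng <- gr$n_groups
    xs <- tapply(m[, i], gr$gid, sum)
    ns <- tabulate(gr$gid, ng)
    props <- as.numeric(xs) / ns
    irf[[labs[i]]] <- data.frame(rest_lo = gr$lo, rest_hi = gr$hi,
                                 n = ns, prop = props)
    nv <- 0L; maxvi <- 0; nsig <- 0L
    for (g1 in seq_len(ng - 1L)) {
      for (g2 in (g1 + 1L):ng) {
        d <- props[g1] - props[g2]
        if (d > minvi) {
          z <- two_prop_z(xs[g1], ns[g1], xs[g2], ns[g2])
          nv <- nv + 1L
          maxvi <- max(maxvi, d)
          sig <- z > crit
          nsig <- nsig + sig
          viol[[length(viol) + 1L]] <- data.frame(
            item = labs[i], group_lo = g1, group_hi = g2,
            magnitude = d, z = as.numeric(z), significant = sig)
        }
      }
    }
    summ[[length(summ) + 1L]] <- data.frame(
      item = labs[i], n_groups = ng, active = ng * (ng - 1L) / 2L,
      violations = nv, max_violation = maxvi, n_significant = nsig)
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(item = character(0), group_lo = integer(0),
               group_hi = integer(0), magnitude = numeric(0),
               z = numeric(0), significant = logical(0))
  rownames(violations) <- NULL
  structure(list(summary = summary, violations = violations, irf = irf,
                 minvi = minvi, minsize = minsize, alpha = alpha),
            class = "monotonicity")
}

#' @export
print.monotonicity <- function(x, ...) {
  cat(sprintf("Manifest monotonicity (minvi = %.2f, minsize = %d): %d violation(s), %d significant\n",
              x$minvi, x$minsize, nrow(x$violations),
              sum(x$violations$significant)))
  print(x$summary)
  invisible(x)
}
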
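#' Order items by difficulty
#'
#' Easiest first: descending percentage correct, ties broken by the
#' published administration order (`test_order`).
#'
#' @param stats data frame with columns `item`, `pct_correct` and
#'   optionally `test_order` (used only for ties).
#' @return Character vector of item labels, easiest to hardest.
#' @examples
#' fx <- load_nart_fixture()
#' head(order_by_difficulty(fx$mini_items), 1)   # "AISLE"
#' @export
order_by_difficulty <- function(stats) {
  stopifnot(is.data.frame(stats), all(c("item", "pct_correct") %in%
                                        names(stats)))
  if (anyNA(stats$pct_correct)) stop("missing pct_correct values")
  tie <- if ("test_order" %in% names(stats)) stats$test_order
    else seq_len(nrow(stats))
  stats$item[order(-stats$pct_correct, tie)]
}

#' Adaptive administration of an invariantly ordered scale
#'
#' Administers the items of a hierarchical (IIO) scale in difficulty order
#' and stops early once the respondent's position in the hierarchy is
#' established, imputing the unadministered responses by the Guttman
#' completion that IIO licenses. Ascending: items run easiest to hardest
#' and testing stops after `stop_after` consecutive failures, all harder
#' items being imputed as failed. Descending: items run hardest to easiest
#' and testing stops after `stop_after` consecutive successes, all easier
#' items being imputed as passed. The imputed total equals the full-scale
#' total exactly for any respondent whose responses follow the hierarchy.
#'
#' @param ordered_items labels easiest to hardest (see
#'   [order_by_difficulty()]).
#' @param responder function taking an item label and returning 0 or 1.
#' @param direction `"ascending"` or `"descending"`.
#' @param stop_after consecutive confirming responses that end the session
#'   (default 2).
#' @return Object of class `adaptive_session`: `responses` data frame
#'   (`item`, `response`, `observed` flag, in administration-then-imputed
#'   order), `imputed_score`, `n_administered`, `direction`, `stop_after`,
#'   `ordered_items`.
#' @examples
#' fx <- load_nart_fixture()
#' items <- order_by_difficulty(fx$mini_items)
#' s <- run_session(items, guttman_responder(10, items), "descending")
#' s$imputed_score   # 10
#' @export
run_session <- function(ordered_items,
                        responder,
                        direction = c("ascending", "descending"),
                        stop_after = 2L) {
  direction <- match.arg(direction)
  stopifnot(is.function(responder), stop_after >= 1L,
            length(ordered_items) >= 1L)
  seq_items <- if (direction == "ascending") ordered_items
    else rev(ordered_items)
  confirm <- if (direction == "ascending") 0L else 1L
  responses <- integer(0)
  run <- 0L
  administered <- 0L
  for (it in seq_items) {
    r <- responder(it)
    if (!r %in% c(0L, 1L)) stop("responder must return 0 or 1")
    administered <- administered + 1L
    responses <- c(responses, as.integer(r))
    run <- if (r == confirm) run + 1L else 0L
    if (run >= stop_after) break
  }
  n_left <- length(seq_items) - administered
  imputed <- rep(if (direction == "ascending") 0L else 1L, n_left)
  all_resp <- c(responses, imputed)
  df <- data.frame(item = seq_items,
                   response = all_resp,
                   observed = c(rep(TRUE, administered),
                                rep(FALSE, n_left)))
  structure(list(responses = df, imputed_score = sum(all_resp),
                 n_administered = administered, direction = direction,
                 stop_after = as.integer(stop_after),
                 ordered_items = ordered_items),
            class = "adaptive_session")
}

#' @rdname run_session
#' @param true_score number of items a perfectly hierarchical respondent
#'   passes (the `true_score` easiest items).
#' @export
guttman_responder <- function(true_score, ordered_items) {
  stopifnot(true_score >= 0, true_score <= length(ordered_items))
  force(ordered_items)
  function(item) {
    rank <- match(item, ordered_items)
    if (is.na(rank)) stop("unknown item: ", item)
    as.integer(rank <= true_score)
  }
}

#' @export
print.adaptive_session <- function(x, ...) {
  cat(sprintf("Adaptive session (%s, stop after %d): %d of %d items administered, imputed score %d\n",
              x$direction, x$stop_after, x$n_administered,
              length(x$ordered_items), x$imputed_score))
  invisible(x)
}
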
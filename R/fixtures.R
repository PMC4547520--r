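#' Published NART item statistics
#'
#' Returns the packaged item-level statistics of the 50-item National Adult
#' Reading Test in 587 community-dwelling older adults of the Lothian Birth
#' Cohort 1936: per-item percentage correct (higher = easier) and position
#' in the standard administration order, plus the 23-item invariantly
#' ordered subset (the mini-NART) with item scalability coefficients Hi and
#' the subset's scale scalability H.
#'
#' @return A list of class `nart_fixture` with components
#'   \describe{
#'     \item{all_items}{data frame of 50 rows: `item`, `test_order`,
#'       `pct_correct`, ordered easiest to hardest.}
#'     \item{mini_items}{data frame of 23 rows: `item`, `test_order`,
#'       `h_i`, `pct_correct`, ordered easiest to hardest.}
#'     \item{scale_h}{scale scalability H of the mini-NART (0.534).}
#'   }
#' @examples
#' fx <- load_nart_fixture()
#' subset(fx$mini_items, item == "LABILE")
#' @export
load_nart_fixture <- function() {
  all_items <- utils::read.csv(
    system.file("extdata", "nart_table2.csv", package = "mininart",
                mustWork = TRUE))
  mini_items <- utils::read.csv(
    system.file("extdata", "nart_table3.csv", package = "mininart",
                mustWork = TRUE))
  all_items <- all_items[, c("item", "test_order", "pct_correct")]
  mini_items <- mini_items[, c("item", "test_order", "h_i", "pct_correct")]
  stopifnot(
    nrow(all_items) == 50L, nrow(mini_items) == 23L,
    !anyDuplicated(all_items$item),
    all(mini_items$item %in% all_items$item),
    all(all_items$pct_correct >= 0 & all_items$pct_correct <= 100)
  )
  structure(list(all_items = all_items, mini_items = mini_items,
                 scale_h = 0.534),
            class = "nart_fixture")
}

#' @export
print.nart_fixture <- function(x, ...) {
  cat("NART item statistics: 50 items; mini-NART subset of",
      nrow(x$mini_items), "items (H =", x$scale_h, ")\n")
  invisible(x)
}
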
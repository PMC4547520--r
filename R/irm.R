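#' Construct a binary item response matrix
#'
#' The universal input of the package: a persons x items matrix of
#' dichotomous scores (0 = incorrect, 1 = correct) with unique item labels
#' as column names. All analysis functions accept either an `irm` object or
#' any plain matrix/data frame coercible to one.
#'
#' @param x matrix or data frame of 0/1 scores, persons in rows.
#' @param item_labels optional character vector of column labels; defaults
#'   to existing column names, or `I1..Ik` when absent.
#' @return An object of class `irm`: an integer matrix with unique column
#'   names and at least 2 rows and 2 columns.
#' @examples
#' m <- item_response_matrix(rbind(c(1, 1), c(1, 0), c(0, 0)))
#' n_items(m)
#' @export
item_response_matrix <- function(x, item_labels = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("'x' must be a matrix or data frame")
  storage.mode(x) <- "integer"
  if (is.null(item_labels)) {
    item_labels <- colnames(x)
    if (is.null(item_labels)) item_labels <- paste0("I", seq_len(ncol(x)))
  }
  colnames(x) <- item_labels
  validate_irm(x)
  class(x) <- c("irm", "matrix", "array")
  x
}

validate_irm <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("a response matrix needs at least 2 persons and 2 items")
  if (anyNA(x) || !all(x == 0L | x == 1L))
    stop("all entries must be 0 or 1")
  labs <- colnames(x)
  if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs)))
    stop("item labels must be present, non-empty and unique")
  invisible(x)
}

#' @rdname item_response_matrix
#' @export
as_irm <- function(x) {
  if (inherits(x, "irm")) return(x)
  item_response_matrix(x)
}

#' @rdname item_response_matrix
#' @export
n_items <- function(x) ncol(x)

#' @rdname item_response_matrix
#' @export
n_persons <- function(x) nrow(x)

#' @export
print.irm <- function(x, ...) {
  cat(sprintf("Item response matrix: %d persons x %d items\n",
              nrow(x), ncol(x)))
  cat("Items:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read a response matrix from a delimited text file
#'
#' Expects a header row of item labels and one respondent per row. The
#' delimiter (comma or tab) is auto-detected from the header line, and an
#' optional leading respondent-identifier column is auto-detected by
#' non-numeric content and dropped. Under `missing_policy = "listwise"`
#' any row containing an entry other than 0/1 (including blanks and NAs)
#' is dropped with a warning stating the count; under `"error"` such rows
#' abort the read.
#'
#' @param path path to a CSV/TSV file.
#' @param missing_policy `"listwise"` (default, complete-case) or `"error"`.
#' @return An [item_response_matrix()].
#' @export
read_responses <- function(path, missing_policy = c("listwise", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("malformed file: fewer than 2 columns")
  # leading ID column: non-numeric content anywhere in the first column
  first <- df[[1L]]
  if (any(!grepl("^\\s*-?[0-9.]*\\s*$", first))) df <- df[, -1L, drop = FALSE]
  labs <- colnames(df)
  if (anyDuplicated(labs))
    stop("duplicate item labels in header: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)), USE.NAMES = FALSE))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  bad <- apply(vals, 1L, function(r) anyNA(r) || any(r != 0 & r != 1))
  if (any(bad)) {
    if (missing_policy == "error")
      stop(sum(bad), " row(s) contain non-0/1 entries")
    warning(sum(bad), " respondent row(s) dropped (non-0/1 entries, ",
            "listwise deletion)")
    vals <- vals[!bad, , drop = FALSE]
  }
  colnames(vals) <- labs
  item_response_matrix(vals)
}

#' Write a response matrix as CSV
#'
#' Inverse of [read_responses()]: `read_responses(write_responses(m, f))`
#' reproduces `m` exactly.
#'
#' @param m response matrix.
#' @param path output path.
#' @export
write_responses <- function(m, path) {
  m <- as_irm(m)
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
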
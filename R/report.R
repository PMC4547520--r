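report_sections <- c("scales", "coefficients", "monotonicity", "iio",
                     "reliability", "regression")

#' Assemble a machine-readable analysis report
#'
#' Collects the outputs of the analysis stages into a single named list
#' ready for [write_report()]. Any stage may be omitted; its section is
#' then present but explicitly empty.
#'
#' @param partition optional [aisp()] result.
#' @param scalability optional [scale_scalability()] result.
#' @param monotonicity optional [check_monotonicity()] result.
#' @param iio optional [backward_select_iio()] result.
#' @param reliability optional [ms_reliability()] result.
#' @param predictor optional [predictor_model()].
#' @return Named list with the six report sections.
#' @export
assemble_report <- function(partition = NULL, scalability = NULL,
                            monotonicity = NULL, iio = NULL,
                            reliability = NULL, predictor = NULL) {
  rep <- stats::setNames(vector("list", length(report_sections)),
                         report_sections)
  for (s in report_sections) rep[[s]] <- list()
  if (!is.null(partition)) {
    rep$scales <- list(
      scales = lapply(partition$scales, names),
      unscalable = names(partition$unscalable),
      lowerbound = partition$lowerbound, alpha = partition$alpha,
      scale_h = vapply(partition$coefficients, `[[`, numeric(1),
                       "h_scale"))
  }
  if (!is.null(scalability)) {
    rep$coefficients <- list(
      h_scale = scalability$h_scale,
      h_item = as.list(scalability$h_item),
      strength = as.character(scalability$strength),
      n_persons = scalability$n_persons)
    if (!is.na(scalability$se_scale))
      rep$coefficients$se_scale <- scalability$se_scale
  }
  if (!is.null(monotonicity)) {
    rep$monotonicity <- list(summary = monotonicity$summary,
                             violations = monotonicity$violations,
                             minvi = monotonicity$minvi)
  }
  if (!is.null(iio)) {
    rep$iio <- list(retained = iio$retained, removed = iio$removed,
                    removal_trace = iio$removal_trace, minvi = iio$minvi)
    if (!is.na(iio$ht)) rep$iio$ht <- iio$ht
  }
  if (!is.null(reliability)) {
    rep$reliability <- list(ms = reliability$ms,
                            reliable = reliability$reliable_flag)
  }
  if (!is.null(predictor)) {
    rep$regression <- list(label = predictor$label,
                           intercept = predictor$intercept,
                           slope = predictor$slope,
                           slope_ci = predictor$slope_ci,
                           r_squared = predictor$r_squared,
                           n = predictor$n)
  }
  rep
}

#' Write / read an analysis report as JSON
#'
#' The report persists losslessly: reading a written report and writing it
#' again produces an identical file. Sections missing from `results` are
#' added as explicit empty sections.
#'
#' @param results named list, typically from [assemble_report()].
#' @param path output path.
#' @export
write_report <- function(results, path) {
  stopifnot(is.list(results))
  for (s in setdiff(report_sections, names(results)))
    results[[s]] <- list()
  con <- try(jsonlite::write_json(results, path, auto_unbox = TRUE,
                                  digits = NA, null = "list",
                                  na = "null", pretty = TRUE),
             silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write report to ", path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no report at ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
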
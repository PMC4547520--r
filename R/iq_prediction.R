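#' Predictor models linking scale scores to criterion IQ
#'
#' A `predictor_model` couples an intercept and slope (IQ points per raw
#' score unit) with the 95% confidence interval of the slope and the
#' variance accounted for. [mini_nart_predictor()] and [nart_predictor()]
#' return the published regression models estimating age-11 IQ from the
#' 23-item mini-NART and the full 50-item NART in the Lothian Birth Cohort
#' 1936 (n = 587):
#' \preformatted{
#'   mini-NART: IQ = 64.94 + 2.345 x score, slope 95% CI [2.13, 2.56]
#'   NART:      IQ = 55.97 + 1.306 x score, slope 95% CI [1.19, 1.42]
#' }
#'
#' @param intercept,slope regression coefficients.
#' @param slope_ci length-2 numeric, 95% CI of the slope.
#' @param r_squared variance accounted for, in [0, 1].
#' @param n fitting sample size.
#' @param label scale name.
#' @param max_score maximum raw score of the scale.
#' @param fit optional underlying `lm` fit (kept by [fit_predictor()] so
#'   that [predict_iq()] can produce standard prediction intervals).
#' @return Object of class `predictor_model`.
#' @export
predictor_model <- function(intercept, slope, slope_ci, r_squared = NA,
                            n = NA, label = "scale", max_score = Inf,
                            fit = NULL) {
  stopifnot(length(slope_ci) == 2L, slope_ci[1L] <= slope,
            slope <= slope_ci[2L])
  structure(list(intercept = intercept, slope = slope,
                 slope_ci = as.numeric(slope_ci), r_squared = r_squared,
                 n = n, label = label, max_score = max_score, fit = fit),
            class = "predictor_model")
}

#' @rdname predictor_model
#' @export
mini_nart_predictor <- function() {
  predictor_model(64.94, 2.345, c(2.13, 2.56), r_squared = 0.448,
                  n = 587, label = "mini-NART", max_score = 23)
}

#' @rdname predictor_model
#' @export
nart_predictor <- function() {
  predictor_model(55.97, 1.306, c(1.19, 1.42), r_squared = 0.465,
                  n = 587, label = "NART", max_score = 50)
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("%s predictor: IQ = %.2f + %.3f x score, slope 95%% CI [%.2f, %.2f]\n",
              x$label, x$intercept, x$slope, x$slope_ci[1L],
              x$slope_ci[2L]))
  if (!is.na(x$r_squared))
    cat(sprintf("  variance accounted for: %.1f%%%s\n",
                100 * x$r_squared,
                if (is.na(x$n)) "" else sprintf(" (n = %d)", x$n)))
  invisible(x)
}

#' Fit a criterion regression for a scale
#'
#' Ordinary least squares of a per-person criterion IQ on per-person scale
#' scores, returning a [predictor_model()] whose `slope_ci` is the 95%
#' confidence interval of the slope and whose `r_squared` is the variance
#' accounted for.
#'
#' @param scores numeric vector of raw scale scores.
#' @param criterion numeric vector of criterion IQ, same length.
#' @param label scale name for the model.
#' @param max_score scale maximum; defaults to `max(scores)`.
#' @export
fit_predictor <- function(scores, criterion, label = "scale",
                          max_score = max(scores)) {
  stopifnot(length(scores) == length(criterion), length(scores) >= 3L)
  if (stats::sd(scores) == 0)
    stop("scores are constant: slope undefined")
  fit <- stats::lm(criterion ~ scores)
  ci <- stats::confint(fit, "scores", level = 0.95)
  predictor_model(unname(stats::coef(fit)[1L]),
                  unname(stats::coef(fit)[2L]),
                  as.numeric(ci), r_squared = summary(fit)$r.squared,
                  n = length(scores), label = label,
                  max_score = max_score, fit = fit)
}

#' Predict criterion IQ from a raw scale score
#'
#' Point estimate `intercept + slope x score`. The default interval follows
#' the published convention of applying the slope's 95% CI with a fixed
#' intercept: `intercept + slope_ci x score`, so the CI width grows
#' linearly in the score and collapses to the intercept at score 0. For
#' models produced by [fit_predictor()], `interval = "prediction"` instead
#' returns a conventional 95% prediction interval for a new observation.
#'
#' @param model a [predictor_model()].
#' @param score raw score(s), each in `[0, max_score]`.
#' @param interval `"slope"` (published convention, default) or
#'   `"prediction"`.
#' @return Object of class `iq_estimate`: list of vectors `score`,
#'   `point`, `ci_low`, `ci_high` (unrounded; round at presentation).
#' @examples
#' predict_iq(mini_nart_predictor(), 20)   # 111.84 [107.54, 116.14]
#' @export
predict_iq <- function(model, score, interval = c("slope", "prediction")) {
  stopifnot(inherits(model, "predictor_model"))
  interval <- match.arg(interval)
  if (any(score < 0 | score > model$max_score))
    stop(sprintf("score out of range: %s scores run from 0 to %s",
                 model$label, format(model$max_score)))
  point <- model$intercept + model$slope * score
  if (interval == "slope") {
    lo <- model$intercept + model$slope_ci[1L] * score
    hi <- model$intercept + model$slope_ci[2L] * score
  } else {
    if (is.null(model$fit))
      stop("prediction intervals need a model from fit_predictor()")
    pr <- stats::predict(model$fit, newdata = data.frame(scores = score),
                         interval = "prediction", level = 0.95)
    lo <- pr[, "lwr"]; hi <- pr[, "upr"]
  }
  structure(list(score = score, point = point, ci_low = unname(lo),
                 ci_high = unname(hi), label = model$label),
            class = "iq_estimate")
}

#' @export
print.iq_estimate <- function(x, ...) {
  for (k in seq_along(x$score))
    cat(sprintf("%s score %g -> predicted IQ %.2f, 95%% CI [%.2f, %.2f]\n",
                x$label, x$score[k], x$point[k], x$ci_low[k],
                x$ci_high[k]))
  invisible(x)
}

#' Score-to-IQ conversion table
#'
#' One row per integer raw score from 0 to `max_score`, with the point
#' prediction, its interval, and the point rounded to the nearest integer
#' IQ.
#'
#' @param model a [predictor_model()].
#' @param max_score table ceiling; defaults to the model's scale maximum.
#' @return Data frame with columns `score`, `predicted_iq`, `ci_low`,
#'   `ci_high`, `iq_rounded`.
#' @examples
#' tail(conversion_table(mini_nart_predictor()), 1)$iq_rounded   # 119
#' @export
conversion_table <- function(model, max_score = model$max_score) {
  stopifnot(is.finite(max_score), max_score >= 1)
  s <- 0:max_score
  est <- predict_iq(model, s)
  data.frame(score = s, predicted_iq = est$point, ci_low = est$ci_low,
             ci_high = est$ci_high, iq_rounded = round(est$point))
}

#' Pearson correlation between scale scores and a criterion
#'
#' @param scores,criterion paired numeric vectors, at least 3 observations.
#' @return Pearson r, or NA (with a warning) when either side has zero
#'   variance.
#' @export
criterion_correlation <- function(scores, criterion) {
  stopifnot(length(scores) == length(criterion), length(scores) >= 3L)
  if (stats::sd(scores) == 0 || stats::sd(criterion) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(scores, criterion)
}
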
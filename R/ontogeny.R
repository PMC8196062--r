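#' Linear trend of a kinematic response on age
#'
#' Ordinary least-squares regression of a per-larva kinematic summary (mean
#' instantaneous swimming speed or mean turning angle) on age in days
#' post-hatch, with the 95% confidence band on the mean prediction from the
#' t distribution. One row per larva enters the fit.
#'
#' @param results Data frame with columns `age_dph` and the response column
#'   (`mean_speed_cm_s` for `"speed"`, `mean_turning_deg` for `"turning"`).
#' @param response `"speed"` or `"turning"`.
#' @return A `trend_fit` list: `response`, `slope`, `intercept`,
#'   `test_stat` (t statistic of the slope), `df`, `p`, `ci95_band`
#'   (function of an age vector returning a data frame
#'   `age_dph, fit, lwr, upr`), and the underlying `lm` fit as `model`.
#' @export
fit_linear_trend <- function(results, response = c("speed", "turning")) {
  response <- match.arg(response)
  col <- c(speed = "mean_speed_cm_s", turning = "mean_turning_deg")[[response]]
  stopifnot(all(c("age_dph", col) %in% names(results)))
  d <- results[!is.na(results[[col]]) & !is.na(results$age_dph), ]
  if (nrow(d) < 3) stop("fit_linear_trend: need >= 3 larvae")
  if (length(unique(d$age_dph)) < 2) {
    stop("fit_linear_trend: all ages identical; slope is not identifiable")
  }
  d$.y <- d[[col]]
  fit <- stats::lm(.y ~ age_dph, data = d)
  sm <- summary(fit)
  structure(
    list(
      response = response,
      slope = unname(stats::coef(fit)["age_dph"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      test_stat = sm$coefficients["age_dph", "t value"],
      df = fit$df.residual,
      p = sm$coefficients["age_dph", "Pr(>|t|)"],
      ci95_band = function(age_dph) {
        pr <- stats::predict(fit, newdata = data.frame(age_dph = age_dph),
                             interval = "confidence", level = 0.95)
        data.frame(age_dph = age_dph, fit = pr[, "fit"],
                   lwr = pr[, "lwr"], upr = pr[, "upr"])
      },
      model = fit
    ),
    class = "trend_fit"
  )
}

#' Logistic regression of orientation success on age
#'
#' Models the probability that a larva orients (classification `oriented`
#' versus `non_oriented` or `device_biased`) as a function of age via
#' binomial logistic regression, and reports the likelihood-ratio chi-square
#' test of the age effect against the intercept-only model (df = 1).
#' Complete separation (or a single outcome class) makes the slope estimate
#' diverge; such fits are flagged `separation = TRUE` and their statistics
#' marked unreliable.
#'
#' @param results Data frame with columns `age_dph` and `classification`.
#' @return A `trend_fit` list: `response = "oriented"`, `slope`,
#'   `intercept` (log-odds scale), `test_stat` (LR chi-square), `df`, `p`,
#'   `separation`, `prop_oriented`, and the `glm` fit as `model`.
#' @export
fit_orientation_logistic <- function(results) {
  stopifnot(all(c("age_dph", "classification") %in% names(results)))
  d <- results[!is.na(results$age_dph), ]
  d$oriented <- as.integer(d$classification == "oriented")
  if (length(unique(d$oriented)) < 2) {
    warning("fit_orientation_logistic: single outcome class; flagged as separation")
    return(structure(
      list(response = "oriented", slope = NA_real_, intercept = NA_real_,
           test_stat = NA_real_, df = 1L, p = NA_real_, separation = TRUE,
           prop_oriented = mean(d$oriented), model = NULL),
      class = "trend_fit"
    ))
  }
  fit <- suppressWarnings(
    stats::glm(oriented ~ age_dph, family = stats::binomial(), data = d)
  )
  # diverging fitted probabilities signal (quasi-)complete separation
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    abs(stats::coef(fit)["age_dph"]) > 15
  lr <- fit$null.deviance - fit$deviance
  structure(
    list(
      response = "oriented",
      slope = unname(stats::coef(fit)["age_dph"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      test_stat = lr,
      df = 1L,
      p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
      separation = separation,
      prop_oriented = mean(d$oriented),
      model = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  if (isTRUE(x$separation)) {
    cat(sprintf("<trend_fit> %s ~ age: complete separation, statistics unreliable\n",
                x$response))
    return(invisible(x))
  }
  cat(sprintf(
    "<trend_fit> %s ~ age: slope %.4g, intercept %.4g, stat %.3g (df = %d), p = %.3g\n",
    x$response, x$slope, x$intercept, x$test_stat, x$df, x$p
  ))
  invisible(x)
}

#' Export a fitted trend curve on an age grid
#'
#' Evaluates the point prediction and 95% band of a linear [fit_linear_trend()]
#' on a grid of ages, for plotting or CSV export.
#'
#' @param fit A `trend_fit` from [fit_linear_trend()].
#' @param ages Age grid, days post-hatch.
#' @return Data frame `age_dph, fit, lwr, upr`.
#' @export
trend_curve <- function(fit, ages = seq(2, 30, by = 0.5)) {
  stopifnot(inherits(fit, "trend_fit"), !is.null(fit$ci95_band))
  fit$ci95_band(ages)
}
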
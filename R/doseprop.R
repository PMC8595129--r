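# Power-model dose-proportionality analysis: ln(PK parameter) regressed on
# ln(dose); the slope's departure from 1 is summarised by the
# dose-normalized ratio Rdnm = r^(slope - 1), r the ratio of highest to
# lowest dose, and classified against bioequivalence-style bounds.

#' Geometric mean from an arithmetic mean and SD
#'
#' Converts a reported `mean +/- SD` summary to a geometric mean under a
#' lognormal assumption: `GM = mean / sqrt(1 + (SD/mean)^2)`. Always
#' `<= mean`.
#'
#' @param mean Arithmetic mean(s), > 0.
#' @param sd Standard deviation(s), >= 0.
#' @return Geometric mean(s).
#' @export
#' @examples
#' gm_from_summary(122.04, 17.27)  # 120.84
gm_from_summary <- function(mean, sd) {
  if (any(!is.finite(mean) | mean <= 0)) {
    stop("mean must be > 0", call. = FALSE)
  }
  if (any(!is.finite(sd) | sd < 0)) stop("sd must be >= 0", call. = FALSE)
  mean / sqrt(1 + (sd / mean)^2)
}

#' Fit the dose-proportionality power model
#'
#' Ordinary least squares of `ln(value)` on `ln(dose)`. Individual-level
#' input uses every observation; summary-level input (columns `mean` and
#' `sd`) is first converted to one geometric mean per dose via
#' [gm_from_summary()]. The confidence interval uses the t distribution
#' with the fit's residual degrees of freedom and is reported as `NA` when
#' fewer than one residual degree of freedom remains.
#'
#' @param data A data.frame with columns `dose` and `value`
#'   (individual-level), or `dose`, `mean`, `sd` and optionally `n`
#'   (summary-level).
#' @param parameter Label of the analysed parameter (for reporting).
#' @param alpha Two-sided significance level for the CI (default 0.10,
#'   i.e. a 90% CI).
#' @return An object of class `power_model_fit`: `slope`, `slope_ci`,
#'   `intercept`, `r` (dose ratio), `rdnm`, `rdnm_ci`,
#'   `predicted_gm` (fitted geometric means at the lowest and highest
#'   dose), `df`, `alpha`, `n`, `parameter`.
#' @export
#' @examples
#' s <- data.frame(dose = c(11.5, 23, 46),
#'                 mean = c(122.04, 232.87, 415.38),
#'                 sd = c(17.27, 18.14, 22.21))
#' fit <- fit_power_model(s, parameter = "auc_inf")
#' round(fit$slope, 2)  # 0.89
fit_power_model <- function(data, parameter = "value", alpha = 0.10) {
  stopifnot(is.data.frame(data), "dose" %in% names(data))
  summary_mode <- all(c("mean", "sd") %in% names(data))
  if (summary_mode) {
    if (anyDuplicated(data$dose)) {
      stop("summary input must have one row per dose", call. = FALSE)
    }
    y <- log(gm_from_summary(data$mean, data$sd))
    x <- log(data$dose)
  } else {
    if (!"value" %in% names(data)) {
      stop("need a 'value' column (or 'mean' and 'sd')", call. = FALSE)
    }
    if (any(!is.finite(data$value) | data$value <= 0)) {
      stop("values must be positive", call. = FALSE)
    }
    y <- log(data$value)
    x <- log(data$dose)
  }
  if (length(unique(data$dose)) < 2) {
    stop("need at least 2 distinct doses", call. = FALSE)
  }
  if (any(!is.finite(data$dose) | data$dose <= 0)) {
    stop("doses must be positive", call. = FALSE)
  }

  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  intercept <- coef(fit)[[1]]
  df <- fit$df.residual
  if (df >= 1) {
    se <- sqrt(sum(fit$residuals^2) / df / sum((x - mean(x))^2))
    tcrit <- qt(1 - alpha / 2, df)
    ci <- slope + c(-1, 1) * tcrit * se
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  r <- max(data$dose) / min(data$dose)
  structure(list(
    parameter = parameter,
    slope = slope, slope_ci = ci, intercept = intercept,
    r = r,
    rdnm = r^(slope - 1),
    rdnm_ci = r^(ci - 1),
    predicted_gm = exp(intercept + slope * log(range(data$dose))),
    df = df, alpha = alpha, n = length(y)
  ), class = "power_model_fit")
}

#' @export
print.power_model_fit <- function(x, ...) {
  lvl <- 100 * (1 - x$alpha)
  fmt_ci <- function(ci) {
    if (any(is.na(ci))) "CI n/a" else sprintf("(%.2f, %.2f)", ci[1], ci[2])
  }
  cat(sprintf("<power_model_fit> %s, n = %d, dose ratio r = %g\n",
              x$parameter, x$n, x$r))
  cat(sprintf("  slope %.2f %s [%g%% CI]; Rdnm %.2f %s\n",
              x$slope, fmt_ci(x$slope_ci), lvl, x$rdnm, fmt_ci(x$rdnm_ci)))
  cat(sprintf("  predicted GM at dose extremes: (%.2f, %.2f)\n",
              x$predicted_gm[1], x$predicted_gm[2]))
  invisible(x)
}

#' Dose-normalized ratio from a power-model fit
#'
#' `Rdnm = r^(slope - 1)`, with CI endpoints `r^(CI_slope - 1)`.
#'
#' @param fit A [fit_power_model()] object.
#' @return List with `estimate`, `ci` and `r`.
#' @export
rdnm <- function(fit) {
  stopifnot(inherits(fit, "power_model_fit"))
  list(estimate = fit$r^(fit$slope - 1),
       ci = fit$r^(fit$slope_ci - 1),
       r = fit$r)
}

#' Classify dose proportionality
#'
#' Interval-inclusion rule on the Rdnm confidence interval:
#' `"proportional"` when the CI lies inside the acceptance bounds,
#' `"nonproportional"` when it lies entirely outside, `"inconclusive"`
#' otherwise (including when the CI is unavailable).
#'
#' @param fit A [fit_power_model()] object, or a length-2 numeric Rdnm CI.
#' @param bounds Acceptance interval on Rdnm (default `c(0.80, 1.25)`).
#' @return `"proportional"`, `"inconclusive"` or `"nonproportional"`.
#' @export
#' @examples
#' classify_proportionality(c(0.75, 0.99))  # "inconclusive"
classify_proportionality <- function(fit, bounds = c(0.80, 1.25)) {
  if (length(bounds) != 2 || !all(is.finite(bounds)) ||
      bounds[1] >= bounds[2]) {
    stop("bounds must be a finite interval with low < high", call. = FALSE)
  }
  ci <- if (inherits(fit, "power_model_fit")) fit$rdnm_ci else fit
  if (length(ci) != 2 || any(is.na(ci))) return("inconclusive")
  ci <- sort(ci)
  if (ci[1] >= bounds[1] && ci[2] <= bounds[2]) return("proportional")
  if (ci[2] < bounds[1] || ci[1] > bounds[2]) return("nonproportional")
  "inconclusive"
}

#' Dose-proportionality report for an NCA table
#'
#' Fits the power model for each requested parameter on individual-level
#' NCA output and reports slope, Rdnm, CIs and classification in the
#' layout of a standard dose-proportionality summary table.
#'
#' @param tab An [nca_table()] data.frame (needs `dose_mg_kg` and the
#'   parameter columns).
#' @param params Parameter columns to analyse.
#' @param alpha Two-sided CI level (default 0.10).
#' @param bounds Rdnm acceptance bounds.
#' @return A data.frame, one row per parameter.
#' @export
doseprop_table <- function(tab, params = c("auc_inf", "cmax"), alpha = 0.10,
                           bounds = c(0.80, 1.25)) {
  rows <- lapply(params, function(p) {
    d <- data.frame(dose = tab$dose_mg_kg, value = tab[[p]])
    d <- d[is.finite(d$value) & d$value > 0, ]
    fit <- fit_power_model(d, parameter = p, alpha = alpha)
    data.frame(
      parameter = p,
      predicted_gm_low = fit$predicted_gm[1],
      predicted_gm_high = fit$predicted_gm[2],
      slope = fit$slope,
      slope_ci_low = fit$slope_ci[1], slope_ci_high = fit$slope_ci[2],
      rdnm = fit$rdnm,
      rdnm_ci_low = fit$rdnm_ci[1], rdnm_ci_high = fit$rdnm_ci[2],
      conclusion = classify_proportionality(fit, bounds),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
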
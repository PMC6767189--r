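# Linear regression with full ANOVA decomposition and 95% bands, the F-test
# survival function, the isobaric thermal expansion coefficient from
# ln(density) vs temperature, and glass-transition (Tg) detection as the
# breakpoint of a continuous two-segment fit.

#' Ordinary least squares with ANOVA decomposition and 95% bands
#'
#' Fits `y = intercept + slope * x` and reports the classical one-way ANOVA
#' decomposition about the mean (model/error/total sums of squares and
#' degrees of freedom), the F statistic for the zero-slope hypothesis with
#' df (1, n-2) and its two-sided upper-tail p-value, and evaluators for
#' pointwise 95% confidence (mean response) and prediction (new observation)
#' bands based on the t quantile.
#'
#' Internal identities (held to floating-point accuracy): `sse_total =
#' sse_model + sse_error`, `df_total = df_model + df_error`, `f_value =
#' mse_model / mse_error`. For an exact fit the p-value is clamped to the
#' smallest positive double so that it stays in (0, 1].
#'
#' @param x,y Numeric vectors, length >= 3; `x` must not be constant.
#' @return A `regression_fit` list: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `df_model`, `df_error`, `df_total`, `sse_model`,
#'   `sse_error`, `sse_total`, `mse_model`, `mse_error`, `f_value`, `p_value`,
#'   `n`, `fitted`, `residuals`, and band evaluators `confidence_band(x0)` and
#'   `prediction_band(x0)` returning data frames with `fit`, `lwr`, `upr`.
#' @export
linear_fit_anova <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate x: all values equal", call. = FALSE)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * x
  residuals <- y - fitted
  sse_error <- sum(residuals^2)
  sse_total <- sum((y - ybar)^2)
  sse_model <- slope^2 * sxx
  df_model <- 1L; df_error <- n - 2L; df_total <- n - 1L
  mse_model <- sse_model / df_model
  mse_error <- sse_error / df_error
  f_value <- if (mse_error == 0) Inf else mse_model / mse_error
  p_value <- max(stats::pf(f_value, df_model, df_error, lower.tail = FALSE),
                 .Machine$double.xmin)
  slope_se <- sqrt(mse_error / sxx)
  intercept_se <- sqrt(mse_error * (1 / n + xbar^2 / sxx))
  tq <- stats::qt(0.975, df_error)
  band <- function(x0, predict = FALSE) {
    lev <- 1 / n + (x0 - xbar)^2 / sxx
    if (predict) lev <- lev + 1
    half <- tq * sqrt(mse_error * lev)
    fit0 <- intercept + slope * x0
    data.frame(x = x0, fit = fit0, lwr = fit0 - half, upr = fit0 + half)
  }
  structure(list(slope = slope, intercept = intercept,
                 slope_se = slope_se, intercept_se = intercept_se,
                 df_model = df_model, df_error = df_error, df_total = df_total,
                 sse_model = sse_model, sse_error = sse_error,
                 sse_total = sse_total, mse_model = mse_model,
                 mse_error = mse_error, f_value = f_value, p_value = p_value,
                 n = n, fitted = fitted, residuals = residuals,
                 confidence_band = function(x0) band(x0, FALSE),
                 prediction_band = function(x0) band(x0, TRUE)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("<regression_fit>\n")
  cat(sprintf("  slope %.6g +/- %.3g, intercept %.6g +/- %.3g (n = %d)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se, x$n))
  cat(sprintf("  %-6s %3s %12s %12s %10s %s\n", "", "DF", "SSE", "MSE", "F",
              "p"))
  cat(sprintf("  %-6s %3d %12.5g %12.5g %10.5g %.5g\n", "Model", x$df_model,
              x$sse_model, x$mse_model, x$f_value, x$p_value))
  cat(sprintf("  %-6s %3d %12.5g %12.5g\n", "Error", x$df_error, x$sse_error,
              x$mse_error))
  cat(sprintf("  %-6s %3d %12.5g\n", "Total", x$df_total, x$sse_total))
  invisible(x)
}

#' ANOVA table of a regression fit
#'
#' Returns the fit's decomposition as a data frame whose columns mirror the
#' conventional ANOVA layout (DF, SSE, MSE, F Value, p-Value).
#'
#' @param fit A `regression_fit`.
#' @return Data frame with rows Model, Error, Total.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  data.frame(term = c("Model", "Error", "Total"),
             DF = c(fit$df_model, fit$df_error, fit$df_total),
             SSE = c(fit$sse_model, fit$sse_error, fit$sse_total),
             MSE = c(fit$mse_model, fit$mse_error, NA),
             `F Value` = c(fit$f_value, NA, NA),
             `p-Value` = c(fit$p_value, NA, NA),
             check.names = FALSE)
}

#' Upper-tail probability of the F distribution
#'
#' Survival function used for the zero-slope F test p-values.
#'
#' @param f_value Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return P(F >= f_value).
#' @examples
#' f_sf(47.56219, 1, 40)   # 2.61381e-08
#' @export
f_sf <- function(f_value, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1",
                                         call. = FALSE)
  stopifnot(all(f_value >= 0))
  stats::pf(f_value, df1, df2, lower.tail = FALSE)
}

#' Isobaric thermal expansion coefficient from a thermo series
#'
#' For a system of fixed mass, \eqn{\alpha_p = (1/V)(\partial V/\partial T)_p
#' = -(\partial \ln\rho/\partial T)_p}; the coefficient is estimated as minus
#' the OLS slope of `ln(density)` on temperature, with the full ANOVA fit
#' attached. Invariant to rescaling the density by any positive constant.
#'
#' @param series A [thermo_series] (or data frame) with `temperature` (K) and
#'   positive `density` columns; >= 3 records.
#' @return An `expansion_result`: `alpha_p` (1/K), `alpha_se` (1/K), `fit`.
#' @export
expansion_coefficient <- function(series) {
  stopifnot(!is.null(series$temperature), !is.null(series$density))
  if (any(series$density <= 0)) {
    stop("non-positive density at record ",
         which(series$density <= 0)[1], call. = FALSE)
  }
  fit <- linear_fit_anova(series$temperature, log(series$density))
  structure(list(alpha_p = -fit$slope, alpha_se = fit$slope_se, fit = fit),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("<expansion_result> alpha_p = %.6g +/- %.3g 1/K\n",
              x$alpha_p, x$alpha_se))
  invisible(x)
}

.two_segment_sse <- function(temps, values, bp) {
  # continuous hinge model: y = a + b1 (t - bp) + (b2 - b1) max(t - bp, 0)
  X <- cbind(1, temps - bp, pmax(temps - bp, 0))
  fit <- stats::lm.fit(X, values)
  list(sse = sum(fit$residuals^2),
       left_slope = fit$coefficients[2],
       right_slope = fit$coefficients[2] + fit$coefficients[3],
       value_at_bp = fit$coefficients[1])
}

#' Glass-transition temperature by continuous two-segment regression
#'
#' Dilatometric Tg detection: fits a continuous piecewise-linear model with a
#' single breakpoint to specific volume vs temperature, choosing the
#' breakpoint that minimizes total SSE. Candidates are the midpoints between
#' consecutive interior temperatures (each side keeping >= 3 points), and the
#' best candidate is refined by golden-section search to 0.1 K.
#'
#' A pure straight line has no meaningful knee: when the SSE improvement of
#' the two-segment model over a single line falls below `flat_threshold`
#' (relative), the fit is flagged unreliable.
#'
#' @param temps Sorted temperatures in K (>= 6 points).
#' @param specific_volume Specific volume in cm^3/g, same length.
#' @param flat_threshold Relative SSE-improvement threshold below which the
#'   breakpoint is flagged unreliable.
#' @return A `tg_fit`: `breakpoint` (K), `left_slope`, `right_slope`
#'   (cm^3/(g K)), `sse`, `sse_one_segment`, `reliable` flag.
#' @export
glass_transition <- function(temps, specific_volume, flat_threshold = 0.05) {
  stopifnot(length(temps) == length(specific_volume), length(temps) >= 6L)
  if (is.unsorted(temps, strictly = FALSE)) {
    stop("temps must be sorted increasing", call. = FALSE)
  }
  n <- length(temps)
  # candidate breakpoints: midpoints with >= 3 points strictly on each side
  cand <- (temps[-1] + temps[-n]) / 2
  cand <- cand[vapply(cand, function(b)
    sum(temps < b) >= 3L && sum(temps > b) >= 3L, TRUE)]
  if (!length(cand)) {
    stop("fewer than 3 points per side for every candidate breakpoint",
         call. = FALSE)
  }
  sse_of <- function(b) .two_segment_sse(temps, specific_volume, b)$sse
  sses <- vapply(cand, sse_of, 1.0)
  best <- which.min(sses)
  lo <- if (best > 1L) cand[best - 1L] else max(temps[temps < cand[best]])
  hi <- if (best < length(cand)) cand[best + 1L] else
    min(temps[temps > cand[best]])
  opt <- stats::optimize(sse_of, lower = lo, upper = hi, tol = 0.01)
  bp <- opt$minimum
  if (sum(temps < bp) < 3L || sum(temps > bp) < 3L) {
    stop("fewer than 3 points per side at the optimum breakpoint",
         call. = FALSE)
  }
  seg <- .two_segment_sse(temps, specific_volume, bp)
  one <- linear_fit_anova(temps, specific_volume)
  # a single line that already fits to numerical precision has no knee
  improvement <- if (one$sse_error > 1e-12 * one$sse_total) {
    (one$sse_error - seg$sse) / one$sse_error
  } else 0
  structure(list(breakpoint = bp, left_slope = unname(seg$left_slope),
                 right_slope = unname(seg$right_slope), sse = seg$sse,
                 sse_one_segment = one$sse_error,
                 improvement = improvement,
                 reliable = improvement >= flat_threshold),
            class = "tg_fit")
}

#' @export
print.tg_fit <- function(x, ...) {
  cat(sprintf("<tg_fit> Tg = %.1f K (slopes %.4g -> %.4g cm^3/(g K))%s\n",
              x$breakpoint, x$left_slope, x$right_slope,
              if (x$reliable) "" else "  [unreliable: no clear knee]"))
  invisible(x)
}
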
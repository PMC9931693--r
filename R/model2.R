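#' Model II (major-axis / standardized major-axis) linear regression
#'
#' Both the fat-meter reading and the measured whole-body lipid content carry
#' measurement error, so an errors-in-both-variables line is appropriate. Two
#' classical estimators are provided in closed form:
#'
#' * **MA** (major axis) minimizes perpendicular distances to the line; slope
#'   \eqn{b = (s_{yy} - s_{xx} + \sqrt{(s_{yy}-s_{xx})^2 + 4 s_{xy}^2}) / (2 s_{xy})}.
#' * **SMA** (standardized major axis) minimizes the summed triangular areas
#'   between points and line; slope \eqn{b = \mathrm{sign}(r)\, s_y / s_x}.
#'
#' SMA is the default because reading (meter units) and lipid (percent) are on
#' different scales, where MA is not scale-invariant. The intercept passes the
#' line through the centroid in either case. Fit quality (`r2_adj`,
#' `residual_se`) is reported from vertical residuals so that the three model
#' families ranked by [rank_calibrations()] share one yardstick.
#'
#' @param x Predictor (fat-meter readings).
#' @param y Response (whole-body lipid, percent).
#' @param method `"SMA"` (default) or `"MA"`.
#' @param log_x Regress on `log(x)` instead of `x` (requires `x > 0`).
#' @return An object of class `linear_fit`: list with `slope`, `intercept`,
#'   `method`, `log_transformed_x`, `n`, `r2_adj`, `residual_se`.
#' @examples
#' x <- c(1, 2, 3, 4, 5)
#' fit_model2(x, 2 * x + 1)
#' @export
fit_model2 <- function(x, y, method = c("SMA", "MA"), log_x = FALSE) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("model II regression needs at least 3 complete pairs")
  if (log_x) {
    if (any(x <= 0)) stop("log_x requires strictly positive x")
    x <- log(x)
  }
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) stop("zero variance in x or y")
  r <- sxy / sqrt(sxx * syy)
  slope <- switch(method,
    SMA = sign(if (r == 0) 1 else r) * sqrt(syy / sxx),
    MA  = if (sxy == 0) stop("MA slope undefined for zero covariance") else
      (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy))
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  rss <- sum(res^2); tss <- syy * (n - 1)
  structure(list(
    slope = slope, intercept = intercept, method = method,
    log_transformed_x = log_x, n = n,
    r2_adj = 1 - (rss / (n - 2)) / (tss / (n - 1)),
    residual_se = sqrt(rss / (n - 2))
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  lab <- if (isTRUE(x$log_transformed_x)) "log(reading)" else "reading"
  cat(sprintf("Model II (%s) fit: lipid = %.4f + %.4f * %s\n",
              x$method, x$intercept, x$slope, lab))
  cat(sprintf("  n = %d, adj. R2 = %.4f, residual SE = %.4f\n",
              x$n, x$r2_adj, x$residual_se))
  invisible(x)
}
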
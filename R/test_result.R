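#' Lightweight container for hypothesis-test output
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (length 1 or 2).
#' @param p_value p-value in `[0, 1]`.
#' @param method Human-readable label.
#' @param estimate Optional named estimates (e.g. group means).
#' @return Object of class `test_result`.
#' @keywords internal
#' @export
test_result <- function(statistic, df, p_value, method, estimate = NULL) {
  if (is.finite(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 estimate = estimate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  if (!is.null(x$estimate)) {
    cat("  estimates:\n")
    for (nm in names(x$estimate))
      cat(sprintf("    %s = %.4g\n", nm, x$estimate[[nm]]))
  }
  invisible(x)
}
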
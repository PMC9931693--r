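#' Predict whole-body lipid content from a fat-meter reading
#'
#' Evaluates a continuous piecewise calibration. Readings below the meter's
#' observable floor are evaluated at the floor with a warning (field sheets
#' occasionally contain them); predictions are clipped to the physical range
#' `[0, 100]` percent.
#'
#' @param reading Fat-meter reading(s), meter units, `>= 0`.
#' @param cal A [piecewise_calibration()] object.
#' @return Whole-body lipid content, percent wet weight.
#' @examples
#' cal <- published_calibration()
#' predict_whole_body_lipid(c(0.6, 1.059, 10), cal)
#' @export
predict_whole_body_lipid <- function(reading, cal) {
  stopifnot(inherits(cal, "piecewise_calibration"))
  if (any(!is.finite(reading))) stop("readings must be finite")
  if (any(reading < 0)) stop("readings must be nonnegative")
  n_floor <- sum(reading < cal$floor)
  if (n_floor > 0)
    warning(sprintf("%d reading(s) below the floor %.2f evaluated at the floor",
                    n_floor, cal$floor))
  r <- pmax(reading, cal$floor)
  h <- pmax(r - cal$breakpoint, 0)
  out <- cal$intercept + cal$slope_below * r + cal$slope_change * h
  pmin(pmax(out, 0), 100)
}

# Mean reading across the requested meter positions (listwise per combo).
.combo_reading <- function(samples, combo) {
  cols <- paste0("reading_pos", strsplit(combo, "")[[1]])
  rowMeans(as.matrix(samples[, cols, drop = FALSE]))
}

#' Rank calibration models across positions and regression families
#'
#' Fits all 21 combinations of meter-position combo (1, 2, 3, 12, 13, 23,
#' 123; multi-position combos use the arithmetic mean of the named positions)
#' and model family (model II on raw readings, model II on log-transformed
#' readings, segmented on raw readings) against whole-body lipid content, and
#' ranks them by adjusted R-squared. Rows with a missing reading are dropped
#' per combo (listwise deletion) and the retained count reported. Ties are
#' broken by fewer positions used, then by lower position index.
#'
#' @param samples Data frame with columns `reading_pos1..3` and
#'   `whole_body_lipid_pct` (as produced by [generate_calibration_set()] or
#'   [read_calibration_csv()]).
#' @param method Model II flavor passed to [fit_model2()].
#' @return Data frame of class `calibration_ranking` with columns
#'   `position_combo`, `family`, `r2_adj`, `n`, ordered best first.
#' @export
rank_calibrations <- function(samples, method = "SMA") {
  need <- c("reading_pos1", "reading_pos2", "reading_pos3",
            "whole_body_lipid_pct")
  if (!all(need %in% names(samples)))
    stop("samples must carry reading_pos1..3 and whole_body_lipid_pct")
  if (nrow(samples) < 5) stop("need at least 5 calibration samples")
  combos <- c("1", "2", "3", "12", "13", "23", "123")
  fams <- c("modelII", "modelII_log", "segmented")
  rows <- list()
  for (combo in combos) {
    x_all <- .combo_reading(samples, combo)
    y_all <- samples$whole_body_lipid_pct
    keep <- is.finite(x_all) & is.finite(y_all)
    x <- x_all[keep]; y <- y_all[keep]
    for (fam in fams) {
      r2 <- tryCatch(switch(fam,
        modelII = fit_model2(x, y, method = method)$r2_adj,
        modelII_log = fit_model2(x, y, method = method, log_x = TRUE)$r2_adj,
        segmented = fit_segmented(x, y)$r2_adj
      ), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        position_combo = combo, family = fam, r2_adj = r2, n = sum(keep),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$r2_adj, nchar(out$position_combo), out$position_combo)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calibration_ranking", "data.frame")
  out
}

#' Test whether a covariate interacts with the fat-meter calibration
#'
#' Nested-model F-test of the `reading x covariate` interaction term:
#' `lipid ~ reading + z` against `lipid ~ reading + z + reading:z`. Used to
#' check that fish size (kg) or maturation state (GSI) does not alter the
#' reading-to-lipid relationship.
#'
#' @param x Readings.
#' @param y Whole-body lipid (percent).
#' @param z Covariate (e.g. mass or GSI).
#' @return A `test_result` with the F statistic, degrees of freedom and
#'   p-value.
#' @export
covariate_interaction_test <- function(x, y, z) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (length(x) < 5) stop("need at least 5 complete cases")
  reduced <- stats::lm(y ~ x + z)
  full <- stats::lm(y ~ x + z + x:z)
  if (any(is.na(stats::coef(full))))
    stop("collinear design: interaction term not estimable")
  a <- stats::anova(reduced, full)
  test_result(statistic = a$F[2], df = c(a$Df[2], a$Res.Df[2]),
              p_value = a$`Pr(>F)`[2],
              method = "interaction F-test (nested least squares)")
}

#' Compare calibration regressions between sexes (ANCOVA)
#'
#' Sequential analysis of covariance on the reading-to-lipid regression:
#' first tests homogeneity of slopes (the `sex x reading` interaction); if
#' slopes are homogeneous at `alpha`, tests equality of adjusted intercepts
#' (the sex main effect in the common-slope model).
#'
#' @param x_m,y_m Readings and lipid for males.
#' @param x_f,y_f Readings and lipid for females.
#' @param alpha Level at which slope homogeneity gates the intercept test.
#' @return List with `slopes` and `intercepts` (`test_result`s); `intercepts`
#'   is `NULL` when the slope test rejects.
#' @export
sex_ancova <- function(x_m, y_m, x_f, y_f, alpha = 0.05) {
  if (length(x_m) < 3 || length(x_f) < 3)
    stop("both sexes need at least 3 observations")
  if (stats::var(x_m) == 0 || stats::var(x_f) == 0)
    stop("a group has zero variance in readings")
  x <- c(x_m, x_f); y <- c(y_m, y_f)
  g <- factor(rep(c("M", "F"), c(length(x_m), length(x_f))))
  common <- stats::lm(y ~ x + g)
  separate <- stats::lm(y ~ x * g)
  a_slope <- stats::anova(common, separate)
  slopes <- test_result(
    statistic = a_slope$F[2], df = c(a_slope$Df[2], a_slope$Res.Df[2]),
    p_value = a_slope$`Pr(>F)`[2], method = "ANCOVA slope homogeneity")
  intercepts <- NULL
  if (is.na(slopes$p_value) || slopes$p_value > alpha) {
    base_m <- stats::lm(y ~ x)
    a_int <- stats::anova(base_m, common)
    intercepts <- test_result(
      statistic = a_int$F[2], df = c(a_int$Df[2], a_int$Res.Df[2]),
      p_value = a_int$`Pr(>F)`[2], method = "ANCOVA adjusted intercepts")
  }
  list(slopes = slopes, intercepts = intercepts)
}
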
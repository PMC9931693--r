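#' Packaged Fraser management-unit reference tables
#'
#' Two small plain-text fixtures transcribed from the published MU-level
#' tables: `fraser_mu_indices()` returns the four migration-difficulty
#' indices (mean spawning-ground elevation in m, mean migration distance in
#' km, and the derived work and slope indices, averaged per stock then per
#' MU); `fraser_mu_summary()` returns the 2020 Albion test-fishery summary
#' (sample sizes, lipid and energy-density statistics, fork length, weight,
#' and run-timing dates); `fraser_mu_lipid()` is the lipid-mean subset used
#' by the correlation analysis. The per-stock source data behind the indices
#' are scattered across the primary literature and not reproduced here, so
#' the MU-level values are treated as ground truth.
#'
#' @return A data frame keyed by `mu`.
#' @export
fraser_mu_indices <- function() {
  utils::read.csv(system.file("extdata", "fraser_mu_indices.csv",
                              package = "chinooklipid"),
                  stringsAsFactors = FALSE)
}

#' @rdname fraser_mu_indices
#' @export
fraser_mu_summary <- function() {
  d <- utils::read.csv(system.file("extdata", "fraser_mu_summary.csv",
                                   package = "chinooklipid"),
                       stringsAsFactors = FALSE)
  for (col in c("run_first", "run_50pct", "run_last"))
    d[[col]] <- as.Date(d[[col]])
  d
}

#' @rdname fraser_mu_indices
#' @export
fraser_mu_lipid <- function() {
  fraser_mu_summary()[, c("mu", "lipid_mean")]
}

#' The packaged lipid-to-energy-density conversion
#'
#' Least-squares fit of MU mean energy density (kcal/kg) on MU mean lipid
#' content (percent) over the packaged [fraser_mu_summary()] table. The
#' original conversion equation's coefficients are not published, so this
#' affine fit to the five printed (lipid, energy-density) MU pairs is the
#' package default; an externally supplied [energy_conversion()] may be used
#' instead anywhere one is accepted.
#'
#' @param exclude Optional character vector of MU labels to hold out of the
#'   fit (e.g. for leave-one-out checks).
#' @return An [energy_conversion()].
#' @examples
#' energy_density(12.8, table3_energy_conversion())  # ~1899 kcal/kg
#' @export
table3_energy_conversion <- function(exclude = NULL) {
  d <- fraser_mu_summary()
  if (!is.null(exclude)) d <- d[!d$mu %in% exclude, , drop = FALSE]
  fit_ed_conversion(d$lipid_mean, d$ed_mean)
}

.require_cols <- function(d, cols, what) {
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0)
    stop(what, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
}

#' Read and write the calibration-cohort CSV
#'
#' The calibration schema is the output of [generate_calibration_set()]:
#' one row per homogenized fish with identifiers, masses (kg), three meter
#' readings, water fractions, replicate dry-mass lipid fractions and the
#' derived whole-body lipid percent. Rows whose somatic and gonad masses do
#' not sum to the total (tolerance 1e-6 kg), or with fractions outside
#' `[0, 1]`, readings below zero, or lipid outside `[0, 100]`, are dropped
#' with a line-numbered warning.
#'
#' @param path File path.
#' @return Validated data frame; attribute `n_rejected` counts dropped rows.
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  .require_cols(d, c("fish_id", "total_mass", "somatic_mass", "gonad_mass",
                     "reading_pos1", "whole_body_lipid_pct"),
                "calibration CSV")
  if ("capture_date" %in% names(d)) d$capture_date <- as.Date(d$capture_date)
  frac_cols <- grep("_frac$|_lipid_dry_rep|_lipid_wet$", names(d),
                    value = TRUE)
  bad <- abs(d$somatic_mass + d$gonad_mass - d$total_mass) > 1e-6
  bad <- bad | d$reading_pos1 < 0 |
    d$whole_body_lipid_pct < 0 | d$whole_body_lipid_pct > 100
  for (col in frac_cols)
    bad <- bad | (!is.na(d[[col]]) & (d[[col]] < 0 | d[[col]] > 1))
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    warning(sprintf("dropped %d invalid calibration row(s): lines %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  out <- d[!bad, , drop = FALSE]
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' @rdname read_calibration_csv
#' @param records Data frame to write.
#' @export
write_calibration_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the survey CSV
#'
#' The survey schema is the output of [generate_survey()]: one row per fish
#' with `fish_id`, ISO-8601 `date`, `mu`, `stock`, `reading_pos1`,
#' `fork_length` (mm), `weight` (kg), `sex`, `fin_clipped`. `day_of_year` is
#' derived from the date on read. Rows with an unknown MU label or a
#' non-positive weight or fork length are dropped with a warning.
#'
#' @param path File path.
#' @return Validated data frame; attribute `n_rejected` counts dropped rows.
#' @export
read_survey_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  .require_cols(d, c("fish_id", "date", "mu", "reading_pos1"), "survey CSV")
  d$date <- as.Date(d$date)
  d$day_of_year <- as.integer(format(d$date, "%j"))
  if ("fin_clipped" %in% names(d)) d$fin_clipped <- as.logical(d$fin_clipped)
  bad <- is.na(d$date) | !(d$mu %in% mu_levels())
  if ("weight" %in% names(d)) bad <- bad | (!is.na(d$weight) & d$weight <= 0)
  if ("fork_length" %in% names(d))
    bad <- bad | (!is.na(d$fork_length) & d$fork_length <= 0)
  if (any(bad))
    warning(sprintf("dropped %d invalid survey row(s): lines %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  out <- d[!bad, , drop = FALSE]
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' @rdname read_survey_csv
#' @param records Data frame to write.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
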
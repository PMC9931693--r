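#' Configuration for the full analysis pipeline
#'
#' Bundles every stage choice: where the calibration comes from, which
#' lipid-to-energy conversion to use, the significance level, any stocks to
#' drop from MU-level statistics (populations geographically atypical for
#' their MU), the reference prey scenario, and the seed used when inputs are
#' simulated.
#'
#' @param calibration_source `"published"` (default), `"fit"` (segmented fit
#'   on the calibration set), or a [piecewise_calibration()] object.
#' @param conversion `"table3_fit"` (default) or an [energy_conversion()].
#' @param alpha Significance level in `(0, 1)`.
#' @param stock_blocklist Stocks excluded from MU-level statistics.
#' @param anova_exclude MUs excluded from ANOVA/Tukey and slope ANCOVA
#'   (default `"Spring4_2"`, whose n = 9 is too small).
#' @param reference_scenario List with `prey_count`, `prey_mass_kg`, and the
#'   MU whose energy density anchors the predator population-energy
#'   back-calculation.
#' @param seed Integer seed used for simulated inputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(calibration_source = "published",
                            conversion = "table3_fit",
                            alpha = 0.05,
                            stock_blocklist = character(),
                            anova_exclude = "Spring4_2",
                            reference_scenario = list(prey_count = 245000,
                                                      prey_mass_kg = 8,
                                                      mu = "Spring5_2"),
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(calibration_source = calibration_source,
                 conversion = conversion, alpha = alpha,
                 stock_blocklist = stock_blocklist,
                 anova_exclude = anova_exclude,
                 reference_scenario = reference_scenario,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.resolve_calibration <- function(source, calibration_set) {
  if (inherits(source, "piecewise_calibration")) return(source)
  switch(source,
    published = published_calibration(),
    fit = {
      if (is.null(calibration_set))
        stop("calibration_source = 'fit' requires a calibration set")
      fit_segmented(calibration_set$reading_pos1,
                    calibration_set$whole_body_lipid_pct)
    },
    stop("unknown calibration source"))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when inputs are not supplied) -> calibrate -> survey
#' -> correlate -> energetics, and optionally writes every stage output plus
#' a run manifest. Idempotent for a fixed seed: the same configuration and
#' inputs produce identical outputs.
#'
#' Stages: (1) obtain calibration and survey data (simulated from the
#' packaged defaults unless data frames or CSV paths are given); (2) rank
#' the 21 calibration models and resolve the working calibration; (3) apply
#' it, attach energy densities, and compute MU summaries, ANOVA + Tukey
#' letters, per-MU seasonal trends, slope ANCOVAs against Fall 4_1, and the
#' hatchery-wild contrast; (4) correlate MU mean lipid with the packaged
#' migration-difficulty indices; (5) evaluate prey-requirement scenarios at
#' the MU mean energy densities, anchored at the reference scenario.
#'
#' @param config A [pipeline_config()].
#' @param calibration_set,survey Optional data frames or CSV paths; omitted
#'   means simulate with the packaged defaults under `config$seed`.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as CSVs plus `manifest.json`.
#' @return List with `calibration`, `ranking`, `survey`, `mu_summary`,
#'   `anova`, `trends`, `slope_tests`, `hatchery`, `correlations`,
#'   `scenarios`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), calibration_set = NULL,
                         survey = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(calibration_set))
    calibration_set <- read_calibration_csv(calibration_set)
  if (is.character(survey)) survey <- read_survey_csv(survey)
  simulated <- is.null(calibration_set) || is.null(survey)
  if (is.null(calibration_set))
    calibration_set <- generate_calibration_set(
      calibration_sim_config(seed = config$seed))
  if (is.null(survey))
    survey <- generate_survey(survey_sim_config(seed = config$seed + 1L))

  ranking <- rank_calibrations(calibration_set)
  cal <- .resolve_calibration(config$calibration_source, calibration_set)
  conv <- if (inherits(config$conversion, "energy_conversion"))
    config$conversion else table3_energy_conversion()

  survey <- apply_calibration(survey, cal)
  survey$ed_kcal_kg <- energy_density(survey$wbl_pct, conv)
  analysed <- survey[!(survey$stock %in% config$stock_blocklist), ,
                     drop = FALSE]
  musum <- mu_summary(analysed)

  stat_set <- analysed[!(analysed$mu %in% config$anova_exclude) &
                         is.finite(analysed$wbl_pct), , drop = FALSE]
  anova_res <- anova_tukey(stat_set$wbl_pct, stat_set$mu,
                           alpha = config$alpha)

  trends <- list()
  for (m in intersect(mu_levels(), unique(analysed$mu))) {
    mu_rec <- analysed[analysed$mu == m, , drop = FALSE]
    trends[[m]] <- tryCatch(seasonal_trend(mu_rec), error = function(e) NULL)
  }
  slope_tests <- list()
  for (m in setdiff(names(trends), c("Fall4_1", config$anova_exclude))) {
    slope_tests[[paste0(m, "_vs_Fall4_1")]] <- tryCatch(
      compare_slopes(analysed[analysed$mu == m, ],
                     analysed[analysed$mu == "Fall4_1", ]),
      error = function(e) NULL)
  }
  hatchery <- tryCatch(
    hatchery_wild_test(analysed[analysed$mu == "Fall4_1" &
                                  analysed$stock == "Harrison", ]),
    error = function(e) NULL)

  correlations <- difficulty_correlation(
    fraser_mu_indices(),
    stats::setNames(musum[c("mu", "lipid_mean")], c("mu", "lipid_mean")))

  ref <- config$reference_scenario
  ref_ed <- musum$ed_mean[musum$mu == ref$mu]
  pop_energy <- back_calculate_population_energy(ref$prey_count,
                                                 ref$prey_mass_kg, ref_ed)
  scenarios <- prey_scenarios(
    stats::setNames(musum$ed_mean, musum$mu), pop_energy, ref$prey_mass_kg)

  manifest <- list(
    package_version = as.character(utils::packageVersion("chinooklipid")),
    seed = config$seed,
    simulated_inputs = simulated,
    n_calibration = nrow(calibration_set),
    n_survey = nrow(survey),
    calibration = cal[c("intercept", "slope_below", "slope_change",
                        "breakpoint", "floor")],
    conversion = conv[c("intercept", "slope", "kj_per_kcal")],
    alpha = config$alpha,
    stock_blocklist = config$stock_blocklist,
    anova_exclude = config$anova_exclude,
    reference_scenario = ref)

  result <- list(calibration = cal, ranking = ranking, survey = survey,
                 mu_summary = musum, anova = anova_res, trends = trends,
                 slope_tests = slope_tests, hatchery = hatchery,
                 correlations = correlations, scenarios = scenarios,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calibration_csv(calibration_set,
                          file.path(out_dir, "calibration_set.csv"))
    write_survey_csv(survey, file.path(out_dir, "survey.csv"))
    utils::write.csv(ranking, file.path(out_dir, "calibration_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(musum, file.path(out_dir, "mu_summary.csv"),
                     row.names = FALSE)
    trend_tab <- do.call(rbind, lapply(names(trends), function(m) {
      t <- trends[[m]]
      if (is.null(t)) return(NULL)
      data.frame(mu = m, slope_pp_per_day = t$slope_pp_per_day,
                 p_value = t$p_value, total_change_pp = t$total_change_pp,
                 weekly_change_pp = t$weekly_change_pp, n = t$n)
    }))
    utils::write.csv(trend_tab, file.path(out_dir, "seasonal_trends.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(scenarios, file.path(out_dir, "prey_scenarios.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}
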
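#' Invert the piecewise calibration: meter reading from lipid content
#'
#' Exact inverse of [predict_whole_body_lipid()] plus optional Gaussian meter
#' noise, clamped below at the meter floor (readings are never observed below
#' it in the field).
#'
#' @param lipid_pct Whole-body lipid, percent wet weight.
#' @param cal A [piecewise_calibration()]; both segment slopes must be
#'   nonzero for the inverse to exist.
#' @param noise_sd Meter noise standard deviation, meter units (default 0).
#' @return Fat-meter reading(s), meter units, `>= cal$floor`.
#' @examples
#' reading_from_lipid(5.184, published_calibration())  # ~1.059
#' @export
reading_from_lipid <- function(lipid_pct, cal, noise_sd = 0) {
  stopifnot(inherits(cal, "piecewise_calibration"))
  if (any(!is.finite(lipid_pct))) stop("lipid_pct must be finite")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  slope_above <- cal$slope_below + cal$slope_change
  if (cal$slope_below == 0 || slope_above == 0)
    stop("calibration is not invertible (zero segment slope)")
  lipid_at_psi <- cal$intercept + cal$slope_below * cal$breakpoint
  r <- ifelse(lipid_pct >= lipid_at_psi,
              cal$breakpoint + (lipid_pct - lipid_at_psi) / slope_above,
              (lipid_pct - cal$intercept) / cal$slope_below)
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  pmax(r, cal$floor)
}

#' Configuration for the synthetic calibration cohort
#'
#' Defaults emulate the homogenization cohort: 63 fish spanning body masses
#' 0.25–11.05 kg and whole-body lipid levels that map onto readings 0.6–16.8
#' under the published calibration; female gonads average 10.03 +/- 1.89
#' percent lipid and male gonads 0.68 +/- 0.36; GSI spans roughly 0.01–0.17.
#' Positions 2 and 3 are position 1 plus independent extra noise, which is
#' what makes position 1 the most informative single position.
#'
#' @param n_fish Number of fish.
#' @param true_calibration Generating [piecewise_calibration()].
#' @param reading_noise_sd Meter noise on position 1, meter units.
#' @param pos23_extra_noise_sd Additional noise on positions 2 and 3.
#' @param lipid_range Whole-body lipid range, percent (min, max).
#' @param mass_range Total-mass range, kg (min, max).
#' @param sex_ratio Fraction female.
#' @param gonad_lipid_female,gonad_lipid_male (mean, sd) of gonad lipid,
#'   percent wet weight.
#' @param gsi_range GSI range (ratio scale).
#' @param seed Optional integer seed for reproducibility.
#' @return A validated list of class `calibration_sim_config`.
#' @export
calibration_sim_config <- function(n_fish = 63,
                                   true_calibration = published_calibration(),
                                   reading_noise_sd = 0.2,
                                   pos23_extra_noise_sd = 0.5,
                                   lipid_range = c(1.0, 13.9),
                                   mass_range = c(0.25, 11.05),
                                   sex_ratio = 0.5,
                                   gonad_lipid_female = c(10.03, 1.89),
                                   gonad_lipid_male = c(0.68, 0.36),
                                   gsi_range = c(0.01, 0.17),
                                   seed = NULL) {
  stopifnot(n_fish >= 0, reading_noise_sd >= 0, pos23_extra_noise_sd >= 0)
  for (rng in list(lipid_range, mass_range, gsi_range))
    if (length(rng) != 2 || rng[1] > rng[2]) stop("ranges must be (min, max)")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  if (gonad_lipid_female[2] < 0 || gonad_lipid_male[2] < 0)
    stop("gonad lipid sd must be nonnegative")
  structure(as.list(environment()), class = "calibration_sim_config")
}

#' Generate a synthetic calibration cohort
#'
#' Draws fish with mutually consistent tissue masses, water fractions, and
#' replicate dry-mass lipid fractions, so that whole-body lipid recomputed
#' from the tissue data via [dry_to_wet_lipid()] and [whole_body_lipid()]
#' equals the value used to generate the meter readings. Deterministic for a
#' fixed `seed`.
#'
#' @param config A [calibration_sim_config()].
#' @return Data frame, one row per fish, in the calibration CSV schema (see
#'   [read_calibration_csv()]).
#' @export
generate_calibration_set <- function(config = calibration_sim_config()) {
  stopifnot(inherits(config, "calibration_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_fish
  if (n == 0) return(.empty_calibration_df())
  cal <- config$true_calibration

  lipid <- stats::runif(n, config$lipid_range[1], config$lipid_range[2])
  total_mass <- stats::runif(n, config$mass_range[1], config$mass_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  gsi <- stats::runif(n, config$gsi_range[1], config$gsi_range[2])
  gonad_mass <- gonad_mass_from_gsi(total_mass, gsi)
  somatic_mass <- total_mass - gonad_mass

  gl_par <- ifelse(sex == "F",
                   stats::rnorm(n, config$gonad_lipid_female[1],
                                config$gonad_lipid_female[2]),
                   stats::rnorm(n, config$gonad_lipid_male[1],
                                config$gonad_lipid_male[2]))
  gonad_lipid_wet <- pmin(pmax(gl_par, 0), 100) / 100
  # choose the somatic lipid fraction so that the whole-body value is met
  somatic_lipid_wet <- (lipid / 100 * total_mass -
                          gonad_mass * gonad_lipid_wet) / somatic_mass
  somatic_lipid_wet <- pmin(pmax(somatic_lipid_wet, 0), 1)
  wbl <- whole_body_lipid(somatic_mass, somatic_lipid_wet,
                          gonad_mass, gonad_lipid_wet)

  r1 <- reading_from_lipid(wbl, cal, config$reading_noise_sd)
  extra <- function() if (config$pos23_extra_noise_sd > 0)
    stats::rnorm(n, 0, config$pos23_extra_noise_sd) else 0
  r2 <- pmax(r1 + extra(), cal$floor)
  r3 <- pmax(r1 + extra(), cal$floor)

  # water inversely related to lipid, as the meter's physics assumes
  somatic_water <- pmin(pmax(0.80 - somatic_lipid_wet +
                               stats::rnorm(n, 0, 0.01), 0.5), 0.85)
  gonad_water <- pmin(pmax(stats::rnorm(n, 0.70, 0.03), 0.5), 0.85)
  somatic_dry <- somatic_lipid_wet / (1 - somatic_water)
  gonad_dry <- gonad_lipid_wet / (1 - gonad_water)
  reps_about <- function(target, k, sd = 0.004) {
    e <- matrix(stats::rnorm(n * k, 0, sd), n, k)
    e <- e - rowMeans(e)  # replicate means hit the target exactly
    pmin(pmax(target + e, 0), 1)
  }
  s_reps <- reps_about(somatic_dry, 3)
  g_reps <- reps_about(gonad_dry, 2)

  fl <- (1000 * total_mass / 0.02)^(1 / 3) * exp(stats::rnorm(n, 0, 0.04))
  doy <- sample(150:280, n, replace = TRUE)
  src <- ifelse(stats::runif(n) < 1 / 3, "troll", "test_fishery")

  data.frame(
    fish_id = sprintf("cal%03d", seq_len(n)),
    source = src,
    capture_date = as.Date(doy - 1, origin = "2020-01-01"),
    sex = sex,
    fork_length = round(fl, 1),
    total_mass = total_mass,
    somatic_mass = somatic_mass,
    gonad_mass = gonad_mass,
    reading_pos1 = r1, reading_pos2 = r2, reading_pos3 = r3,
    somatic_water_frac = somatic_water,
    gonad_water_frac = gonad_water,
    somatic_lipid_dry_rep1 = s_reps[, 1],
    somatic_lipid_dry_rep2 = s_reps[, 2],
    somatic_lipid_dry_rep3 = s_reps[, 3],
    gonad_lipid_dry_rep1 = g_reps[, 1],
    gonad_lipid_dry_rep2 = g_reps[, 2],
    somatic_lipid_wet = somatic_lipid_wet,
    gonad_lipid_wet = gonad_lipid_wet,
    whole_body_lipid_pct = wbl,
    stringsAsFactors = FALSE)
}

.empty_calibration_df <- function() {
  generate_calibration_set(calibration_sim_config(n_fish = 1, seed = 1))[0, ]
}

.mu_block <- function(n, run_start, run_end, lipid_start_mean, lipid_end_mean,
                      lipid_sd, fork_length, weight, hatchery_fraction = 0,
                      hatchery_lipid_offset = 0, gsi_start = 0.03,
                      gsi_end = 0.08, stock = NA_character_) {
  stopifnot(n >= 0, lipid_sd >= 0,
            hatchery_fraction >= 0, hatchery_fraction <= 1)
  run_start <- as.Date(run_start); run_end <- as.Date(run_end)
  if (run_start > run_end) stop("run_start must not follow run_end")
  list(n = n, run_start = run_start, run_end = run_end,
       lipid_start_mean = lipid_start_mean, lipid_end_mean = lipid_end_mean,
       lipid_sd = lipid_sd, fork_length = fork_length, weight = weight,
       hatchery_fraction = hatchery_fraction,
       hatchery_lipid_offset = hatchery_lipid_offset,
       gsi_start = gsi_start, gsi_end = gsi_end, stock = stock)
}

#' Configuration for the synthetic river-entry survey
#'
#' One block per management unit. The packaged defaults reproduce the 2020
#' Albion test-fishery structure: per-MU sample sizes 289/9/72/966/473, run
#' windows from the published run-timing dates, mean lipid levels of
#' 12.8/12.2/12.7/10.8/7.3 percent, and within-season linear lipid declines
#' of 5/4/5/6/4 percentage points (start/end means are the MU mean plus and
#' minus half the decline, so uniform catch dates recover the MU mean).
#' `lipid_sd` is the residual spread around the seasonal line, set so the
#' total spread approximates the published MU standard deviations. Fall 4_1
#' carries a 30% hatchery (fin-clipped) fraction at a -0.82 pp lipid offset
#' (the Harrison River contrast) and a GSI rise from 0.1 to 0.2 across its
#' run.
#'
#' @param mus Named list of MU blocks; see source for the block fields.
#' @param reading_noise_sd Meter noise applied when converting the simulated
#'   lipid back to a position-1 reading.
#' @param true_calibration Generating calibration (readings are its inverse).
#' @param seed Optional integer seed.
#' @return List of class `survey_sim_config`.
#' @export
survey_sim_config <- function(mus = NULL, reading_noise_sd = 0.1,
                              true_calibration = published_calibration(),
                              seed = NULL) {
  if (is.null(mus)) {
    mus <- list(
      Spring5_2 = .mu_block(289, "2020-04-21", "2020-09-07", 15.3, 10.3, 1.8,
                            c(660.9, 67.4), c(7.0, 2.4)),
      Spring4_2 = .mu_block(9, "2020-04-22", "2020-08-02", 14.2, 10.2, 1.5,
                            c(584.7, 70.9), c(4.8, 2.1)),
      Summer5_2 = .mu_block(72, "2020-07-02", "2020-09-04", 15.2, 10.2, 1.5,
                            c(658.3, 55.0), c(7.1, 1.9)),
      Summer4_1 = .mu_block(966, "2020-07-16", "2020-09-29", 13.8, 7.8, 1.0,
                            c(638.2, 49.8), c(6.4, 1.6),
                            gsi_start = 0.05, gsi_end = 0.12,
                            stock = "SouthThompson"),
      Fall4_1 = .mu_block(473, "2020-08-24", "2020-10-27", 9.3, 5.3, 1.0,
                          c(671.5, 61.4), c(8.2, 2.6),
                          hatchery_fraction = 0.3,
                          hatchery_lipid_offset = -0.82,
                          gsi_start = 0.1, gsi_end = 0.2,
                          stock = "Harrison"))
  }
  if (!all(names(mus) %in% mu_levels()))
    stop("unknown MU label(s): ",
         paste(setdiff(names(mus), mu_levels()), collapse = ", "))
  stopifnot(reading_noise_sd >= 0)
  structure(list(mus = mus, reading_noise_sd = reading_noise_sd,
                 true_calibration = true_calibration, seed = seed),
            class = "survey_sim_config")
}

#' Generate a synthetic river-entry survey
#'
#' For each MU, catch dates are uniform over the run window and the expected
#' lipid declines linearly from `lipid_start_mean` to `lipid_end_mean` across
#' it; fin-clip flags are drawn at `hatchery_fraction` with the configured
#' lipid offset; GSI rises linearly across the run. Position-1 readings are
#' the inverse of the generating calibration evaluated at the simulated lipid
#' (plus meter noise), so applying that calibration recovers the lipid values
#' up to noise and the meter floor. Deterministic under a fixed `seed`.
#'
#' @param config A [survey_sim_config()].
#' @return Data frame in the survey CSV schema (see [read_survey_csv()]),
#'   with the simulated ground-truth lipid kept in `wbl_true_pct`.
#' @export
generate_survey <- function(config = survey_sim_config()) {
  stopifnot(inherits(config, "survey_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cal <- config$true_calibration
  out <- list()
  for (mu in names(config$mus)) {
    b <- config$mus[[mu]]
    if (b$n == 0) next
    n <- b$n
    days <- as.integer(b$run_end - b$run_start)
    date <- b$run_start + sample.int(days + 1, n, replace = TRUE) - 1
    frac <- if (days > 0) as.numeric(date - b$run_start) / days else rep(0, n)
    clipped <- stats::runif(n) < b$hatchery_fraction
    mu_lip <- b$lipid_start_mean +
      (b$lipid_end_mean - b$lipid_start_mean) * frac
    # the hatchery offset is centred so the MU-wide mean stays at mu_lip
    off <- ifelse(clipped,
                  (1 - b$hatchery_fraction) * b$hatchery_lipid_offset,
                  -b$hatchery_fraction * b$hatchery_lipid_offset)
    lip <- mu_lip + stats::rnorm(n, 0, b$lipid_sd) + off
    lip <- pmin(pmax(lip, 0.5), 25)
    gsi <- pmax(b$gsi_start + (b$gsi_end - b$gsi_start) * frac +
                  stats::rnorm(n, 0, 0.01), 0)
    out[[mu]] <- data.frame(
      fish_id = paste0(mu, "_", seq_len(n)),
      date = date,
      day_of_year = as.integer(format(date, "%j")),
      mu = mu,
      stock = if (is.na(b$stock)) mu else b$stock,
      reading_pos1 = reading_from_lipid(lip, cal, config$reading_noise_sd),
      fork_length = stats::rnorm(n, b$fork_length[1], b$fork_length[2]),
      weight = pmax(stats::rnorm(n, b$weight[1], b$weight[2]), 0.3),
      sex = sample(c("M", "F"), n, replace = TRUE),
      fin_clipped = clipped,
      gsi = gsi,
      wbl_true_pct = lip,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
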
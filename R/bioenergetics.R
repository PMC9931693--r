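#' Gonad mass implied by a gonadosomatic index
#'
#' With GSI defined as gonad mass over somatic mass, a fish of total mass
#' `m` has gonad mass `m * gsi / (1 + gsi)`. Exact inverse of
#' [gonadosomatic_index()].
#'
#' @param total_mass Total body mass, kg; positive.
#' @param gsi Gonadosomatic index (ratio); nonnegative.
#' @return Gonad mass, kg.
#' @examples
#' gonad_mass_from_gsi(8, 0.1)  # 0.7273
#' @export
gonad_mass_from_gsi <- function(total_mass, gsi) {
  if (any(total_mass <= 0)) stop("total_mass must be positive")
  if (any(gsi < 0)) stop("gsi must be nonnegative")
  total_mass * gsi / (1 + gsi)
}

#' Energy invested in gonadal development across a run
#'
#' Energy corresponding to a within-season GSI increase, as gonad-mass gain
#' times gonad energy density (default 7.79 kJ/g). The reference body mass is
#' interpreted as total mass by default; with `mass_basis = "somatic"` it is
#' instead held fixed as somatic mass (gonad mass is then `mass * gsi`).
#'
#' @param mass Reference body mass, kg.
#' @param gsi_start,gsi_end GSI at the start and end of the interval (ratios).
#' @param gonad_energy_density_kj_g Gonad energy density, kJ/g.
#' @param mass_basis `"total"` (default) or `"somatic"`.
#' @return Energy, kJ.
#' @examples
#' gonad_energy_change(8, 0.1, 0.2)  # ~4721 kJ
#' @export
gonad_energy_change <- function(mass, gsi_start, gsi_end,
                                gonad_energy_density_kj_g = 7.79,
                                mass_basis = c("total", "somatic")) {
  mass_basis <- match.arg(mass_basis)
  if (any(mass <= 0)) stop("mass must be positive")
  if (any(c(gsi_start, gsi_end) < 0)) stop("GSI must be nonnegative")
  if (gonad_energy_density_kj_g <= 0)
    stop("gonad energy density must be positive")
  gm <- switch(mass_basis,
    total = gonad_mass_from_gsi(mass, gsi_end) -
      gonad_mass_from_gsi(mass, gsi_start),
    somatic = mass * (gsi_end - gsi_start))
  gm * 1000 * gonad_energy_density_kj_g
}

#' Whole-body energy content of a fish
#'
#' @param mass Body mass, kg; positive.
#' @param lipid_pct Whole-body lipid, percent.
#' @param conv An [energy_conversion()].
#' @return Energy, kJ: `mass * energy_density(lipid) * kj_per_kcal`.
#' @export
whole_body_energy <- function(mass, lipid_pct, conv) {
  if (any(mass <= 0)) stop("mass must be positive")
  mass * energy_density(lipid_pct, conv) * conv$kj_per_kcal
}

#' Annual prey requirement of a predator population
#'
#' Number of prey fish per year needed to meet a population-level energy
#' requirement, given average prey mass and energy density. Used for
#' southern resident killer whale scenarios in which the population forages
#' on a single Chinook management unit.
#'
#' @param population_energy_kcal Population energy requirement, kcal/year.
#' @param prey_mass_kg Average prey mass, kg (default 8).
#' @param ed_kcal_kg Prey energy density, kcal/kg.
#' @return Prey count, fish/year.
#' @examples
#' pe <- back_calculate_population_energy(245000, 8, 1900)
#' prey_requirement(pe, 8, 1436)  # ~324,000 fish on the Fall 4_1 diet
#' @export
prey_requirement <- function(population_energy_kcal, prey_mass_kg = 8,
                             ed_kcal_kg) {
  if (any(c(population_energy_kcal, prey_mass_kg, ed_kcal_kg) <= 0))
    stop("all inputs must be positive")
  population_energy_kcal / (prey_mass_kg * ed_kcal_kg)
}

#' @rdname prey_requirement
#' @param prey_count Prey consumed, fish/year.
#' @return `back_calculate_population_energy()`: kcal/year; exact inverse of
#'   [prey_requirement()].
#' @export
back_calculate_population_energy <- function(prey_count, prey_mass_kg = 8,
                                             ed_kcal_kg) {
  if (any(c(prey_count, prey_mass_kg, ed_kcal_kg) <= 0))
    stop("all inputs must be positive")
  prey_count * prey_mass_kg * ed_kcal_kg
}

#' Prey-requirement scenario table
#'
#' Evaluates [prey_requirement()] for a set of labelled energy densities
#' (e.g. MU mean EDs) under a common population energy requirement and prey
#' mass.
#'
#' @param ed_kcal_kg Named vector of prey energy densities.
#' @param population_energy_kcal Population requirement, kcal/year.
#' @param prey_mass_kg Average prey mass, kg.
#' @return Data frame with `label`, `ed_kcal_kg`, `prey_count`.
#' @export
prey_scenarios <- function(ed_kcal_kg, population_energy_kcal,
                           prey_mass_kg = 8) {
  data.frame(
    label = if (is.null(names(ed_kcal_kg)))
      as.character(seq_along(ed_kcal_kg)) else names(ed_kcal_kg),
    ed_kcal_kg = unname(ed_kcal_kg),
    prey_count = prey_requirement(population_energy_kcal, prey_mass_kg,
                                  unname(ed_kcal_kg)),
    stringsAsFactors = FALSE)
}
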
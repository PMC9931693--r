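#' Convert a dry-mass lipid fraction to a wet-mass lipid fraction
#'
#' Gravimetric lipid extraction reports lipid as a fraction of dried tissue;
#' combining tissues and comparing with fat-meter output both require the
#' wet-mass basis. The conversion simply rescales by the tissue's solid
#' fraction.
#'
#' @param lipid_frac_dry Lipid as a fraction of dry tissue mass, in `[0, 1]`.
#' @param water_frac Water as a fraction of wet tissue mass, in `[0, 1]`.
#' @return Lipid as a fraction of wet tissue mass:
#'   `lipid_frac_dry * (1 - water_frac)`.
#' @examples
#' dry_to_wet_lipid(0.30, 0.70)  # 0.09
#' @export
dry_to_wet_lipid <- function(lipid_frac_dry, water_frac) {
  stopifnot(is.numeric(lipid_frac_dry), is.numeric(water_frac))
  if (any(!is.finite(lipid_frac_dry)) || any(!is.finite(water_frac)))
    stop("lipid and water fractions must be finite")
  if (any(lipid_frac_dry < 0 | lipid_frac_dry > 1))
    stop("lipid_frac_dry must lie in [0, 1]")
  if (any(water_frac < 0 | water_frac > 1))
    stop("water_frac must lie in [0, 1]")
  lipid_frac_dry * (1 - water_frac)
}

#' Whole-body lipid content from somatic and gonadal compartments
#'
#' Mass-weighted combination of the two tissue compartments of a homogenized
#' fish (viscera are ground with the carcass and counted as somatic). The
#' result is a percentage of total wet mass and always lies between the two
#' tissue percentages.
#'
#' @param somatic_mass Somatic (carcass plus viscera) mass, kg.
#' @param somatic_lipid_wet Somatic lipid as a fraction of wet mass.
#' @param gonad_mass Gonad mass, kg.
#' @param gonad_lipid_wet Gonadal lipid as a fraction of wet mass.
#' @return Whole-body lipid content, percent of wet mass.
#' @examples
#' whole_body_lipid(7, 0.11, 1, 0.1003)
#' @export
whole_body_lipid <- function(somatic_mass, somatic_lipid_wet,
                             gonad_mass, gonad_lipid_wet) {
  if (any(somatic_mass < 0) || any(gonad_mass < 0))
    stop("masses must be nonnegative")
  if (any(somatic_mass + gonad_mass <= 0))
    stop("somatic and gonad mass cannot both be zero")
  for (f in list(somatic_lipid_wet, gonad_lipid_wet))
    if (any(f < 0 | f > 1)) stop("lipid fractions must lie in [0, 1]")
  100 * (somatic_mass * somatic_lipid_wet + gonad_mass * gonad_lipid_wet) /
    (somatic_mass + gonad_mass)
}

#' Gonadosomatic index
#'
#' GSI is gonad mass divided by somatic mass, kept as a dimensionless ratio
#' throughout the package (percent-style rendering is a formatting concern).
#'
#' @param gonad_mass Gonad mass, kg.
#' @param somatic_mass Somatic mass, kg; must be positive.
#' @return `gonad_mass / somatic_mass`.
#' @examples
#' gonadosomatic_index(0.5, 5.0)  # 0.1
#' @export
gonadosomatic_index <- function(gonad_mass, somatic_mass) {
  if (any(somatic_mass <= 0)) stop("somatic_mass must be positive")
  if (any(gonad_mass < 0)) stop("gonad_mass must be nonnegative")
  gonad_mass / somatic_mass
}
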
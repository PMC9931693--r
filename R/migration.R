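#' Migration-difficulty indices for a stock
#'
#' Two composite indices summarize the difficulty of a stock's freshwater
#' migration from its distance to the spawning ground (km from freshwater
#' entry) and the spawning-ground elevation (m):
#' work = elevation x distance / 1000 and slope = 500 x elevation / distance.
#'
#' @param distance_km Migration distance, km; must be positive.
#' @param elevation_m Spawning-ground elevation, m; nonnegative.
#' @return Data frame with columns `work` and `slope_index`.
#' @examples
#' stock_indices(994, 713)
#' @export
stock_indices <- function(distance_km, elevation_m) {
  if (any(!is.finite(distance_km)) || any(distance_km <= 0))
    stop("distance_km must be positive")
  if (any(!is.finite(elevation_m)) || any(elevation_m < 0))
    stop("elevation_m must be nonnegative")
  data.frame(work = elevation_m * distance_km / 1000,
             slope_index = 500 * elevation_m / distance_km)
}

#' Average per-stock migration indices to management-unit level
#'
#' Indices are computed per stock first and then averaged within the MU
#' (a mean of products, not a product of means) — the only aggregation
#' consistent with composite indices computed from heterogeneous stocks.
#'
#' @param stocks Data frame with `stock`, `mu`, `distance_km`, `elevation_m`.
#' @return Data frame with per-MU means of `elevation_m`, `distance_km`,
#'   `work`, `slope_index`.
#' @export
mu_mean_indices <- function(stocks) {
  stopifnot(all(c("mu", "distance_km", "elevation_m") %in% names(stocks)))
  idx <- stock_indices(stocks$distance_km, stocks$elevation_m)
  d <- cbind(stocks[c("mu", "distance_km", "elevation_m")], idx)
  out <- stats::aggregate(
    d[c("elevation_m", "distance_km", "work", "slope_index")],
    by = list(mu = d$mu), FUN = mean)
  out[match(mu_levels(), out$mu, nomatch = 0), , drop = FALSE]
}

#' Correlate migration difficulty with management-unit lipid content
#'
#' Pearson correlation of MU mean whole-body lipid with each of the four
#' difficulty indices (elevation, distance, work, slope), with two-sided
#' p-values from the t transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}.
#'
#' @param mu_indices Data frame as from [mu_mean_indices()] (or the packaged
#'   [fraser_mu_indices()] fixture), with an `mu` column.
#' @param mu_lipid Data frame with `mu` and `lipid_mean` (percent).
#' @return Data frame with `index`, `pearson_r`, `p_value`, `n`.
#' @examples
#' difficulty_correlation(fraser_mu_indices(), fraser_mu_lipid())
#' @export
difficulty_correlation <- function(mu_indices, mu_lipid) {
  stopifnot("mu" %in% names(mu_indices), all(c("mu", "lipid_mean") %in% names(mu_lipid)))
  d <- merge(mu_indices, mu_lipid[c("mu", "lipid_mean")], by = "mu")
  if (nrow(d) < 3) stop("need at least 3 MUs with both indices and lipid")
  cols <- c(elevation = "elevation_m", distance = "distance_km",
            work = "work", slope = "slope_index")
  rows <- lapply(names(cols), function(nm) {
    v <- d[[cols[[nm]]]]
    if (stats::var(v) == 0 || stats::var(d$lipid_mean) == 0)
      stop("zero variance in ", nm, " or lipid")
    ct <- stats::cor.test(v, d$lipid_mean, method = "pearson")
    data.frame(index = nm, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
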
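#' Management-unit labels for Fraser River Chinook
#'
#' The five management units (MUs) group Fraser Chinook conservation units by
#' run timing (Spring/Summer/Fall), typical age at return (4 or 5), and
#' juvenile life history (stream- or ocean-type).
#'
#' @return Character vector of the five MU labels in run-timing order.
#' @export
mu_levels <- function() {
  c("Spring5_2", "Spring4_2", "Summer5_2", "Summer4_1", "Fall4_1")
}

#' Apply a fat-meter calibration to survey records
#'
#' Adds a `wbl_pct` (whole-body lipid, percent wet weight) column computed
#' from `reading_pos1` via [predict_whole_body_lipid()]. Records with a
#' missing reading get `NA` and are counted; readings below the calibration
#' floor are evaluated at the floor and counted.
#'
#' @param records Survey data frame with a `reading_pos1` column.
#' @param cal A [piecewise_calibration()].
#' @return `records` with `wbl_pct` added; attributes `n_missing` and
#'   `n_floor` carry the counts.
#' @export
apply_calibration <- function(records, cal) {
  if (!"reading_pos1" %in% names(records))
    stop("records must carry reading_pos1")
  r <- records$reading_pos1
  ok <- is.finite(r)
  wbl <- rep(NA_real_, length(r))
  n_floor <- sum(r[ok] < cal$floor)
  if (any(ok))
    wbl[ok] <- suppressWarnings(predict_whole_body_lipid(r[ok], cal))
  if (n_floor > 0)
    message(sprintf("%d reading(s) below floor %.2f evaluated at the floor",
                    n_floor, cal$floor))
  if (sum(!ok) > 0)
    message(sprintf("%d record(s) missing a position-1 reading; wbl_pct = NA",
                    sum(!ok)))
  records$wbl_pct <- wbl
  attr(records, "n_missing") <- sum(!ok)
  attr(records, "n_floor") <- n_floor
  records
}

#' Fit the lipid-to-energy-density conversion
#'
#' Ordinary least squares line relating whole-body lipid content (percent)
#' to energy density (kcal/kg wet mass). Energy density in salmon is driven
#' almost entirely by lipid, so an affine map with positive slope is the
#' standard model.
#'
#' @param lipid_pct Lipid percentages.
#' @param ed_kcal_kg Energy densities, kcal/kg.
#' @return Object of class `energy_conversion`: `intercept` (kcal/kg),
#'   `slope` (kcal/kg per lipid percentage point), `kj_per_kcal` (4.184).
#' @seealso [table3_energy_conversion()] for the packaged default.
#' @export
fit_ed_conversion <- function(lipid_pct, ed_kcal_kg) {
  ok <- is.finite(lipid_pct) & is.finite(ed_kcal_kg)
  lipid_pct <- lipid_pct[ok]; ed_kcal_kg <- ed_kcal_kg[ok]
  if (length(lipid_pct) < 2 || length(unique(lipid_pct)) < 2)
    stop("need at least 2 pairs with distinct lipid values")
  f <- stats::lm(ed_kcal_kg ~ lipid_pct)
  co <- unname(stats::coef(f))
  if (co[2] <= 0) stop("fitted conversion is not increasing in lipid")
  energy_conversion(intercept = co[1], slope = co[2])
}

#' @rdname fit_ed_conversion
#' @param intercept,slope Conversion coefficients (kcal/kg and kcal/kg per
#'   percentage point); `slope` must be positive.
#' @param kj_per_kcal Thermochemical conversion constant.
#' @export
energy_conversion <- function(intercept, slope, kj_per_kcal = 4.184) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  structure(list(intercept = intercept, slope = slope,
                 kj_per_kcal = kj_per_kcal),
            class = "energy_conversion")
}

#' @export
print.energy_conversion <- function(x, ...) {
  cat(sprintf("Energy density = %.2f + %.2f * lipid%%  [kcal/kg]\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Energy density from lipid content
#'
#' @param lipid_pct Whole-body lipid, percent, in `[0, 100]`.
#' @param conv An [energy_conversion()].
#' @return Energy density, kcal/kg.
#' @export
energy_density <- function(lipid_pct, conv) {
  stopifnot(inherits(conv, "energy_conversion"))
  if (any(lipid_pct < 0 | lipid_pct > 100, na.rm = TRUE))
    stop("lipid_pct must lie in [0, 100]")
  conv$intercept + conv$slope * lipid_pct
}

.stat_block <- function(v, prefix) {
  v <- v[is.finite(v)]
  out <- list(mean(v), stats::sd(v), min(v), max(v))
  names(out) <- paste0(prefix, c("_mean", "_sd", "_min", "_max"))
  out
}

#' Per-management-unit summary of a survey
#'
#' Descriptive statistics of lipid, energy density, fork length and weight
#' per MU, plus run timing: first catch date, the first date at which the
#' cumulative catch reaches at least half the MU total, and last catch date.
#' Empty MUs are omitted with a notice.
#'
#' @param records Survey data frame with `mu`, `date`, `wbl_pct` and
#'   optionally `ed_kcal_kg`, `fork_length`, `weight`.
#' @return Data frame, one row per MU present.
#' @export
mu_summary <- function(records) {
  stopifnot(all(c("mu", "date", "wbl_pct") %in% names(records)))
  records$date <- as.Date(records$date)
  mus <- mu_levels()
  rows <- list()
  for (m in mus) {
    d <- records[records$mu == m & is.finite(records$wbl_pct), , drop = FALSE]
    if (nrow(d) == 0) { message("MU ", m, " has no records; omitted"); next }
    dates <- sort(d$date)
    cum <- seq_along(dates) / length(dates)
    row <- c(list(mu = m, n = nrow(d)),
             .stat_block(d$wbl_pct, "lipid"),
             if ("ed_kcal_kg" %in% names(d)) .stat_block(d$ed_kcal_kg, "ed"),
             if ("fork_length" %in% names(d)) .stat_block(d$fork_length, "fl"),
             if ("weight" %in% names(d)) .stat_block(d$weight, "wt"),
             list(run_first = dates[1],
                  run_50pct = dates[which(cum >= 0.5)[1]],
                  run_last = dates[length(dates)]))
    rows[[m]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = groups differ). Groups must be ordered as desired.
.cld_insert_absorb <- function(sig) {
  g <- rownames(sig)
  sets <- list(g)
  for (i in seq_len(nrow(sig) - 1)) for (j in (i + 1):nrow(sig)) {
    if (!isTRUE(sig[i, j])) next
    a <- g[i]; b <- g[j]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s)
        new_sets <- c(new_sets, list(setdiff(s, a), setdiff(s, b)))
      else new_sets <- c(new_sets, list(s))
    }
    # drop duplicates and absorb sets contained in a strictly larger one
    new_sets <- unique(new_sets[lengths(new_sets) > 0])
    keep <- rep(TRUE, length(new_sets))
    for (k in seq_along(new_sets)) for (l in seq_along(new_sets)) {
      if (k != l && keep[k] && keep[l] &&
          length(new_sets[[k]]) < length(new_sets[[l]]) &&
          all(new_sets[[k]] %in% new_sets[[l]]))
        keep[k] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # order letters by the first (highest-ranked) member of each set
  first_idx <- vapply(sets, function(s) min(match(s, g)), numeric(1))
  sets <- sets[order(first_idx)]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    for (m in sets[[k]])
      letters_out[m] <- paste0(letters_out[m], LETTERS[k])
  letters_out
}

#' One-way ANOVA with Tukey HSD letter groupings
#'
#' Compares mean lipid content across groups (MUs) with a one-way ANOVA,
#' follows up with Tukey's honestly-significant-difference test on all
#' pairs (studentized-range distribution), and assigns a compact letter
#' display by the insert-and-absorb algorithm: groups sharing a letter do not
#' differ at `alpha`. Groups with fewer than 2 observations are excluded with
#' a notice. Letters are assigned with groups ordered by decreasing mean.
#'
#' @param values Numeric response (lipid percent).
#' @param groups Grouping factor/character of the same length.
#' @param alpha Significance level for the letter display.
#' @return List with `anova` (a `test_result`), `tukey` (data frame of
#'   pairwise differences and adjusted p-values), and `letters` (named
#'   character vector).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    message("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups with n >= 2")
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  a <- summary(fit)[[1]]
  res <- test_result(statistic = a$`F value`[1],
                     df = c(a$Df[1], a$Df[2]),
                     p_value = a$`Pr(>F)`[1], method = "one-way ANOVA")
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  means <- sort(tapply(values, g, mean), decreasing = TRUE)
  nm <- names(means)
  sig <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(nrow(tukey))) {
    pr <- strsplit(tukey$pair[k], "-", fixed = TRUE)[[1]]
    sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- tukey$p_adj[k] < alpha
  }
  list(anova = res, tukey = tukey, letters = .cld_insert_absorb(sig))
}

#' Seasonal trend of lipid content within a management unit
#'
#' OLS regression of whole-body lipid on day of year. The total within-season
#' change is reported two ways, since weekly summaries and a regression span
#' need not agree exactly: `total_change_pp` (slope times the observed
#' day-of-year span) and `weekly_change_pp` (last minus first weekly mean).
#'
#' @param records Survey data frame of one MU with `wbl_pct` and
#'   `day_of_year` (or `date`).
#' @return List of class `seasonal_trend`: `slope_pp_per_day`, `p_value`,
#'   `r2_adj`, `span_days`, `total_change_pp`, `weekly_change_pp`, `n`.
#' @export
seasonal_trend <- function(records) {
  if (!"day_of_year" %in% names(records)) {
    stopifnot("date" %in% names(records))
    records$day_of_year <- as.integer(format(as.Date(records$date), "%j"))
  }
  d <- records[is.finite(records$wbl_pct) & is.finite(records$day_of_year), ]
  if (nrow(d) < 3) stop("need at least 3 records with lipid and date")
  if (stats::var(d$day_of_year) == 0) stop("no spread in dates")
  if (stats::var(d$wbl_pct) == 0) {
    # constant response: flat line, no evidence against the null
    wk0 <- floor(d$day_of_year / 7)
    return(structure(list(
      slope_pp_per_day = 0, intercept = d$wbl_pct[1], p_value = 1,
      r2_adj = 0, span_days = diff(range(d$day_of_year)),
      total_change_pp = 0, weekly_change_pp = 0, n = nrow(d)),
      class = "seasonal_trend"))
  }
  f <- stats::lm(wbl_pct ~ day_of_year, data = d)
  s <- summary(f)
  slope <- unname(stats::coef(f)[2])
  p <- s$coefficients[2, 4]
  if (is.nan(p)) p <- 1
  span <- diff(range(d$day_of_year))
  wk <- floor(d$day_of_year / 7)
  wk_means <- tapply(d$wbl_pct, wk, mean)
  structure(list(
    slope_pp_per_day = slope,
    intercept = unname(stats::coef(f)[1]),
    p_value = p,
    r2_adj = s$adj.r.squared,
    span_days = span,
    total_change_pp = slope * span,
    weekly_change_pp = unname(wk_means[length(wk_means)] - wk_means[1]),
    n = nrow(d)
  ), class = "seasonal_trend")
}

#' @export
print.seasonal_trend <- function(x, ...) {
  cat(sprintf(
    "Seasonal lipid trend: %.4f pp/day over %d days (total %.2f pp), p = %.3g, n = %d\n",
    x$slope_pp_per_day, x$span_days, x$total_change_pp, x$p_value, x$n))
  invisible(x)
}

#' Compare seasonal lipid slopes between two management units (ANCOVA)
#'
#' F-test on the group-by-day interaction in the pooled regression of lipid
#' on day of year.
#'
#' @param records_a,records_b Survey data frames for the two MUs.
#' @return A `test_result`.
#' @export
compare_slopes <- function(records_a, records_b) {
  for (r in list(records_a, records_b))
    if (!all(c("wbl_pct", "day_of_year") %in% names(r)))
      stop("records need wbl_pct and day_of_year")
  d <- rbind(
    data.frame(y = records_a$wbl_pct, t = records_a$day_of_year, g = "a"),
    data.frame(y = records_b$wbl_pct, t = records_b$day_of_year, g = "b"))
  d <- d[is.finite(d$y) & is.finite(d$t), ]
  if (any(tapply(d$t, d$g, stats::var) == 0)) stop("no spread in dates")
  common <- stats::lm(y ~ t + g, data = d)
  separate <- stats::lm(y ~ t * g, data = d)
  a <- stats::anova(common, separate)
  test_result(statistic = a$F[2], df = c(a$Df[2], a$Res.Df[2]),
              p_value = a$`Pr(>F)`[2],
              method = "ANCOVA day-of-year slope comparison")
}

#' Hatchery vs. wild lipid comparison
#'
#' Welch two-sample t-test of whole-body lipid between fin-clipped (hatchery)
#' and unclipped (wild) fish, intended for a single population where all
#' hatchery releases are marked (e.g. Harrison River within Fall 4_1).
#'
#' @param records Survey data frame with `wbl_pct` and logical `fin_clipped`.
#' @return A `test_result`; `estimate` carries the two group means and
#'   `diff_pp` (clipped minus unclipped, percentage points).
#' @export
hatchery_wild_test <- function(records) {
  stopifnot(all(c("wbl_pct", "fin_clipped") %in% names(records)))
  d <- records[is.finite(records$wbl_pct) & !is.na(records$fin_clipped), ]
  clipped <- d$wbl_pct[d$fin_clipped]
  wild <- d$wbl_pct[!d$fin_clipped]
  if (length(clipped) < 2 || length(wild) < 2)
    stop("need both fin-clipped and unclipped fish (n >= 2 each)")
  tt <- stats::t.test(clipped, wild)
  test_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value, method = "Welch t-test hatchery vs wild",
              estimate = list(mean_clipped = mean(clipped),
                              mean_wild = mean(wild),
                              diff_pp = mean(clipped) - mean(wild)))
}

#' Weekly catch-per-unit-effort by management unit
#'
#' Aggregates catch events to ISO weeks: for each week and MU,
#' CPUE = total catch / total effort, effort in fathom-minutes per boat day.
#' Rows with non-positive effort are rejected and counted.
#'
#' @param events Data frame with `date`, `mu`, `catch`, `effort`.
#' @return Data frame with `iso_week`, `mu`, `catch`, `effort`, `cpue`.
#' @export
weekly_cpue <- function(events) {
  stopifnot(all(c("date", "mu", "catch", "effort") %in% names(events)))
  bad <- !is.finite(events$effort) | events$effort <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) with non-positive effort rejected")
    events <- events[!bad, , drop = FALSE]
  }
  if (nrow(events) == 0)
    return(data.frame(iso_week = character(), mu = character(),
                      catch = numeric(), effort = numeric(),
                      cpue = numeric()))
  wk <- format(as.Date(events$date), "%G-W%V")
  agg_c <- stats::aggregate(events$catch, list(iso_week = wk, mu = events$mu), sum)
  agg_e <- stats::aggregate(events$effort, list(iso_week = wk, mu = events$mu), sum)
  out <- merge(agg_c, agg_e, by = c("iso_week", "mu"))
  names(out)[3:4] <- c("catch", "effort")
  out$cpue <- out$catch / out$effort
  out[order(out$iso_week, out$mu), , drop = FALSE]
}
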
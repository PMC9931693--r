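test_that("applying a calibration fills wbl_pct and counts problem rows", {
  cal <- published_calibration()
  rec <- data.frame(reading_pos1 = c(0.6, 2, NA, 0.3))
  out <- suppressMessages(apply_calibration(rec, cal))
  expect_equal(round(out$wbl_pct[1], 2), 2.08)
  expect_equal(out$wbl_pct[2], predict_whole_body_lipid(2, cal))
  expect_true(is.na(out$wbl_pct[3]))
  expect_equal(attr(out, "n_missing"), 1)
  expect_equal(attr(out, "n_floor"), 1)
  empty <- apply_calibration(data.frame(reading_pos1 = numeric()), cal)
  expect_equal(nrow(empty), 0)
  same <- apply_calibration(data.frame(reading_pos1 = rep(3, 5)), cal)
  expect_equal(var(same$wbl_pct), 0)
})

test_that("energy conversion fit reproduces the MU-table least squares", {
  d <- fraser_mu_summary()
  conv <- fit_ed_conversion(d$lipid_mean, d$ed_mean)
  # frozen from the normal equations on the five printed MU pairs
  expect_equal(conv$slope, 84.28679, tolerance = 1e-6)
  expect_equal(conv$intercept, 819.95938, tolerance = 1e-6)
  expect_equal(round(energy_density(12.8, conv)), 1899)
  # two points: the exact interpolating line
  conv2 <- fit_ed_conversion(c(5, 10), c(1200, 1700))
  expect_equal(energy_density(c(5, 10), conv2), c(1200, 1700))
  expect_error(fit_ed_conversion(c(5, 5), c(1, 2)), "distinct")
  # affine and strictly increasing
  L <- seq(0, 20, by = 0.5)
  expect_true(all(diff(energy_density(L, conv)) > 0))
  expect_equal(energy_density(0, conv), conv$intercept)
})

test_that("MU summary matches a brute-force pass over the records", {
  s <- make_toy_survey(40)
  ms <- mu_summary(s)
  expect_equal(ms$n, 40)
  expect_equal(ms$lipid_mean, mean(s$wbl_pct))
  expect_equal(ms$lipid_sd, sd(s$wbl_pct))
  expect_equal(ms$lipid_min, min(s$wbl_pct))
  expect_equal(ms$ed_max, max(s$ed_kcal_kg))
  expect_equal(ms$run_first, min(s$date))
  expect_equal(ms$run_last, max(s$date))
  # cumulative-50% date by brute-force scan
  dates <- sort(s$date)
  cum <- cumsum(rep(1, length(dates)))
  expect_equal(ms$run_50pct, dates[which(cum >= length(dates) / 2)[1]])
  # single record degenerates cleanly
  one <- mu_summary(s[1, ])
  expect_equal(one$lipid_mean, s$wbl_pct[1])
  expect_equal(one$lipid_sd, NA_real_)
  expect_equal(one$run_first, one$run_last)
  expect_equal(one$run_first, one$run_50pct)
})

test_that("identical groups share one Tukey letter and a zero F", {
  v <- rep(c(5, 6, 7), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(v, g)
  expect_equal(res$anova$statistic, 0)
  expect_true(all(res$letters == "A"))
})

test_that("Tukey adjusted p agrees with a permutation oracle on a toy set", {
  # groups close enough to exchangeable for the label-permutation null of
  # the maximum absolute pairwise mean difference to track the
  # studentized-range familywise adjustment
  set.seed(66)
  v <- c(5.0, 5.3, 4.9, 5.2, 5.1,  5.4, 5.0, 5.6, 5.2, 5.3,
         5.5, 5.1, 5.0, 5.7, 5.4)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- anova_tukey(v, g)
  m <- tapply(v, g, mean)
  perm <- replicate(4000, {
    gp <- sample(g)
    mm <- tapply(v, gp, mean)
    max(abs(c(mm[1] - mm[2], mm[1] - mm[3], mm[2] - mm[3])))
  })
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    obs <- abs(m[pair[1]] - m[pair[2]])
    p_perm <- mean(perm >= obs)
    p_tukey <- res$tukey$p_adj[res$tukey$pair == paste(pair, collapse = "-")]
    expect_lt(abs(p_tukey - p_perm), 0.1)
  }
})

test_that("groups with n < 2 are excluded from the ANOVA with a notice", {
  v <- c(1, 2, 3, 4, 9)
  g <- c("a", "a", "b", "b", "tiny")
  expect_message(res <- anova_tukey(v, g), "tiny")
  expect_setequal(names(res$letters), c("a", "b"))
})

test_that("seasonal trend slope equals the closed form and handles edges", {
  d <- data.frame(day_of_year = c(200, 210, 220, 230, 240),
                  wbl_pct = c(12, 11.5, 10.8, 10.1, 9.4))
  tr <- seasonal_trend(d)
  expect_equal(tr$slope_pp_per_day,
               cov(d$day_of_year, d$wbl_pct) / var(d$day_of_year))
  expect_equal(tr$total_change_pp, tr$slope_pp_per_day * 40)
  const <- data.frame(day_of_year = c(200, 210, 220), wbl_pct = rep(8, 3))
  trc <- seasonal_trend(const)
  expect_equal(trc$slope_pp_per_day, 0)
  expect_equal(trc$p_value, 1)
  expect_error(seasonal_trend(
    data.frame(day_of_year = rep(200, 5), wbl_pct = 1:5)), "spread")
})

test_that("slope ANCOVA equals the nested-RSS F and is calibrated", {
  a <- data.frame(day_of_year = c(200, 210, 220, 230, 240),
                  wbl_pct = c(12, 11.2, 10.1, 9.6, 8.5))
  b <- data.frame(day_of_year = c(205, 215, 225, 235, 245),
                  wbl_pct = c(9, 8.8, 8.4, 8.1, 7.9))
  res <- compare_slopes(a, b)
  d <- rbind(cbind(a, g = "a"), cbind(b, g = "b"))
  rss_c <- sum(resid(lm(wbl_pct ~ day_of_year + g, d))^2)
  full <- lm(wbl_pct ~ day_of_year * g, d)
  f_manual <- (rss_c - sum(resid(full)^2)) /
    (sum(resid(full)^2) / full$df.residual)
  expect_equal(res$statistic, f_manual)
  # null simulation: common generating slope, nominal rejection rate
  set.seed(101)
  p <- replicate(100, {
    t1 <- runif(40, 200, 260); t2 <- runif(40, 200, 260)
    compare_slopes(
      data.frame(day_of_year = t1, wbl_pct = 15 - 0.05 * t1 + rnorm(40)),
      data.frame(day_of_year = t2, wbl_pct = 14 - 0.05 * t2 + rnorm(40))
    )$p_value
  })
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.13)
  # survey-scale power for a 0.04 pp/day slope difference
  set.seed(102)
  t1 <- runif(400, 200, 260); t2 <- runif(400, 200, 260)
  strong <- compare_slopes(
    data.frame(day_of_year = t1, wbl_pct = 20 - 0.09 * t1 + rnorm(400)),
    data.frame(day_of_year = t2, wbl_pct = 20 - 0.05 * t2 + rnorm(400)))
  expect_lt(strong$p_value, 0.001)
})

test_that("hatchery-wild Welch test matches the textbook computation", {
  clipped <- c(5.1, 6.2, 5.8, 6.5, 5.4, 6.0)
  wild <- seq(6, 8, length.out = 20) + 0.3 * sin(1:20)
  rec <- data.frame(wbl_pct = c(clipped, wild),
                    fin_clipped = rep(c(TRUE, FALSE), c(6, 20)))
  res <- hatchery_wild_test(rec)
  se <- sqrt(var(clipped) / 6 + var(wild) / 20)
  t_manual <- (mean(clipped) - mean(wild)) / se
  expect_equal(res$statistic, t_manual)
  expect_equal(res$estimate$diff_pp, mean(clipped) - mean(wild))
  # identical groups: t = 0, p = 1
  same <- data.frame(wbl_pct = rep(c(5, 6, 7), 2),
                     fin_clipped = rep(c(TRUE, FALSE), each = 3))
  res0 <- hatchery_wild_test(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(hatchery_wild_test(
    data.frame(wbl_pct = 1:5, fin_clipped = rep(FALSE, 5))), "both")
})

test_that("synthetic Harrison contrast recovers the configured offset", {
  diffs <- vapply(1:5, function(i) {
    s <- generate_survey(survey_sim_config(seed = 300 + i))
    s <- apply_calibration(s, published_calibration())
    hatchery_wild_test(s[s$stock == "Harrison", ])$estimate$diff_pp
  }, numeric(1))
  expect_equal(mean(diffs), -0.82, tolerance = 0.25)
})

test_that("weekly CPUE is total catch over total effort per ISO week", {
  ev <- data.frame(date = as.Date("2020-09-21") + c(0, 1, 2),
                   mu = "Fall4_1", catch = c(4, 3, 3), effort = c(2, 2, 1))
  out <- weekly_cpue(ev)
  expect_equal(nrow(out), 1)
  expect_equal(out$cpue, 2)
  # splitting a week's catch across equal-effort days changes nothing
  ev2 <- data.frame(date = as.Date("2020-09-21") + c(0, 1),
                    mu = "Fall4_1", catch = c(10, 0), effort = c(5, 5))
  ev3 <- data.frame(date = as.Date("2020-09-21"),
                    mu = "Fall4_1", catch = 10, effort = 10)
  expect_equal(weekly_cpue(ev2)$cpue, weekly_cpue(ev3)$cpue)
  # brute-force groupby oracle on a larger toy table
  set.seed(12)
  ev4 <- data.frame(date = as.Date("2020-08-01") + sample(0:27, 20, TRUE),
                    mu = sample(c("Fall4_1", "Summer4_1"), 20, TRUE),
                    catch = rpois(20, 5), effort = runif(20, 1, 4))
  out4 <- weekly_cpue(ev4)
  key <- paste(format(ev4$date, "%G-W%V"), ev4$mu)
  for (k in unique(key)) {
    rows <- key == k
    expect_equal(out4$cpue[paste(out4$iso_week, out4$mu) == k],
                 sum(ev4$catch[rows]) / sum(ev4$effort[rows]))
  }
  expect_message(weekly_cpue(
    data.frame(date = as.Date("2020-08-01"), mu = "Fall4_1",
               catch = 1, effort = 0)), "rejected")
})
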
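# brute-force model II losses: SMA minimizes the summed triangle areas,
# equivalently sum((y - a - b x)^2) / |b|; MA minimizes perpendicular
# distances, sum((y - a - b x)^2) / (1 + b^2)
.bf_model2 <- function(x, y, loss = c("SMA", "MA")) {
  loss <- match.arg(loss)
  fn <- function(p) {
    r2 <- sum((y - p[1] - p[2] * x)^2)
    if (loss == "SMA") r2 / abs(p[2]) else r2 / (1 + p[2]^2)
  }
  best <- NULL
  for (b0 in c(0.5, 1, 2, 5)) {
    o <- stats::optim(c(mean(y) - b0 * mean(x), b0), fn,
                      control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

test_that("model II fits recover an exact line with either estimator", {
  x <- c(1, 2, 3, 4, 5)
  for (m in c("SMA", "MA")) {
    f <- fit_model2(x, 2 * x + 1, method = m)
    expect_equal(f$slope, 2, tolerance = 1e-12)
    expect_equal(f$intercept, 1, tolerance = 1e-12)
    expect_equal(f$r2_adj, 1, tolerance = 1e-12)
  }
})

test_that("closed-form SMA and MA match brute-force loss minimization", {
  set.seed(21)
  for (rep in 1:5) {
    x <- runif(10, 0.5, 12)
    y <- 1.5 + 0.9 * x + rnorm(10, 0, 1.2)
    for (m in c("SMA", "MA")) {
      f <- fit_model2(x, y, method = m)
      p <- .bf_model2(x, y, m)
      expect_equal(f$slope, p[2], tolerance = 1e-4)
      expect_equal(f$intercept, p[1], tolerance = 1e-3)
    }
  }
})

test_that("SMA slope is sign(r)*sd(y)/sd(x) and symmetric under axis swap", {
  set.seed(3)
  x <- runif(20); y <- 3 - 2 * x + rnorm(20, 0, 0.3)
  f <- fit_model2(x, y)
  expect_equal(f$slope, sign(cor(x, y)) * sd(y) / sd(x))
  f_rev <- fit_model2(y, x)
  expect_equal(f_rev$slope, 1 / f$slope)
})

test_that("model II estimates approach OLS as response noise vanishes", {
  set.seed(8)
  x <- runif(40, 1, 15)
  y <- -2 + 6.8 * x + rnorm(40, 0, 1e-7)
  ols <- unname(coef(lm(y ~ x)))
  for (m in c("SMA", "MA")) {
    f <- fit_model2(x, y, method = m)
    expect_equal(f$slope, ols[2], tolerance = 1e-6)
    expect_equal(f$intercept, ols[1], tolerance = 1e-6)
  }
})

test_that("model II input validation rejects degenerate data", {
  expect_error(fit_model2(1:2, 1:2), "at least 3")
  expect_error(fit_model2(rep(1, 5), 1:5), "variance")
  expect_error(fit_model2(c(-1, 1, 2), 1:3, log_x = TRUE), "positive")
})

test_that("segmented fit recovers generating parameters on noise-free data", {
  d <- make_piecewise_xy()
  f <- fit_segmented(d$x, d$y)
  expect_lt(abs(f$breakpoint - 1.059), 1e-6)
  expect_lt(abs(f$intercept - (-1.973)), 1e-6)
  expect_lt(abs(f$slope_below - 6.758), 1e-6)
  expect_lt(abs(f$slope_change - (-6.202)), 1e-6)
})

test_that("segmented fit of purely linear data estimates no slope change", {
  x <- seq(1, 20, length.out = 30)
  f <- fit_segmented(x, 0.5 + 2 * x)
  expect_lt(abs(f$slope_change), 1e-6)
  expect_equal(f$slope_below, 2, tolerance = 1e-8)
})

test_that("segmented RSS never exceeds the single-line OLS RSS", {
  set.seed(14)
  for (rep in 1:10) {
    x <- runif(40, 0, 10)
    y <- 1 + 0.8 * x + rnorm(40)
    f <- fit_segmented(x, y)
    h <- pmax(x - f$breakpoint, 0)
    rss_seg <- sum(lm.fit(cbind(1, x, h), y)$residuals^2)
    rss_ols <- sum(resid(lm(y ~ x))^2)
    expect_lte(rss_seg, rss_ols + 1e-9)
  }
})

test_that("segmented fit falls back to a single line when no break fits", {
  x <- c(1, 1, 1, 2, 2, 2)  # no candidate leaves 3 points per side
  y <- c(1, 1.1, 0.9, 2, 2.1, 1.9)
  expect_warning(f <- fit_segmented(x, y), "single-segment")
  expect_true(f$single_segment)
  expect_equal(f$slope_change, 0)
})

test_that("piecewise prediction matches the published worked points", {
  cal <- published_calibration()
  expect_equal(round(predict_whole_body_lipid(0.6, cal), 2), 2.08)
  # continuity at the breakpoint: both branches agree
  eps <- 1e-9
  expect_equal(predict_whole_body_lipid(1.059 - eps, cal),
               predict_whole_body_lipid(1.059 + eps, cal),
               tolerance = 1e-6)
  expect_equal(predict_whole_body_lipid(1.059, cal),
               -1.973 + 6.758 * 1.059)
  expect_equal(round(predict_whole_body_lipid(10, cal), 2), 10.15)
  # increasing on [floor, inf) with the published slopes
  r <- seq(0.6, 20, by = 0.05)
  expect_true(all(diff(predict_whole_body_lipid(r, cal)) > 0))
})

test_that("predictions clip to [0, 100] and floor readings warn", {
  cal <- published_calibration()
  low <- piecewise_calibration(-10, 1, 0, 2, floor = 0.6)
  expect_equal(suppressWarnings(predict_whole_body_lipid(1, low)), 0)
  expect_warning(predict_whole_body_lipid(0.2, cal), "floor")
  expect_equal(suppressWarnings(predict_whole_body_lipid(0.2, cal)),
               predict_whole_body_lipid(0.6, cal))
  expect_error(predict_whole_body_lipid(NA_real_, cal), "finite")
})

test_that("ranking covers all 21 models and prefers position 1 segmented", {
  set.seed(31)
  d <- generate_calibration_set(calibration_sim_config(
    seed = 31, reading_noise_sd = 0.15, pos23_extra_noise_sd = 0.8))
  rk <- rank_calibrations(d)
  expect_equal(nrow(rk), 21)
  expect_setequal(unique(rk$family), c("modelII", "modelII_log", "segmented"))
  expect_equal(rk$position_combo[1], "1")
  expect_equal(rk$family[1], "segmented")
  expect_true(all(diff(rk$r2_adj) <= 1e-12))
})

test_that("identical readings across positions give identical rankings", {
  d <- make_piecewise_xy(noise_sd = 0)
  set.seed(4)
  samples <- data.frame(reading_pos1 = d$x, reading_pos2 = d$x,
                        reading_pos3 = d$x,
                        whole_body_lipid_pct = d$y + rnorm(length(d$y), 0, 0.5))
  rk <- rank_calibrations(samples)
  for (fam in unique(rk$family)) {
    r2 <- rk$r2_adj[rk$family == fam]
    expect_lt(diff(range(r2)), 1e-12)
  }
})

test_that("interaction F-test matches its nested-RSS definition", {
  set.seed(77)
  x <- runif(30, 1, 10); z <- runif(30, 0, 1)
  y <- 1 + 2 * x + 0.5 * z + rnorm(30, 0, 0.5)
  res <- covariate_interaction_test(x, y, z)
  rss_red <- sum(resid(lm(y ~ x + z))^2)
  full <- lm(y ~ x + z + x:z)
  rss_full <- sum(resid(full)^2)
  f_manual <- (rss_red - rss_full) / (rss_full / full$df.residual)
  expect_equal(res$statistic, f_manual)
  # strong interaction is detected
  y2 <- 1 + 2 * x + 3 * x * z + rnorm(30, 0, 0.3)
  expect_lt(covariate_interaction_test(x, y2, z)$p_value, 0.001)
})

test_that("interaction test holds its nominal type-I rate under the null", {
  set.seed(123)
  p <- replicate(200, {
    x <- runif(25, 1, 10); z <- runif(25)
    y <- 1 + 2 * x + rnorm(25)
    covariate_interaction_test(x, y, z)$p_value
  })
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.11)
})

test_that("sex ANCOVA detects slope heterogeneity and nothing more", {
  set.seed(55)
  x_m <- runif(20, 1, 10); x_f <- runif(20, 1, 10)
  # identical generating process: both tests quiet
  y_m <- 1 + 2 * x_m + rnorm(20, 0, 0.4)
  y_f <- 1 + 2 * x_f + rnorm(20, 0, 0.4)
  same <- sex_ancova(x_m, y_m, x_f, y_f)
  expect_gt(same$slopes$p_value, 0.05)
  expect_false(is.null(same$intercepts))
  # slopes 6.8 vs 3.0 at low noise: slope test fires, intercept test gated
  y_m2 <- 1 + 6.8 * x_m + rnorm(20, 0, 0.4)
  y_f2 <- 1 + 3.0 * x_f + rnorm(20, 0, 0.4)
  diff_s <- sex_ancova(x_m, y_m2, x_f, y_f2)
  expect_lt(diff_s$slopes$p_value, 0.01)
  expect_null(diff_s$intercepts)
  expect_error(sex_ancova(rep(1, 5), 1:5, x_f, y_f), "variance")
})

test_that("sex ANCOVA slope F matches dummy-variable regression", {
  x_m <- c(1, 2, 3, 4, 5); y_m <- c(1.1, 2.9, 5.2, 7.1, 8.8)
  x_f <- c(1, 2, 3, 4, 5); y_f <- c(2.0, 3.1, 3.9, 5.2, 6.1)
  res <- sex_ancova(x_m, y_m, x_f, y_f)
  g <- rep(0:1, each = 5); x <- c(x_m, x_f); y <- c(y_m, y_f)
  rss_c <- sum(resid(lm(y ~ x + g))^2)
  full <- lm(y ~ x + g + x:g)
  f_manual <- (rss_c - sum(resid(full)^2)) /
    (sum(resid(full)^2) / full$df.residual)
  expect_equal(res$slopes$statistic, f_manual)
})
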
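# Noise-free readings spanning the published calibration with enough points
# on each side of the breakpoint for a segmented fit.
make_piecewise_xy <- function(cal = published_calibration(),
                              n_below = 8, n_above = 55, noise_sd = 0) {
  x <- c(seq(cal$floor, cal$breakpoint - 0.01, length.out = n_below),
         seq(cal$breakpoint + 0.05, 16.8, length.out = n_above))
  y <- predict_whole_body_lipid(x, cal)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  list(x = x, y = y)
}

# Reading design mimicking the homogenization cohort: whole-body lipid
# uniform over the observed range, mapped through the calibration inverse.
make_cohort_xy <- function(n = 63, noise_sd = 1,
                           cal = published_calibration()) {
  lipid <- stats::runif(n, 2.2, 13.9)
  x <- reading_from_lipid(lipid, cal)
  y <- predict_whole_body_lipid(x, cal) + stats::rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

# Tiny survey-like frame for summary/trend oracles.
make_toy_survey <- function(n = 30, mu = "Summer4_1", seed = 99) {
  set.seed(seed)
  doy <- sample(200:260, n, replace = TRUE)
  data.frame(
    fish_id = paste0("f", seq_len(n)),
    date = as.Date(doy - 1, origin = "2020-01-01"),
    day_of_year = doy,
    mu = mu,
    stock = mu,
    wbl_pct = stats::runif(n, 5, 15),
    ed_kcal_kg = stats::runif(n, 1200, 2100),
    fork_length = stats::rnorm(n, 650, 50),
    weight = stats::runif(n, 4, 10),
    fin_clipped = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE)
}
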
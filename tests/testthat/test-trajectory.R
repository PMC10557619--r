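test_that("data from the model class are interpolated exactly", {
  set.seed(10)
  spec <- rcs_spec()
  ages <- stats::runif(500, 0, 100)
  beta <- c(0.4, 0.01, 0.3, -0.5, 0.25, -0.1)
  y <- drop(cbind(1, rcs_basis(ages, spec)) %*% beta)
  m <- fit_trajectory(data.frame(age = ages, value = y), spec,
                      covariates = character(0))
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-6)
  expect_lt(m$residual_sd, 1e-8)
})

test_that("noise-free linear data give slope 0.3 and zero nonlinear terms", {
  set.seed(11)
  ages <- stats::runif(300, 0, 100)
  sex <- sample(c("F", "M"), 300, replace = TRUE)
  y <- 2 + 0.3 * ages
  m <- fit_trajectory(data.frame(age = ages, value = y, sex = sex))
  expect_equal(unname(m$coefficients["age"]), 0.3, tolerance = 1e-6)
  expect_lt(max(abs(m$coefficients[grep("^rcs", names(m$coefficients))])), 1e-6)
  expect_equal(unname(difference_per_year(m, c(10, 50, 90))), rep(0.3, 3),
               tolerance = 1e-6)
})

test_that("the sex covariate is estimated and applied at prediction", {
  set.seed(12)
  ages <- stats::runif(400, 0, 100)
  sex <- rep(c("F", "M"), 200)
  y <- 1 + 0.02 * ages + 0.5 * (sex == "F")
  m <- fit_trajectory(data.frame(age = ages, value = y, sex = sex))
  expect_equal(unname(m$coefficients["sexF"]), 0.5, tolerance = 1e-6)
  expect_equal(predict_curve(m, 50, "female") - predict_curve(m, 50, "male"),
               0.5, tolerance = 1e-6)
  # average reference weights by the observed female proportion
  expect_equal(predict_curve(m, 50, "average"),
               predict_curve(m, 50, "male") + 0.5 * m$p_female,
               tolerance = 1e-6)
})

test_that("predictions satisfy the least-squares mean identity", {
  dat <- quad_fit_data(150, seed = 21)
  m <- fit_trajectory(dat)
  expect_equal(mean(predict_curve(m, dat$age, "average")), mean(dat$value),
               tolerance = 1e-8)
})

test_that("predictions beyond the last knot are affine in age", {
  dat <- quad_fit_data(150, seed = 22)
  m <- fit_trajectory(dat)
  p <- predict_curve(m, c(92, 96, 100))
  expect_equal(p[2] - p[1], p[3] - p[2], tolerance = 1e-8)
  expect_error(predict_curve(m, 130), "\\[0, 120\\]")
})

test_that("constant data give a flat curve with zero derivative", {
  set.seed(13)
  ages <- stats::runif(200, 0, 100)
  m <- fit_trajectory(data.frame(age = ages, value = rep(3.3, 200)),
                      covariates = character(0))
  expect_equal(unname(predict_curve(m, c(5, 50, 95))), rep(3.3, 3),
               tolerance = 1e-8)
  expect_lt(max(abs(difference_per_year(m, seq(1, 99, by = 7)))), 1e-8)
})

test_that("the analytic derivative matches finite differences on a fitted model", {
  dat <- quad_fit_data(200, seed = 23)
  m <- fit_trajectory(dat)
  ages <- seq(1, 99, by = 0.5)
  d <- difference_per_year(m, ages)
  h <- 0.005
  d_num <- (predict_curve(m, ages + h) - predict_curve(m, ages - h)) / (2 * h)
  expect_lt(max(abs(d - d_num) / pmax(abs(d_num), 1e-6)), 1e-4)
})

test_that("percent difference per year composes derivative over fit", {
  dat <- quad_fit_data(200, seed = 24)
  m <- fit_trajectory(dat)
  ages <- seq(2, 90, by = 1)
  expect_equal(percent_difference_per_year(m, ages),
               100 * difference_per_year(m, ages) / predict_curve(m, ages),
               tolerance = 1e-9)
})

test_that("exponential growth shows a ~2 percent yearly difference", {
  set.seed(14)
  ages <- stats::runif(3000, 0, 100)
  y <- exp(0.02 * ages)
  m <- fit_trajectory(data.frame(age = ages, value = y),
                      covariates = character(0))
  pct <- percent_difference_per_year(m, seq(5, 85, by = 5))
  expect_true(all(abs(pct - 2) < 0.2))
})

test_that("extrema are classified as peak, minimum or none", {
  dat <- quad_fit_data(500, seed = 25)
  ex <- find_extremum(fit_trajectory(dat))
  expect_equal(ex$type, "peak")
  expect_lt(abs(ex$age - 25), 2)

  # monotone truth -> none
  set.seed(15)
  ages <- stats::runif(400, 0, 100)
  mono <- fit_trajectory(data.frame(age = ages, value = 1 + 0.01 * ages),
                         covariates = character(0))
  expect_equal(find_extremum(mono)$type, "none")

  # U-shape with minimum at 40
  gen <- generate_feature_table(
    list(truth_record("b1", "MD", "quadratic",
                      params = c(1.2, -0.016, 0.0002), noise_sd = 0.01)),
    default_cohorts(500), seed = 26)
  mu <- fit_trajectory(fit_data(gen$table, "MD"))
  exu <- find_extremum(mu)
  expect_equal(exu$type, "minimum")
  expect_lt(abs(exu$age - 40), 2)
})

test_that("value shifts and rescalings act on the fitted curve as expected", {
  dat <- quad_fit_data(200, seed = 27)
  m <- fit_trajectory(dat)
  ages <- seq(5, 95, by = 5)

  dat_shift <- dat; dat_shift$value <- dat$value + 10
  m_shift <- fit_trajectory(dat_shift)
  expect_equal(predict_curve(m_shift, ages), predict_curve(m, ages) + 10,
               tolerance = 1e-8)
  expect_equal(difference_per_year(m_shift, ages),
               difference_per_year(m, ages), tolerance = 1e-8)

  dat_scale <- dat; dat_scale$value <- dat$value * 7
  m_scale <- fit_trajectory(dat_scale)
  expect_equal(difference_per_year(m_scale, ages),
               7 * difference_per_year(m, ages), tolerance = 1e-8)
  expect_equal(percent_difference_per_year(m_scale, ages),
               percent_difference_per_year(m, ages), tolerance = 1e-8)
})

test_that("degenerate fits raise informative errors", {
  expect_error(fit_trajectory(data.frame(age = 1:5, value = 1:5),
                              covariates = character(0)),
               "more observations")
  set.seed(16)
  dat <- data.frame(age = stats::runif(100, 0, 100))
  dat$value <- stats::rnorm(100)
  dat$sex <- "F"  # sexF column constant = collinear with intercept
  expect_error(fit_trajectory(dat), "collinear")
})

test_that("noise-free bootstrap bands collapse onto the point fit", {
  set.seed(17)
  spec <- rcs_spec()
  ages <- stats::runif(300, 0, 100)
  beta <- c(0.4, 0.01, 0.3, -0.5, 0.25, -0.1)
  dat <- data.frame(age = ages,
                    value = drop(cbind(1, rcs_basis(ages, spec)) %*% beta),
                    subject_id = seq_along(ages))
  bt <- bootstrap_trajectory(dat, spec, character(0),
                             pipeline_config(B = 50, seed = 1))
  expect_lt(max(bt$upper - bt$lower), 1e-6)
  expect_equal(bt$B_dropped, 0)
})

test_that("bootstrap output is reproducible under a fixed seed", {
  dat <- quad_fit_data(80, seed = 28)
  b1 <- bootstrap_trajectory(dat, config = pipeline_config(B = 40, seed = 5))
  b2 <- bootstrap_trajectory(dat, config = pipeline_config(B = 40, seed = 5))
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_identical(b1$extremum, b2$extremum)
  b3 <- bootstrap_trajectory(dat, config = pipeline_config(B = 40, seed = 6))
  expect_false(identical(b1$lower, b3$lower))
})

test_that("bootstrap resamples whole subjects", {
  # two-session infant subjects: both sessions follow their subject
  gen <- generate_feature_table(list(quad_truth()),
                                default_cohorts(60, infant_sessions = c(2, 2)),
                                seed = 29)
  dat <- fit_data(gen$table)
  bt <- bootstrap_trajectory(dat, config = pipeline_config(B = 25, seed = 2))
  expect_s3_class(bt, "trajectory_bootstrap")
  expect_equal(bt$B_used + bt$B_dropped, 25)
})

test_that("binned rates average the curve over cohort bins", {
  ages <- seq(0, 100, by = 0.1)
  expect_equal(bin_rates(ages, rep(1, length(ages)))$mean_pct_per_year,
               rep(1, 4))
  split_pct <- ifelse(ages < 21, 1, -1)
  br <- bin_rates(ages, split_pct)
  expect_equal(br$mean_pct_per_year[br$bin == "infant"], 1)
  expect_gt(br$mean_pct_per_year[br$bin == "development"], 0.8)
  expect_equal(br$mean_pct_per_year[br$bin == "aging"], -1)

  # trapezoid oracle on a linear rate curve (exact for uniform grids)
  lin <- 0.5 + 0.02 * ages
  br_lin <- bin_rates(ages, lin)
  for (i in seq_len(4)) {
    sel <- ages >= default_bins()$low[i] & ages < default_bins()$high[i]
    x <- ages[sel]; y <- lin[sel]
    trap <- sum((y[-1] + y[-length(y)]) / 2 * diff(x)) / (max(x) - min(x))
    expect_equal(br_lin$mean_pct_per_year[i], trap, tolerance = 1e-6)
  }
  expect_warning(bin_rates(c(1, 2), c(0.1, 0.2)), "empty bins")
})
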
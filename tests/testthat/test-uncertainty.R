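test_that("beta fit enforces the mean and is symmetric for symmetric input", {
  bp <- beta_from_mean_ui(0.5, 0.35, 0.65)
  expect_equal(bp$alpha, bp$beta, tolerance = 1e-6)
  expect_equal(bp$alpha / (bp$alpha + bp$beta), 0.5, tolerance = 1e-10)

  bp2 <- beta_from_mean_ui(0.3, 0.25, 0.36)
  expect_equal(bp2$alpha / (bp2$alpha + bp2$beta), 0.3, tolerance = 1e-10)
  expect_false(bp2$point_mass)
})

test_that("beta quantile fits round-trip intervals generated from true betas", {
  set.seed(2024)
  for (i in 1:50) {
    a <- stats::runif(1, 0.8, 60)
    b <- stats::runif(1, 0.8, 120)
    m <- a / (a + b)
    lo <- stats::qbeta(0.025, a, b)
    hi <- stats::qbeta(0.975, a, b)
    bp <- beta_from_mean_ui(m, lo, hi, tolerance = 1e-6)
    expect_equal(stats::qbeta(0.025, bp$alpha, bp$beta), lo, tolerance = 1e-5)
    expect_equal(stats::qbeta(0.975, bp$alpha, bp$beta), hi, tolerance = 1e-5)
  }
})

test_that("zero-width intervals become flagged point masses", {
  bp <- beta_from_mean_ui(0.3, 0.3, 0.3)
  expect_true(bp$point_mass)
  expect_identical(cheproj:::sample_beta_params(bp, 5), rep(0.3, 5))
  expect_error(beta_from_mean_ui(0.3, 0.32, 0.36), "lo <= mean")
})

test_that("gamma moment matching is exact in closed form", {
  gp <- gamma_from_mean_sd(4.5, 2.9)
  expect_equal(gp$shape, (4.5 / 2.9)^2, tolerance = 1e-12)
  expect_equal(gp$scale, 2.9^2 / 4.5, tolerance = 1e-12)
  expect_equal(gp$shape, 2.40784780, tolerance = 1e-6)
  expect_equal(gp$scale, 1.86888889, tolerance = 1e-6)
  # reconstructed moments round-trip
  expect_equal(gp$shape * gp$scale, 4.5, tolerance = 1e-12)
  expect_equal(sqrt(gp$shape) * gp$scale, 2.9, tolerance = 1e-12)
  expect_equal(gamma_from_mean_sd(2, 2)$shape, 1, tolerance = 1e-12)
  expect_error(gamma_from_mean_sd(-1, 2), "mean > 0")
})

test_that("coefficient draws follow the model's Gaussian", {
  sim <- generate_panel(small_config(seed = 61))
  model <- suppressMessages(fit_che_model(sim$panel))

  # zero vcov: every draw equals the point estimate
  m0 <- model
  m0$beta_vcov[] <- 0
  draws0 <- sample_coefficients(m0, 50, seed = 1)
  expect_equal(unname(draws0), matrix(rep(model$beta, each = 50), 50, 4),
               tolerance = 1e-14)

  # seeded determinism
  expect_identical(sample_coefficients(model, 100, seed = 5),
                   sample_coefficients(model, 100, seed = 5))

  # CLT bound on the draw mean, and empirical covariance near the vcov
  n <- 1e5
  draws <- sample_coefficients(model, n, seed = 2)
  for (j in 1:4) {
    expect_lt(abs(mean(draws[, j]) - model$beta[j]),
              4 * model$beta_se[j] / sqrt(n))
  }
  expect_equal(stats::cov(draws), model$beta_vcov, tolerance = 0.05)

  # cross-check against an independent multivariate-normal sampler
  set.seed(3)
  ref <- MASS::mvrnorm(n, model$beta, model$beta_vcov)
  expect_equal(unname(colMeans(draws)), unname(colMeans(ref)), tolerance = 0.01)
  expect_equal(stats::cov(draws), stats::cov(ref), tolerance = 0.05)

  bad <- model
  bad$beta_vcov[1, 2] <- bad$beta_vcov[2, 1] <- 10
  expect_error(sample_coefficients(bad, 10, seed = 1), "semi-definite")
})

test_that("percentile UI uses linear interpolation between closest ranks", {
  expect_equal(percentile_ui(1:100), c(3.475, 97.525), tolerance = 1e-12)
  expect_equal(percentile_ui(rep(0.7, 10)), c(0.7, 0.7), tolerance = 1e-14)
  x <- stats::runif(500)
  expect_equal(percentile_ui(x), percentile_ui(sample(x)), tolerance = 1e-14)
  expect_error(percentile_ui(1), ">= 2")
})

test_that("target probabilities count strict threshold exceedances", {
  mc <- structure(list(
    n = 4L, seed = 1L,
    countries = data.frame(country_id = "A", income_group = cheproj:::as_income_group("LIC")),
    per_country = matrix(c(0.004, 0.006, 0.012, 0.020), 4, 1,
                         dimnames = list(NULL, "A")),
    per_group = matrix(c(0.004, 0.006, 0.012, 0.020), 4, 1,
                       dimnames = list(NULL, "LIC")),
    decline_per_group = NULL, baseline_per_group = NULL, horizon_years = 27
  ), class = "che_mc")
  rep1 <- target_probabilities(mc, thresholds = 0.01)
  expect_equal(rep1$probabilities$probability, 0.5)  # 2 of 4 strictly below
  rep2 <- target_probabilities(mc, thresholds = c(0.004, 0.03))
  # strict inequality: the 0.004 draw does not count at threshold 0.004
  expect_equal(rep2$probabilities$probability, c(0, 1))
  # nondecreasing in threshold
  rep3 <- target_probabilities(mc)
  expect_true(all(diff(rep3$probabilities$probability) >= 0))
})

test_that("gap-closing probability is a strict paired comparison", {
  expect_equal(gap_closing_probability(rep(0.02, 10), rep(0.01, 10)), 1)
  x <- stats::runif(100)
  expect_equal(gap_closing_probability(x, x), 0)  # ties do not count
  expect_error(gap_closing_probability(1:3, 1:4), "equal length")
  set.seed(9)
  n <- 1e5
  a <- stats::rnorm(n)
  b <- stats::rnorm(n)
  expect_lt(abs(gap_closing_probability(a, b) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("Monte Carlo groups are exact row-means and seeds are reproducible", {
  sim <- generate_panel(small_config(seed = 62))
  model <- suppressMessages(fit_che_model(sim$panel))
  fc <- generate_forecasts(sim$truth)
  growth <- summarize_growth(generate_gdp_projections(sim$truth))
  bl <- baseline_covariates(sim$panel)
  mc1 <- run_monte_carlo(model, fc, growth, n = 2000, seed = 7, baseline = bl)
  mc2 <- run_monte_carlo(model, fc, growth, n = 2000, seed = 7, baseline = bl)
  expect_identical(mc1$per_country, mc2$per_country)
  expect_identical(mc1$per_group, mc2$per_group)
  expect_identical(mc1$decline_per_group, mc2$decline_per_group)

  for (g in colnames(mc1$per_group)) {
    members <- mc1$countries$country_id[
      as.character(mc1$countries$income_group) == g]
    expect_identical(mc1$per_group[, g],
                     rowMeans(mc1$per_country[, members, drop = FALSE]))
  }
  expect_true(all(mc1$per_country > 0 & mc1$per_country < 1))

  mc3 <- run_monte_carlo(model, fc, growth, n = 2000, seed = 8, baseline = bl)
  expect_false(identical(mc1$per_group, mc3$per_group))
})

test_that("per-trial decline uses the same coefficient draw at both endpoints", {
  sim <- generate_panel(small_config(seed = 63, che_missingness = 0))
  model <- suppressMessages(fit_che_model(sim$panel))
  fc <- generate_forecasts(sim$truth)
  growth <- summarize_growth(generate_gdp_projections(sim$truth))
  bl <- baseline_covariates(sim$panel)
  mc <- run_monte_carlo(model, fc, growth, n = 500, seed = 3, baseline = bl)
  ny <- mc$horizon_years
  expect_equal(ny, 27)
  reconstructed <- 1 - (mc$per_group / mc$baseline_per_group)^(1 / ny)
  expect_equal(mc$decline_per_group, reconstructed, tolerance = 1e-14)

  # fixed-baseline alternative divides by the supplied constants
  fixed <- baseline_group_che(sim$panel, model, type = "fitted")
  mcf <- run_monte_carlo(model, fc, growth, n = 500, seed = 3,
                         decline_baseline = "fixed", fixed_baseline = fixed)
  manual <- 1 - sweep(mcf$per_group, 2, fixed[colnames(mcf$per_group)], `/`)^(1 / ny)
  expect_equal(mcf$decline_per_group, manual, tolerance = 1e-14)
})

test_that("group uncertainty intervals cover the generator's true group CHE", {
  hits <- 0L
  total <- 0L
  for (k in 1:100) {
    cfg <- generator_config(
      n_countries_per_group = c(LIC = 5, LMIC = 5, UMIC = 5, HIC = 5),
      years = 2006:2013, seed = 3000L + k)
    sim <- generate_panel(cfg)
    model <- suppressWarnings(suppressMessages(fit_che_model(sim$panel)))
    fc <- generate_forecasts(sim$truth)
    growth <- summarize_growth(generate_gdp_projections(sim$truth))
    mc <- run_monte_carlo(model, fc, growth, n = 1000, seed = 4000L + k,
                          use_blup = TRUE)
    truth_group <- tapply(sim$truth$countries$che_true,
                          as.character(sim$truth$countries$income_group), mean)
    for (g in colnames(mc$per_group)) {
      ui <- percentile_ui(mc$per_group[, g])
      hits <- hits + (ui[1] <= truth_group[[g]] && truth_group[[g]] <= ui[2])
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.85)
})
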
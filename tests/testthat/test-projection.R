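make_growth_input <- function(rates, groups, years = 2015:2021) {
  rows <- lapply(seq_along(rates), function(i) {
    data.frame(country_id = sprintf("C%02d", i), income_group = groups[i],
               year = years, gdp_c = 1000 * (1 + rates[i])^(years - years[1]))
  })
  gdp_projections(do.call(rbind, rows))
}

test_that("growth summary gives the per-group mean and sample SD of rates", {
  gp <- make_growth_input(c(0.045, 0.045, 0.03, 0.05), c("LIC", "LIC", "LMIC", "LMIC"))
  expect_warning(gr <- summarize_growth(gp), "UMIC, HIC")
  lic <- gr[gr$income_group == "LIC", ]
  expect_equal(lic$mean_rate, 0.045, tolerance = 1e-10)
  expect_equal(lic$sd_rate, 0, tolerance = 1e-10)
  lmic <- gr[gr$income_group == "LMIC", ]
  expect_equal(lmic$mean_rate, 0.04, tolerance = 1e-10)
  expect_equal(lmic$sd_rate, stats::sd(c(0.03, 0.05)), tolerance = 1e-10)
  expect_equal(lmic$sd_rate, 0.0141421356, tolerance = 1e-6)
  # absent groups are omitted from the output map
  expect_false("UMIC" %in% as.character(gr$income_group))
})

test_that("GDP is projected with the group rate over the horizon", {
  growth <- manual_growth()
  fc <- list(income_group = "LIC", gdp_c_base = 1000,
             base_year = 2013, horizon_year = 2040)
  expect_equal(project_gdp_2040(fc, growth), 1000 * 1.045^27, tolerance = 1e-10)
  fc0 <- list(income_group = "HIC", gdp_c_base = 1000,
              base_year = 2013, horizon_year = 2013 + 27)
  growth0 <- manual_growth(mean_rate = rep(0, 4), sd_rate = rep(0, 4))
  expect_equal(project_gdp_2040(fc0, growth0), 1000, tolerance = 1e-14)
})

test_that("two same-group countries with equal base GDP get equal projected GDP", {
  sim <- generate_panel(small_config(seed = 51))
  fc <- generate_forecasts(sim$truth)
  growth <- manual_growth()
  lic <- fc[as.character(fc$income_group) == "LIC", ][1:2, ]
  lic$gdp_c_base <- 900
  expect_equal(project_gdp_2040(lic[1, ], growth),
               project_gdp_2040(lic[2, ], growth), tolerance = 1e-14)
})

test_that("group aggregation is exactly the unweighted arithmetic mean", {
  sim <- generate_panel(small_config(seed = 52))
  model <- suppressMessages(fit_che_model(sim$panel))
  fc <- generate_forecasts(sim$truth)
  growth <- summarize_growth(generate_gdp_projections(sim$truth))
  proj <- project_group_che(model, fc, growth)
  for (g in as.character(proj$group$income_group)) {
    members <- proj$country$che_2040[as.character(proj$country$income_group) == g]
    expect_identical(proj$group$che_point[as.character(proj$group$income_group) == g],
                     mean(members))
  }
  # single-country group equals that country's prediction
  one <- fc[c(which(as.character(fc$income_group) == "LIC")[1],
              which(as.character(fc$income_group) == "UMIC")), ]
  proj1 <- project_group_che(model, forecast_set(one), growth)
  expect_identical(proj1$group$che_point[1],
                   proj1$country$che_2040[proj1$country$income_group == "LIC"])
})

test_that("projection is invariant to country order and fully deterministic", {
  sim <- generate_panel(small_config(seed = 53))
  model <- suppressMessages(fit_che_model(sim$panel))
  fc <- generate_forecasts(sim$truth)
  growth <- summarize_growth(generate_gdp_projections(sim$truth))
  proj1 <- project_group_che(model, fc, growth)
  shuffled <- forecast_set(fc[rev(seq_len(nrow(fc))), ])
  proj2 <- project_group_che(model, shuffled, growth)
  expect_identical(proj1$country, proj2$country)
  expect_identical(proj1$group, proj2$group)
})

test_that("raising every oop forecast raises every group mean (beta1 > 0)", {
  sim <- generate_panel(small_config(seed = 54))
  model <- suppressMessages(fit_che_model(sim$panel))
  expect_gt(model$beta[["beta1"]], 0)
  fc <- generate_forecasts(sim$truth)
  growth <- summarize_growth(generate_gdp_projections(sim$truth))
  base <- project_group_che(model, fc, growth)
  up <- fc
  for (col in c("oop_exp_mean", "oop_exp_lo", "oop_exp_hi")) {
    up[[col]] <- inv_logit(logit(up[[col]]) + 0.3)
  }
  raised <- project_group_che(model, forecast_set(up), growth)
  expect_true(all(raised$group$che_point > base$group$che_point))
})

test_that("countries without a growth summary are excluded with a warning", {
  sim <- generate_panel(small_config(seed = 55))
  model <- suppressMessages(fit_che_model(sim$panel))
  fc <- generate_forecasts(sim$truth)
  growth <- summarize_growth(generate_gdp_projections(sim$truth))
  growth_no_hic <- growth[as.character(growth$income_group) != "HIC", ]
  class(growth_no_hic) <- c("che_growth", "data.frame")
  expect_warning(proj <- project_group_che(model, fc, growth_no_hic), "HIC")
  expect_false("HIC" %in% as.character(proj$group$income_group))
})

test_that("decline between group levels matches its closed form and inverse", {
  expect_equal(compute_decline(0.02, 0.02), 0, tolerance = 1e-14)
  r <- compute_decline(0.0183, 0.0115, 27)
  expect_equal(cumulative_decline(r, 27), 1 - 0.0115 / 0.0183, tolerance = 1e-12)
  # a 1.7%/yr decline removes ~37% over 27 years
  expect_equal(round(100 * cumulative_decline(0.017, 27)), 37)
})

test_that("fitted and observed baselines are both available per group", {
  cfg <- small_config(seed = 56, che_missingness = 0)
  sim <- generate_panel(cfg)
  model <- suppressMessages(fit_che_model(sim$panel))
  fitted_bl <- baseline_group_che(sim$panel, model, type = "fitted")
  observed_bl <- baseline_group_che(sim$panel, type = "observed")
  expect_named(fitted_bl, income_groups())
  expect_named(observed_bl, income_groups())
  expect_true(all(fitted_bl > 0 & fitted_bl < 1))
  # on generator output the two baselines agree to within the residual noise
  expect_equal(unname(fitted_bl), unname(observed_bl), tolerance = 0.5)
})
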
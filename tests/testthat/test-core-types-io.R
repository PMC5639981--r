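make_panel_df <- function() {
  data.frame(
    country_id = c("ETH", "ETH", "KEN"),
    income_group = c("LIC", "LIC", "LMIC"),
    year = c(2004L, 2005L, 2004L),
    che = c(0.021, 0.0193, 0.015),
    oop_exp = c(0.45, 0.44, 0.38),
    hex_gdp = c(0.05, 0.052, 0.06),
    gdp_c = c(650, 700, 1200)
  )
}

test_that("panel CSV round trip preserves every field", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_panel_df()
  write_country_panel(country_panel(df), path)
  panel <- read_country_panel(path)
  expect_s3_class(panel, "che_panel")
  expect_equal(nrow(panel), 3)
  expect_equal(panel$che, df$che, tolerance = 1e-12)
  expect_equal(panel$gdp_c, df$gdp_c, tolerance = 1e-12)
  expect_identical(as.character(panel$income_group), df$income_group)
})

test_that("percent-scale input is converted by the declared flag only", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_panel_df()
  df[c("che", "oop_exp", "hex_gdp")] <- df[c("che", "oop_exp", "hex_gdp")] * 100
  utils::write.csv(df, path, row.names = FALSE)
  panel <- read_country_panel(path, percent_input = TRUE)
  expect_equal(panel$che[panel$country_id == "KEN"], 0.015, tolerance = 1e-12)
  # without the flag the same file is rejected, never magnitude-guessed
  expect_error(read_country_panel(path), "outside")
})

test_that("boundary proportions are clipped with a warning, interior untouched", {
  df <- make_panel_df()
  df$che[1] <- 0
  expect_warning(panel <- country_panel(df, clip_epsilon = 1e-6), "clipped")
  expect_equal(panel$che[panel$country_id == "ETH" & panel$year == 2004], 1e-6)
  # values already inside (eps, 1 - eps) are never changed
  expect_equal(panel$che[panel$country_id == "KEN"], 0.015, tolerance = 1e-15)
})

test_that("duplicate (country, year) pairs are rejected naming the offenders", {
  df <- make_panel_df()
  df$year[2] <- 2004L
  expect_error(country_panel(df), "ETH, 2004")
  df2 <- make_panel_df()
  df2$gdp_c[3] <- -5
  expect_error(country_panel(df2), "gdp_c")
  expect_error(country_panel(df2[, -1]), "missing column")
})

make_forecast_df <- function() {
  data.frame(
    country_id = c("ETH", "KEN"), income_group = c("LIC", "LMIC"),
    oop_exp_mean = c(0.30, 0.25), oop_exp_lo = c(0.25, 0.20),
    oop_exp_hi = c(0.36, 0.31),
    hex_gdp_mean = c(0.05, 0.06), hex_gdp_lo = c(0.04, 0.05),
    hex_gdp_hi = c(0.065, 0.075),
    gdp_c_base = c(650, 1200), base_year = 2013L, horizon_year = 2040L
  )
}

test_that("forecast interval ordering is enforced; point intervals accepted", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_forecast_df()
  utils::write.csv(df, path, row.names = FALSE)
  fs <- read_forecasts(path)
  expect_s3_class(fs, "che_forecasts")

  bad <- df
  bad$oop_exp_lo[1] <- 0.32  # lo > mean
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_forecasts(path), "ordering")

  degen <- df
  degen[1, c("oop_exp_lo", "oop_exp_hi")] <- degen$oop_exp_mean[1]
  utils::write.csv(degen, path, row.names = FALSE)
  fs2 <- read_forecasts(path)
  expect_equal(fs2$oop_exp_lo[fs2$country_id == "ETH"],
               fs2$oop_exp_hi[fs2$country_id == "ETH"])

  panel <- country_panel(make_panel_df())
  extra <- rbind(df, within(df[1, ], country_id <- "ZZZ"))
  utils::write.csv(extra, path, row.names = FALSE)
  expect_warning(fs3 <- read_forecasts(path, panel = panel), "ZZZ")
  expect_true("ZZZ" %in% fs3$country_id)  # retained despite the warning
})

test_that("GDP projection reader validates per-country series", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(country_id = rep(c("ETH", "KEN"), each = 3),
                   income_group = rep(c("LIC", "LMIC"), each = 3),
                   year = rep(2015:2017, 2),
                   gdp_c = c(650, 660, 690, 1200, 1210, 1230))
  utils::write.csv(df, path, row.names = FALSE)
  gp <- read_gdp_projections(path)
  expect_s3_class(gp, "che_gdp_proj")
  expect_error(gdp_projections(df[c(1, 4, 5), ]), "ETH")
})

test_that("target report round-trips through CSV at high precision", {
  sim <- generate_panel(small_config(seed = 3))
  model <- suppressMessages(fit_che_model(sim$panel))
  fc <- generate_forecasts(sim$truth)
  gr <- summarize_growth(generate_gdp_projections(sim$truth))
  mc <- run_monte_carlo(model, fc, gr, n = 400, seed = 5,
                        baseline = baseline_covariates(sim$panel))
  report <- target_probabilities(mc)
  expect_equal(nrow(report$probabilities), 3 * 4)  # 3 non-HIC groups x 4 thresholds

  path <- withr::local_tempfile(fileext = ".csv")
  write_target_report(report, path)
  back <- read_target_report(path)
  expect_equal(back$probabilities$probability,
               report$probabilities$probability, tolerance = 1e-12)
  expect_equal(back$groups$che_point, report$groups$che_point,
               tolerance = 1e-12)
  expect_equal(back$groups$gap_probability, report$groups$gap_probability,
               tolerance = 1e-12)
})

test_that("an empty report writes a header-only CSV", {
  empty <- structure(list(
    probabilities = data.frame(income_group = character(),
                               threshold = numeric(), probability = numeric()),
    groups = data.frame(income_group = character(), che_point = numeric(),
                        che_lo = numeric(), che_hi = numeric()),
    thresholds = numeric()), class = "che_target_report")
  path <- withr::local_tempfile(fileext = ".csv")
  write_target_report(empty, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "income_group,threshold,probability")
})
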
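#' Configuration for the synthetic country-panel generator
#'
#' Defines the ground-truth data-generating process: the logit-linear CHE
#' model with country random intercepts, per-group covariate distributions,
#' and per-group GDP growth. Defaults mirror the study conditions the
#' projection pipeline is designed for: 179 countries in the four World
#' Bank income groups (32/45/51/51), observation years 1995-2013, slope
#' coefficients 0.67 (logit OOP_EXP), 0.67 (logit HEX_GDP) and -0.38
#' (ln GDP per capita), country random-intercept variance 0.29, and annual
#' GDP growth of 4.5% (SD 2.9%), 4.5% (2.7%), 4.1% (2.4%) and 3.4% (2.0%)
#' for LIC, LMIC, UMIC and HIC respectively.
#'
#' Covariate distributions are per-group: beta for the two shares, log-
#' normal for GDP per capita. Their defaults are documented constants
#' chosen so that low-income panels carry higher out-of-pocket shares and
#' lower GDP than high-income panels; they are qualitative stand-ins, not
#' estimates of any real dataset.
#'
#' @param n_countries_per_group Named integer vector over LIC/LMIC/UMIC/HIC.
#' @param years Integer vector of observation years.
#' @param true_beta Length-4 vector `(beta0, beta1, beta2, beta3)`:
#'   intercept and slopes on logit(oop_exp), logit(hex_gdp), ln(gdp_c).
#' @param random_effect_sd SD of the country random intercept (>= 0).
#' @param residual_sd SD of the residual on the logit scale (>= 0).
#' @param covariate_distributions Per-group list with elements `oop_exp`
#'   and `hex_gdp` (each `c(shape1, shape2)` beta parameters) and `gdp_c`
#'   (`c(meanlog, sdlog)`).
#' @param gdp_growth Per-group list of `c(mean, sd)` annual growth rates.
#' @param che_missingness Fraction of country-years with CHE unobserved,
#'   in `[0, 1)`.
#' @param ar1_rho Optional AR(1) correlation of covariates across years
#'   within a country (on the transformed scale); 0 = independent draws.
#' @param horizon_year Year the ground-truth CHE is evaluated at.
#' @param seed Integer RNG seed; identical seeds give identical panels.
#' @return A `che_generator_config` list.
#' @export
generator_config <- function(
    n_countries_per_group = c(LIC = 32, LMIC = 45, UMIC = 51, HIC = 51),
    years = 1995:2013,
    true_beta = c(beta0 = 0, beta1 = 0.67, beta2 = 0.67, beta3 = -0.38),
    random_effect_sd = sqrt(0.29),
    residual_sd = 0.5,
    covariate_distributions = default_covariate_distributions(),
    gdp_growth = default_gdp_growth(),
    che_missingness = 0.3,
    ar1_rho = 0,
    horizon_year = 2040,
    seed = 1L) {
  stopifnot(length(true_beta) == 4, length(years) >= 1)
  if (random_effect_sd < 0 || residual_sd < 0) {
    stop("random_effect_sd and residual_sd must be >= 0", call. = FALSE)
  }
  if (che_missingness < 0 || che_missingness >= 1) {
    stop("che_missingness must be in [0, 1)", call. = FALSE)
  }
  if (abs(ar1_rho) >= 1) stop("ar1_rho must be in (-1, 1)", call. = FALSE)
  n_countries_per_group <- n_countries_per_group[income_groups()]
  names(n_countries_per_group) <- income_groups()
  n_countries_per_group[is.na(n_countries_per_group)] <- 0
  if (any(n_countries_per_group < 0)) stop("group counts must be >= 0", call. = FALSE)
  for (g in income_groups()) {
    cd <- covariate_distributions[[g]]
    if (is.null(cd)) stop("covariate_distributions missing group ", g, call. = FALSE)
    if (any(cd$oop_exp <= 0) || any(cd$hex_gdp <= 0)) {
      stop("beta shape parameters must be positive (group ", g, ")", call. = FALSE)
    }
    if (cd$gdp_c[2] < 0) stop("gdp_c sdlog must be >= 0 (group ", g, ")", call. = FALSE)
    gg <- gdp_growth[[g]]
    if (is.null(gg) || length(gg) != 2 || gg[2] < 0 || gg[1] <= -1) {
      stop("gdp_growth for group ", g, " must be c(mean > -1, sd >= 0)", call. = FALSE)
    }
  }
  names(true_beta) <- c("beta0", "beta1", "beta2", "beta3")
  structure(list(
    n_countries_per_group = n_countries_per_group,
    years = as.integer(years),
    true_beta = true_beta,
    random_effect_sd = random_effect_sd,
    residual_sd = residual_sd,
    covariate_distributions = covariate_distributions,
    gdp_growth = gdp_growth,
    che_missingness = che_missingness,
    ar1_rho = ar1_rho,
    horizon_year = as.integer(horizon_year),
    seed = as.integer(seed)
  ), class = "che_generator_config")
}

#' @rdname generator_config
#' @export
default_covariate_distributions <- function() {
  # beta shapes as mean * kappa, (1 - mean) * kappa; lognormal (meanlog, sdlog)
  list(
    LIC  = list(oop_exp = c(9.0, 11.0),  hex_gdp = c(5.5, 94.5),
                gdp_c = c(log(800), 0.5)),
    LMIC = list(oop_exp = c(8.0, 12.0),  hex_gdp = c(5.5, 94.5),
                gdp_c = c(log(2500), 0.5)),
    UMIC = list(oop_exp = c(6.0, 14.0),  hex_gdp = c(6.0, 94.0),
                gdp_c = c(log(8000), 0.5)),
    HIC  = list(oop_exp = c(3.6, 16.4),  hex_gdp = c(9.0, 91.0),
                gdp_c = c(log(35000), 0.4))
  )
}

#' @rdname generator_config
#' @export
default_gdp_growth <- function() {
  list(LIC = c(0.045, 0.029), LMIC = c(0.045, 0.027),
       UMIC = c(0.041, 0.024), HIC = c(0.034, 0.020))
}

# AR(1) series on the transformed scale; rho = 0 reduces to i.i.d. draws.
# Innovations come from the target marginal by probability-integral
# transform of a latent standard-normal AR(1), so the marginal is preserved.
draw_covariate_series <- function(n, rho, qfun) {
  z <- stats::rnorm(n)
  if (rho != 0 && n > 1) {
    for (t in 2:n) z[t] <- rho * z[t - 1] + sqrt(1 - rho^2) * z[t]
  }
  qfun(stats::pnorm(z))
}

# One truncated-normal growth draw (> -0.99 so GDP stays positive).
draw_growth <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    g <- stats::rnorm(1, mean, sd)
    if (g > -0.99) return(g)
  }
}

#' Generate a synthetic country panel with known ground truth
#'
#' Simulates the exact forward model the fitting stage assumes: one random
#' intercept per country, covariates drawn from the configured per-group
#' distributions, and
#' `logit(CHE) = b0 + b1 logit(OOP_EXP) + b2 logit(HEX_GDP) + b3 ln(GDP_C)
#' + b_country + eps`. A fraction of country-years has CHE set missing.
#'
#' The returned ground truth carries, per country, the realised random
#' effect, the base-year (last panel year) GDP per capita, the true
#' horizon-year covariates (a fresh draw from the same distributions plus a
#' truncated-normal growth rate compounded from the base year), and the
#' true horizon-year CHE under the noiseless model (random effect included,
#' residual excluded).
#'
#' @param config A [generator_config()].
#' @return List with elements `panel` (a `che_panel`) and `truth` (a
#'   `che_ground_truth`: the config, plus a per-country data frame
#'   `countries`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "che_generator_config"))
  with_seed(config$seed, {
    beta <- config$true_beta
    years <- config$years
    base_year <- max(years)
    n_years <- length(years)
    rows <- list()
    truth_rows <- list()
    for (g in income_groups()) {
      n_g <- config$n_countries_per_group[[g]]
      if (n_g == 0) next
      cd <- config$covariate_distributions[[g]]
      gg <- config$gdp_growth[[g]]
      for (i in seq_len(n_g)) {
        cid <- sprintf("%s%03d", g, i)
        b_country <- stats::rnorm(1, 0, config$random_effect_sd)
        oop <- draw_covariate_series(n_years, config$ar1_rho,
                                     function(p) stats::qbeta(p, cd$oop_exp[1], cd$oop_exp[2]))
        hex <- draw_covariate_series(n_years, config$ar1_rho,
                                     function(p) stats::qbeta(p, cd$hex_gdp[1], cd$hex_gdp[2]))
        gdp <- draw_covariate_series(n_years, config$ar1_rho,
                                     function(p) stats::qlnorm(p, cd$gdp_c[1], cd$gdp_c[2]))
        eps <- if (config$residual_sd > 0) stats::rnorm(n_years, 0, config$residual_sd) else rep(0, n_years)
        che <- stats::plogis(beta[1] + beta[2] * stats::qlogis(oop) +
                               beta[3] * stats::qlogis(hex) +
                               beta[4] * log(gdp) + b_country + eps)
        if (config$che_missingness > 0) {
          che[stats::runif(n_years) < config$che_missingness] <- NA_real_
        }
        rows[[cid]] <- data.frame(country_id = cid, income_group = g,
                                  year = years, che = che, oop_exp = oop,
                                  hex_gdp = hex, gdp_c = gdp)
        # ground truth at the horizon year
        gdp_base <- gdp[n_years]
        oop_h <- stats::rbeta(1, cd$oop_exp[1], cd$oop_exp[2])
        hex_h <- stats::rbeta(1, cd$hex_gdp[1], cd$hex_gdp[2])
        g_true <- draw_growth(gg[1], gg[2])
        gdp_h <- gdp_base * (1 + g_true)^(config$horizon_year - base_year)
        che_h <- stats::plogis(beta[1] + beta[2] * stats::qlogis(oop_h) +
                                 beta[3] * stats::qlogis(hex_h) +
                                 beta[4] * log(gdp_h) + b_country)
        truth_rows[[cid]] <- data.frame(
          country_id = cid, income_group = g, random_effect = b_country,
          gdp_c_base = gdp_base, growth_true = g_true,
          oop_exp_true = oop_h, hex_gdp_true = hex_h,
          gdp_c_true = gdp_h, che_true = che_h)
      }
    }
    panel <- country_panel(do.call(rbind, rows),
                           provenance = sprintf("synthetic (seed %d)", config$seed))
    countries <- do.call(rbind, truth_rows)
    countries$income_group <- as_income_group(countries$income_group)
    rownames(countries) <- NULL
    truth <- structure(list(config = config, countries = countries,
                            base_year = base_year,
                            horizon_year = config$horizon_year),
                       class = "che_ground_truth")
    list(panel = panel, truth = truth)
  })
}

#' Generate horizon-year covariate forecasts around the ground truth
#'
#' Emulates external covariate forecasts: per country, the reported mean is
#' the true horizon-year value perturbed on the logit scale by
#' `Normal(0, noise_sd)`, and the 95% interval is symmetric on the logit
#' scale with half-width `1.96 * noise_sd * ui_width_factor`. With the
#' default `ui_width_factor = 1` the interval width therefore matches the
#' noise actually injected into the mean, so intervals are calibrated;
#' `ui_width_factor = 0` yields point forecasts.
#'
#' @param truth A `che_ground_truth` from [generate_panel()].
#' @param ui_width_factor Non-negative scale factor on the logit-scale
#'   interval half-width.
#' @param noise_sd Logit-scale SD of the forecast-mean perturbation.
#' @param seed RNG seed; defaults to the generator seed + 1.
#' @return A `che_forecasts` data frame.
#' @export
generate_forecasts <- function(truth, ui_width_factor = 1, noise_sd = 0.15,
                               seed = truth$config$seed + 1L) {
  stopifnot(inherits(truth, "che_ground_truth"), ui_width_factor >= 0,
            noise_sd >= 0)
  with_seed(seed, {
    ct <- truth$countries
    half <- 1.96 * noise_sd * ui_width_factor
    mk <- function(true_vals) {
      m_logit <- stats::qlogis(true_vals) + stats::rnorm(nrow(ct), 0, noise_sd)
      list(mean = stats::plogis(m_logit),
           lo = stats::plogis(m_logit - half),
           hi = stats::plogis(m_logit + half))
    }
    oop <- mk(ct$oop_exp_true)
    hex <- mk(ct$hex_gdp_true)
    forecast_set(data.frame(
      country_id = ct$country_id, income_group = as.character(ct$income_group),
      oop_exp_mean = oop$mean, oop_exp_lo = oop$lo, oop_exp_hi = oop$hi,
      hex_gdp_mean = hex$mean, hex_gdp_lo = hex$lo, hex_gdp_hi = hex$hi,
      gdp_c_base = ct$gdp_c_base, base_year = truth$base_year,
      horizon_year = truth$horizon_year))
  })
}

#' Generate GDP-per-capita projection runs
#'
#' Emulates a short run of GDP projections (e.g. 2015-2021): per country a
#' constant growth rate is drawn from the group's `Normal(mean, sd)`
#' (truncated above -100%) and compounded from the base-year GDP, so
#' [annualized_rate()] applied to any generated series recovers the drawn
#' rate exactly.
#'
#' @param truth A `che_ground_truth` from [generate_panel()].
#' @param years Integer years of the projection run.
#' @param seed RNG seed; defaults to the generator seed + 2.
#' @return A `che_gdp_proj` data frame.
#' @export
generate_gdp_projections <- function(truth, years = 2015:2021,
                                     seed = truth$config$seed + 2L) {
  stopifnot(inherits(truth, "che_ground_truth"), length(years) >= 2)
  years <- as.integer(years)
  with_seed(seed, {
    ct <- truth$countries
    rows <- lapply(seq_len(nrow(ct)), function(i) {
      gg <- truth$config$gdp_growth[[as.character(ct$income_group[i])]]
      g <- draw_growth(gg[1], gg[2])
      data.frame(country_id = ct$country_id[i],
                 income_group = as.character(ct$income_group[i]),
                 year = years,
                 gdp_c = ct$gdp_c_base[i] * (1 + g)^(years - truth$base_year))
    })
    gdp_projections(do.call(rbind, rows))
  })
}
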
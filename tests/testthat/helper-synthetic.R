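# Shared small generator configurations for fast tests.

small_config <- function(seed = 1L, ...) {
  generator_config(
    n_countries_per_group = c(LIC = 8, LMIC = 10, UMIC = 10, HIC = 10),
    years = 2006:2013,
    seed = seed,
    ...
  )
}

# A hand-built model object with chosen coefficients and no estimation
# uncertainty, for tests that need exact control over the linear predictor.
manual_model <- function(beta = c(0, 0.67, 0.67, -0.38),
                         vcov_mat = matrix(0, 4, 4),
                         re_var = 0, resid_var = 0,
                         country_effects = numeric(0)) {
  nm <- c("beta0", "beta1", "beta2", "beta3")
  dimnames(vcov_mat) <- list(nm, nm)
  structure(list(
    beta = stats::setNames(beta, nm),
    beta_se = stats::setNames(sqrt(diag(vcov_mat)), nm),
    beta_vcov = vcov_mat,
    p_values = stats::setNames(rep(NA_real_, 4), nm),
    random_effect_variance = re_var,
    residual_variance = resid_var,
    country_effects = country_effects,
    r_squared = NA_real_,
    n_obs = 0L, n_countries = 0L, method = "REML"
  ), class = "che_model")
}

manual_growth <- function(groups = income_groups(),
                          mean_rate = c(0.045, 0.045, 0.041, 0.034),
                          sd_rate = c(0.029, 0.027, 0.024, 0.020)) {
  out <- data.frame(income_group = cheproj:::as_income_group(groups),
                    mean_rate = mean_rate, sd_rate = sd_rate,
                    n_countries = 10L)
  structure(out, class = c("che_growth", "data.frame"))
}
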
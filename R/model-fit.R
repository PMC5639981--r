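#' Fit the mixed-effects logit-linear CHE model
#'
#' Estimates the panel model
#' `logit(CHE) = b0 + b1 logit(OOP_EXP) + b2 logit(HEX_GDP) + b3 ln(GDP_C)
#' + b_country + eps`, where `b_country` is a country random intercept
#' capturing between-country heterogeneity and `eps` is the residual. The
#' outcome is transformed to the logit scale and the model fitted as a
#' linear mixed model (via \pkg{lme4}); REML is the default estimator, ML
#' is available for likelihood comparisons. Rows with missing CHE are
#' dropped from fitting with a message (their countries can still be
#' projected later).
#'
#' Coefficient p-values use the two-sided normal approximation on
#' estimate/SE. A near-zero random-effect variance (singular fit) degrades
#' the model to an effectively fixed-effects fit and raises a warning.
#'
#' @param panel A `che_panel` with at least 2 countries carrying
#'   non-missing CHE.
#' @param method `"REML"` (default) or `"ML"`.
#' @return A `che_model`: list with `beta` (named length-4 vector),
#'   `beta_se`, `beta_vcov` (4x4), `p_values`, `random_effect_variance`,
#'   `residual_variance`, `country_effects` (named BLUP vector),
#'   `r_squared` (marginal), `n_obs`, `n_countries`, `method`.
#' @export
fit_che_model <- function(panel, method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "che_panel"))
  fit_df <- panel[!is.na(panel$che), , drop = FALSE]
  n_dropped <- nrow(panel) - nrow(fit_df)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " row(s) with missing CHE from fitting")
  }
  if (length(unique(fit_df$country_id)) < 2) {
    stop("mixed-model fitting needs >= 2 countries with observed CHE",
         call. = FALSE)
  }
  dat <- data.frame(
    y = logit(fit_df$che),
    x1 = logit(fit_df$oop_exp),
    x2 = logit(fit_df$hex_gdp),
    x3 = log(fit_df$gdp_c),
    country_id = fit_df$country_id
  )
  fit <- lme4::lmer(y ~ x1 + x2 + x3 + (1 | country_id), data = dat,
                    REML = (method == "REML"),
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  conv_msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(conv_msgs) && any(grepl("failed to converge", conv_msgs))) {
    stop("mixed-model optimizer failed to converge: ",
         paste(conv_msgs, collapse = "; "), call. = FALSE)
  }
  beta <- lme4::fixef(fit)
  names(beta) <- c("beta0", "beta1", "beta2", "beta3")
  vcov_mat <- as.matrix(stats::vcov(fit))
  dimnames(vcov_mat) <- list(names(beta), names(beta))
  se <- sqrt(diag(vcov_mat))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_var <- vc$vcov[vc$grp == "country_id"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  if (re_var < 1e-8) {
    warning("random-effect variance is ~0 (singular fit); ",
            "model degrades to a fixed-effects fit", call. = FALSE)
  }
  blups_df <- lme4::ranef(fit)$country_id
  country_effects <- stats::setNames(blups_df[["(Intercept)"]],
                                     rownames(blups_df))
  model <- structure(list(
    beta = beta,
    beta_se = stats::setNames(se, names(beta)),
    beta_vcov = vcov_mat,
    p_values = stats::setNames(2 * stats::pnorm(-abs(beta / se)), names(beta)),
    random_effect_variance = re_var,
    residual_variance = resid_var,
    country_effects = country_effects,
    n_obs = nrow(dat),
    n_countries = length(unique(dat$country_id)),
    method = method
  ), class = "che_model")
  model$r_squared <- compute_r_squared(model, panel, "marginal")
  model
}

#' @export
print.che_model <- function(x, ...) {
  cat("Mixed-effects logit CHE model (", x$method, "), ",
      x$n_obs, " obs / ", x$n_countries, " countries\n", sep = "")
  tab <- data.frame(estimate = x$beta, se = x$beta_se,
                    p = signif(x$p_values, 3))
  rownames(tab) <- c("(Intercept)", "logit(OOP_EXP)", "logit(HEX_GDP)",
                     "ln(GDP_C)")
  print(tab, digits = 3)
  cat("Random-effect variance:", signif(x$random_effect_variance, 3),
      " Residual variance:", signif(x$residual_variance, 3), "\n")
  cat("Marginal R-squared:", signif(x$r_squared, 3), "\n")
  invisible(x)
}

#' Predict CHE incidence from covariates
#'
#' Inverse-logit of the linear predictor
#' `b0 + b1 logit(oop_exp) + b2 logit(hex_gdp) + b3 ln(gdp_c) +
#' country_effect`. Vectorised over covariates.
#'
#' @param model A `che_model`.
#' @param oop_exp,hex_gdp Proportions in (0, 1).
#' @param gdp_c Positive GDP per capita.
#' @param country_effect Country random intercept to apply (default 0,
#'   i.e. a population-level prediction).
#' @return Predicted CHE incidence, always in (0, 1).
#' @export
predict_che <- function(model, oop_exp, hex_gdp, gdp_c, country_effect = 0) {
  stopifnot(inherits(model, "che_model"))
  if (any(gdp_c <= 0)) stop("gdp_c must be positive", call. = FALSE)
  b <- model$beta
  stats::plogis(b[[1]] + b[[2]] * logit(oop_exp) + b[[3]] * logit(hex_gdp) +
                  b[[4]] * log(gdp_c) + country_effect)
}

#' Coefficient of determination for a fitted CHE model
#'
#' Variance-decomposition R-squared for mixed models: the marginal version
#' is `var(fixed predictions) / (var(fixed) + random-effect variance +
#' residual variance)`; the conditional version credits the random effects
#' to the numerator as well, so it is never smaller than the marginal one.
#'
#' @param model A `che_model`.
#' @param panel The `che_panel` the model was fitted on (rows with missing
#'   CHE are ignored).
#' @param definition `"marginal"` (default) or `"conditional"`.
#' @return R-squared in `[0, 1]`.
#' @export
compute_r_squared <- function(model, panel,
                              definition = c("marginal", "conditional")) {
  definition <- match.arg(definition)
  stopifnot(inherits(model, "che_model"), inherits(panel, "che_panel"))
  fit_df <- panel[!is.na(panel$che), , drop = FALSE]
  if (!all(names(model$country_effects) %in% fit_df$country_id)) {
    stop("panel does not contain the countries the model was fitted on",
         call. = FALSE)
  }
  b <- model$beta
  eta <- b[[1]] + b[[2]] * logit(fit_df$oop_exp) +
    b[[3]] * logit(fit_df$hex_gdp) + b[[4]] * log(fit_df$gdp_c)
  var_f <- stats::var(eta)
  denom <- var_f + model$random_effect_variance + model$residual_variance
  num <- if (definition == "conditional") var_f + model$random_effect_variance else var_f
  max(0, min(1, num / denom))
}

#' Serialise / restore a fitted CHE model as JSON
#'
#' Stores coefficients, their variance-covariance matrix, variance
#' components, BLUPs and fit metadata so the uncertainty engine can run
#' without refitting, and for audit.
#'
#' @param model A `che_model`.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `che_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "che_model"))
  payload <- list(
    beta = as.list(model$beta),
    beta_se = as.list(model$beta_se),
    beta_vcov = model$beta_vcov,
    p_values = as.list(model$p_values),
    random_effect_variance = model$random_effect_variance,
    residual_variance = model$residual_variance,
    country_effects = as.list(model$country_effects),
    r_squared = model$r_squared,
    n_obs = model$n_obs,
    n_countries = model$n_countries,
    method = model$method
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vcov_mat <- matrix(unlist(p$beta_vcov), 4, 4)
  nm <- c("beta0", "beta1", "beta2", "beta3")
  dimnames(vcov_mat) <- list(nm, nm)
  structure(list(
    beta = stats::setNames(unlist(p$beta), nm),
    beta_se = stats::setNames(unlist(p$beta_se), nm),
    beta_vcov = vcov_mat,
    p_values = stats::setNames(unlist(p$p_values), nm),
    random_effect_variance = p$random_effect_variance,
    residual_variance = p$residual_variance,
    country_effects = unlist(p$country_effects),
    r_squared = p$r_squared,
    n_obs = p$n_obs,
    n_countries = p$n_countries,
    method = p$method
  ), class = "che_model")
}
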
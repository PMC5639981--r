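#' Fit a beta distribution to a mean and 95% uncertainty interval
#'
#' Finds beta parameters whose mean equals the stated mean (enforced
#' exactly via the parameterisation `alpha = mean * kappa`,
#' `beta = (1 - mean) * kappa`) and whose 2.5th and 97.5th quantiles match
#' the stated interval bounds in the least-squares sense. The
#' concentration `kappa` is found by 1-D numerical optimisation,
#' initialised from the moment estimate with `sd0 = (hi - lo) / 3.92`.
#'
#' A zero-width interval (`lo == mean == hi`) returns a flagged point-mass
#' surrogate: sampling from it returns the mean.
#'
#' @param mean,lo,hi Proportions with `0 < lo <= mean <= hi < 1`.
#' @param tolerance Convergence tolerance on the quantile residuals.
#' @param strict If `TRUE` (default), error when the least-squares fit
#'   leaves a large quantile residual; if `FALSE`, return the best fit
#'   regardless (used for censored summaries, e.g. intervals clipped at a
#'   policy cap, where no beta can match both quantiles). Residuals are
#'   always reported.
#' @return A `beta_params` list: `alpha`, `beta`, `mean`, `point_mass`,
#'   `quantile_residuals` (fitted minus stated `(lo, hi)`).
#' @export
beta_from_mean_ui <- function(mean, lo, hi, tolerance = 1e-6, strict = TRUE) {
  stopifnot(length(mean) == 1, length(lo) == 1, length(hi) == 1)
  if (!(lo <= mean && mean <= hi)) {
    stop("need lo <= mean <= hi", call. = FALSE)
  }
  if (lo <= 0 || hi >= 1) stop("bounds must lie inside (0, 1)", call. = FALSE)
  if (hi - lo < 1e-12) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, mean = mean,
                          point_mass = TRUE,
                          quantile_residuals = c(lo = 0, hi = 0)),
                     class = "beta_params"))
  }
  obj <- function(log_kappa) {
    k <- exp(log_kappa)
    a <- mean * k
    b <- (1 - mean) * k
    (stats::qbeta(0.025, a, b) - lo)^2 + (stats::qbeta(0.975, a, b) - hi)^2
  }
  # moment-matching initialisation: kappa0 from sd0 = (hi - lo)/3.92
  sd0 <- (hi - lo) / 3.92
  kappa0 <- max(mean * (1 - mean) / sd0^2 - 1, 1e-3)
  # bracket generously around the initial guess, then refine
  interval <- log(kappa0) + c(-12, 12)
  opt <- stats::optimize(obj, interval = interval, tol = 1e-12)
  kappa <- exp(opt$minimum)
  a <- mean * kappa
  b <- (1 - mean) * kappa
  resid <- c(lo = stats::qbeta(0.025, a, b) - lo,
             hi = stats::qbeta(0.975, a, b) - hi)
  # the single free parameter cannot always absorb an asymmetric interval;
  # error only when the least-squares fit is far from the stated bounds
  if (strict && max(abs(resid)) > max(0.2 * (hi - lo), 1000 * tolerance)) {
    stop("beta quantile fit did not converge; residuals (lo, hi) = (",
         format(resid[1]), ", ", format(resid[2]), ")", call. = FALSE)
  }
  structure(list(alpha = a, beta = b, mean = mean, point_mass = FALSE,
                 quantile_residuals = resid),
            class = "beta_params")
}

sample_beta_params <- function(params, n) {
  if (params$point_mass) rep(params$mean, n)
  else stats::rbeta(n, params$alpha, params$beta)
}

#' Fit a gamma distribution by moment matching
#'
#' Closed form: `shape = (mean/sd)^2`, `scale = sd^2/mean`, so the fitted
#' distribution reproduces the stated mean and SD exactly. Used for
#' income-group GDP growth rates.
#'
#' @param mean,sd Positive mean and standard deviation.
#' @return A `gamma_params` list: `shape`, `scale`.
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) {
    stop("gamma moment matching needs mean > 0 and sd > 0", call. = FALSE)
  }
  structure(list(shape = (mean / sd)^2, scale = sd^2 / mean),
            class = "gamma_params")
}

#' Draw model coefficients from their sampling distribution
#'
#' Draws `n` coefficient vectors from a multivariate Gaussian with the
#' fitted coefficients as mean and their variance-covariance matrix as
#' covariance. The matrix square root is taken by symmetric eigen
#' decomposition; eigenvalues in `[-1e-10, 0)` are clipped to 0, anything
#' more negative is an error.
#'
#' @param model A `che_model`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return `n x 4` matrix of coefficient draws (columns `beta0..beta3`).
#' @export
sample_coefficients <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "che_model"), n >= 1)
  v <- (model$beta_vcov + t(model$beta_vcov)) / 2
  ev <- eigen(v, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    stop("coefficient variance-covariance matrix is not positive ",
         "semi-definite (min eigenvalue ", format(min(ev$values)), ")",
         call. = FALSE)
  }
  vals <- pmax(ev$values, 0)
  root <- ev$vectors %*% diag(sqrt(vals), nrow = length(vals))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * 4), n, 4)
    draws <- sweep(z %*% t(root), 2, model$beta, `+`)
    colnames(draws) <- names(model$beta)
    draws
  })
}

#' Monte Carlo propagation of parameter and estimation uncertainty
#'
#' The probabilistic sensitivity analysis. Per trial it draws (i) one
#' coefficient vector from the model's multivariate Gaussian, (ii) per
#' country one `oop_exp` and one `hex_gdp` value from beta distributions
#' fitted to the forecast mean and 95% interval, and (iii) one GDP growth
#' rate per income group (shared by all group members within the trial)
#' from a gamma distribution moment-matched to the group's mean and SD of
#' annualised growth. GDP is compounded to the horizon, CHE predicted per
#' country, and trials aggregated per group by the unweighted arithmetic
#' mean, yielding `n` group samples. Neither the residual term nor a fresh
#' random-effect draw enters by default (only input-parameter and
#' coefficient uncertainty); `include_residual` adds a residual draw for
#' sensitivity analysis.
#'
#' If base-year covariates are supplied, per-trial annualised decline
#' rates are also computed: with `decline_baseline = "per_trial"`
#' (default) the base-year group CHE is re-predicted within each trial
#' from the same coefficient draw, preserving the draw correlation between
#' baseline and endpoint; `"fixed"` divides by a fixed baseline instead
#' (supply `fixed_baseline`, e.g. from [baseline_group_che()]).
#'
#' @param model A `che_model`.
#' @param forecasts A `che_forecasts`.
#' @param growth A `che_growth` from [summarize_growth()].
#' @param n Number of Monte Carlo trials (default 100000); fewer than 100
#'   warns of unstable percentiles.
#' @param seed Integer seed controlling all draws.
#' @param use_blup Add each country's BLUP to its linear predictor.
#' @param baseline Optional data frame from [baseline_covariates()].
#' @param decline_baseline `"per_trial"` or `"fixed"`.
#' @param fixed_baseline Named per-group baseline CHE vector (required for
#'   `decline_baseline = "fixed"`).
#' @param include_residual Add a `Normal(0, residual SD)` draw to each
#'   country's logit prediction.
#' @return A `che_mc` object: `n`, `seed`, `countries` (id/group frame),
#'   `per_country` (`n x C` matrix), `per_group` (`n x G` matrix),
#'   `decline_per_group`, `baseline_per_group` (or NULL), `horizon_years`.
#' @export
run_monte_carlo <- function(model, forecasts, growth, n = 100000, seed = 1L,
                            use_blup = FALSE, baseline = NULL,
                            decline_baseline = c("per_trial", "fixed"),
                            fixed_baseline = NULL, include_residual = FALSE) {
  decline_baseline <- match.arg(decline_baseline)
  stopifnot(inherits(model, "che_model"), inherits(forecasts, "che_forecasts"),
            inherits(growth, "che_growth"), n >= 1)
  if (n < 100) warning("n < 100 Monte Carlo trials: percentiles unstable",
                       call. = FALSE)
  fs <- forecasts[order(forecasts$country_id), , drop = FALSE]
  known <- as.character(fs$income_group) %in% as.character(growth$income_group)
  if (any(!known)) {
    warning("excluding countries with no group growth summary: ",
            paste(fs$country_id[!known], collapse = ", "), call. = FALSE)
    fs <- fs[known, , drop = FALSE]
  }
  n_c <- nrow(fs)
  if (n_c == 0) stop("no usable forecast countries", call. = FALSE)

  # fit input distributions up front (deterministic); a country under a
  # policy cap gets a best-effort fit because its clipped interval may be
  # top-censored (no beta matches it exactly) -- its draws are clipped at
  # the cap below, which realises the censored distribution directly
  has_cap <- if (is.null(fs$oop_exp_cap)) rep(FALSE, n_c) else !is.na(fs$oop_exp_cap)
  oop_dist <- lapply(seq_len(n_c), function(i) {
    tryCatch(
      beta_from_mean_ui(fs$oop_exp_mean[i], fs$oop_exp_lo[i],
                        fs$oop_exp_hi[i], strict = !has_cap[i]),
      error = function(e) NULL)
  })
  hex_dist <- lapply(seq_len(n_c), function(i) {
    tryCatch(
      beta_from_mean_ui(fs$hex_gdp_mean[i], fs$hex_gdp_lo[i], fs$hex_gdp_hi[i]),
      error = function(e) NULL)
  })
  usable <- !vapply(oop_dist, is.null, logical(1)) &
    !vapply(hex_dist, is.null, logical(1))
  if (any(!usable)) {
    warning("excluding countries whose forecast distributions could not be ",
            "fitted: ", paste(fs$country_id[!usable], collapse = ", "),
            call. = FALSE)
    fs <- fs[usable, , drop = FALSE]
    oop_dist <- oop_dist[usable]
    hex_dist <- hex_dist[usable]
    n_c <- nrow(fs)
  }
  groups_present <- income_groups()[income_groups() %in% as.character(fs$income_group)]
  horizon_years <- fs$horizon_year - fs$base_year

  with_seed(seed, {
    # draw order is fixed: coefficients, then group growth (group level
    # order), then per country (sorted ids) oop/hex (+ optional residual)
    coefs <- {
      v <- (model$beta_vcov + t(model$beta_vcov)) / 2
      ev <- eigen(v, symmetric = TRUE)
      if (any(ev$values < -1e-10)) {
        stop("coefficient vcov not PSD", call. = FALSE)
      }
      root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 4)
      sweep(matrix(stats::rnorm(n * 4), n, 4) %*% t(root), 2, model$beta, `+`)
    }
    growth_draws <- list()
    for (g in groups_present) {
      gl <- growth_lookup(growth, g)
      growth_draws[[g]] <- if (gl$sd_rate == 0) {
        rep(gl$mean_rate, n)
      } else {
        gp <- gamma_from_mean_sd(gl$mean_rate, gl$sd_rate)
        stats::rgamma(n, shape = gp$shape, scale = gp$scale)
      }
    }
    per_country <- matrix(NA_real_, n, n_c,
                          dimnames = list(NULL, fs$country_id))
    base_country <- if (!is.null(baseline) && decline_baseline == "per_trial") {
      matrix(NA_real_, n, n_c, dimnames = list(NULL, fs$country_id))
    } else NULL
    if (!is.null(baseline)) {
      bl <- baseline[match(fs$country_id, baseline$country_id), , drop = FALSE]
    }
    resid_sd <- sqrt(model$residual_variance)
    for (i in seq_len(n_c)) {
      oop <- sample_beta_params(oop_dist[[i]], n)
      if (!is.null(fs$oop_exp_cap) && !is.na(fs$oop_exp_cap[i])) {
        oop <- pmin(oop, fs$oop_exp_cap[i])
      }
      hex <- sample_beta_params(hex_dist[[i]], n)
      g <- as.character(fs$income_group[i])
      gdp <- fs$gdp_c_base[i] * (1 + growth_draws[[g]])^horizon_years[i]
      effect <- if (use_blup) {
        e <- model$country_effects[fs$country_id[i]]
        if (is.na(e)) 0 else unname(e)
      } else 0
      eta <- coefs[, 1] + coefs[, 2] * stats::qlogis(oop) +
        coefs[, 3] * stats::qlogis(hex) + coefs[, 4] * log(gdp) + effect
      if (include_residual && resid_sd > 0) {
        eta <- eta + stats::rnorm(n, 0, resid_sd)
      }
      per_country[, i] <- stats::plogis(eta)
      if (!is.null(base_country)) {
        if (is.na(bl$oop_exp[i]) || is.na(bl$hex_gdp[i]) || is.na(bl$gdp_c[i])) {
          base_country[, i] <- NA_real_
        } else {
          eta_b <- coefs[, 1] + coefs[, 2] * stats::qlogis(bl$oop_exp[i]) +
            coefs[, 3] * stats::qlogis(bl$hex_gdp[i]) +
            coefs[, 4] * log(bl$gdp_c[i]) + effect
          base_country[, i] <- stats::plogis(eta_b)
        }
      }
    }
    group_cols <- lapply(groups_present, function(g) {
      members <- which(as.character(fs$income_group) == g)
      rowMeans(per_country[, members, drop = FALSE])
    })
    per_group <- do.call(cbind, group_cols)
    colnames(per_group) <- groups_present

    decline_per_group <- baseline_per_group <- NULL
    ny <- max(horizon_years)
    if (!is.null(base_country)) {
      baseline_cols <- lapply(groups_present, function(g) {
        members <- which(as.character(fs$income_group) == g)
        m <- base_country[, members, drop = FALSE]
        rowMeans(m[, colSums(is.na(m)) == 0, drop = FALSE])
      })
      baseline_per_group <- do.call(cbind, baseline_cols)
      colnames(baseline_per_group) <- groups_present
      decline_per_group <- 1 - (per_group / baseline_per_group)^(1 / ny)
    } else if (!is.null(fixed_baseline) && decline_baseline == "fixed") {
      fb <- fixed_baseline[groups_present]
      decline_per_group <- 1 - sweep(per_group, 2, fb, `/`)^(1 / ny)
    }
    structure(list(n = n, seed = seed,
                   countries = fs[c("country_id", "income_group")],
                   per_country = per_country, per_group = per_group,
                   decline_per_group = decline_per_group,
                   baseline_per_group = baseline_per_group,
                   horizon_years = ny),
              class = "che_mc")
  })
}

#' @export
print.che_mc <- function(x, ...) {
  cat("Monte Carlo CHE samples:", x$n, "trials,",
      ncol(x$per_country), "countries,",
      ncol(x$per_group), "groups\n")
  for (g in colnames(x$per_group)) {
    ui <- percentile_ui(x$per_group[, g])
    cat(sprintf("  %-4s mean %.4f%%  95%% UI (%.4f%%, %.4f%%)\n", g,
                100 * mean(x$per_group[, g]), 100 * ui[1], 100 * ui[2]))
  }
  invisible(x)
}

#' Percentile-based uncertainty interval
#'
#' The 2.5th and 97.5th percentiles (by default) of a sample vector, using
#' linear interpolation between closest ranks (R's default quantile type
#' 7), giving the 95% uncertainty interval of Monte Carlo draws.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param lo_pct,hi_pct Percentile bounds in percent.
#' @return Length-2 numeric `(lo, hi)`.
#' @export
percentile_ui <- function(samples, lo_pct = 2.5, hi_pct = 97.5) {
  if (length(samples) < 2) stop("need >= 2 samples", call. = FALSE)
  unname(stats::quantile(samples, c(lo_pct, hi_pct) / 100,
                         type = 7, names = FALSE))
}

#' Financial-risk-protection target attainment probabilities
#'
#' For each income group and CHE threshold, the fraction of Monte Carlo
#' trials in which the group's CHE incidence lies strictly below the
#' threshold. Default thresholds are the four candidate targets 0.5%, 1%,
#' 1.5% and 2% (as proportions). High-income countries are excluded from
#' the probability table by default (they are reported in the group
#' summary regardless); set `include_hic = TRUE` to include them.
#'
#' @param samples A `che_mc` from [run_monte_carlo()].
#' @param thresholds Proportions in (0, 1).
#' @param include_hic Include HIC rows in the probability table.
#' @param point Optional named per-group point estimates (e.g. from the
#'   deterministic projection) to report alongside; defaults to the Monte
#'   Carlo means.
#' @param gap_reference Group against which gap-closing probabilities are
#'   computed (fraction of trials with a group's decline rate strictly
#'   above the reference group's); only when decline samples exist.
#' @return A `che_target_report`: `probabilities` (long data frame),
#'   `groups` (point, UI, decline and gap summaries), `thresholds`.
#' @export
target_probabilities <- function(samples,
                                 thresholds = c(0.005, 0.010, 0.015, 0.020),
                                 include_hic = FALSE, point = NULL,
                                 gap_reference = "UMIC") {
  stopifnot(inherits(samples, "che_mc"))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be proportions in (0, 1)", call. = FALSE)
  }
  thresholds <- sort(thresholds)
  groups <- colnames(samples$per_group)
  prob_groups <- if (include_hic) groups else setdiff(groups, "HIC")
  probs <- do.call(rbind, lapply(prob_groups, function(g) {
    data.frame(income_group = g, threshold = thresholds,
               probability = vapply(thresholds, function(th) {
                 mean(samples$per_group[, g] < th)
               }, 0))
  }))
  if (is.null(probs)) {
    probs <- data.frame(income_group = character(), threshold = numeric(),
                        probability = numeric())
  } else {
    probs$income_group <- as_income_group(probs$income_group)
  }
  group_rows <- lapply(groups, function(g) {
    draws <- samples$per_group[, g]
    ui <- percentile_ui(draws)
    row <- data.frame(income_group = g,
                      che_point = if (!is.null(point)) unname(point[g]) else mean(draws),
                      che_lo = ui[1], che_hi = ui[2],
                      decline_point = NA_real_, decline_lo = NA_real_,
                      decline_hi = NA_real_, gap_probability = NA_real_)
    if (!is.null(samples$decline_per_group) &&
        g %in% colnames(samples$decline_per_group)) {
      d <- samples$decline_per_group[, g]
      dui <- percentile_ui(d)
      row$decline_point <- mean(d)
      row$decline_lo <- dui[1]
      row$decline_hi <- dui[2]
      if (g != gap_reference &&
          gap_reference %in% colnames(samples$decline_per_group)) {
        row$gap_probability <- gap_closing_probability(
          d, samples$decline_per_group[, gap_reference])
      }
    }
    row
  })
  groups_df <- do.call(rbind, group_rows)
  groups_df$income_group <- as_income_group(groups_df$income_group)
  structure(list(probabilities = probs, groups = groups_df,
                 thresholds = thresholds),
            class = "che_target_report")
}

#' Probability that one group's decline outpaces a reference group's
#'
#' Fraction of paired Monte Carlo trials in which `decline_a` strictly
#' exceeds `decline_ref`. Trials must be matched pairwise (same trial
#' index), preserving the coefficient-draw correlation between groups;
#' ties count as not exceeding.
#'
#' @param decline_a,decline_ref Equal-length per-trial decline-rate vectors.
#' @return Probability in `[0, 1]`.
#' @export
gap_closing_probability <- function(decline_a, decline_ref) {
  if (length(decline_a) != length(decline_ref)) {
    stop("decline arrays must have equal length (paired trials)", call. = FALSE)
  }
  mean(decline_a > decline_ref)
}
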
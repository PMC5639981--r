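#' Logit and inverse-logit transforms
#'
#' `logit(p)` maps a proportion in (0, 1) to the real line via
#' `log(p / (1 - p))`; `inv_logit()` is its inverse. Both the CHE outcome
#' and the OOP_EXP / HEX_GDP covariates enter the model on this scale.
#'
#' @param p Numeric vector of proportions, strictly inside (0, 1).
#' @param x Numeric vector on the real line.
#' @return Numeric vector of the same length.
#' @examples
#' logit(0.5)        # 0
#' inv_logit(logit(0.4))
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("logit() requires proportions strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Relative change in outcome odds implied by a logit-logit coefficient
#'
#' For a model linear in the logit of a predictor, a relative change `c` in
#' the *odds* of that predictor multiplies the outcome odds by
#' `(1 + c)^beta`. This returns the implied fractional change
#' `(1 + c)^beta - 1`. Note this is an odds ratio statement, not a
#' risk-ratio approximation: it describes odds, and only approximates
#' relative risk when the outcome is rare.
#'
#' @param beta Coefficient on the logit (or log, for log-transformed
#'   predictors such as GDP per capita) of the predictor.
#' @param relative_change Fractional change in the predictor's odds (or
#'   level, for log predictors); must be greater than -1.
#' @return Fractional change in the outcome odds.
#' @examples
#' odds_effect(0.67, -0.10)  # ~ -0.068: a 10% odds reduction upstream
#' @export
odds_effect <- function(beta, relative_change) {
  stopifnot(is.numeric(beta), is.numeric(relative_change))
  if (any(relative_change <= -1)) {
    stop("relative_change must be > -1", call. = FALSE)
  }
  (1 + relative_change)^beta - 1
}

#' Annualised (geometric) rate of change between series endpoints
#'
#' Returns the constant per-year growth rate `r` such that
#' `first * (1 + r)^(year_last - year_first) = last`. Used to annualise
#' GDP-per-capita runs before compounding them to the horizon year.
#'
#' @param values Positive numeric vector (at least 2 values).
#' @param years Integer vector of the same length, strictly increasing.
#' @param method `"endpoint"` (default) uses only the first and last
#'   observations; `"ols_log"` fits a log-linear regression over all years
#'   and returns `exp(slope) - 1`.
#' @return Per-year fractional rate of change (> -1).
#' @examples
#' annualized_rate(c(100, 104.5), c(2015, 2016))  # 0.045
#' @export
annualized_rate <- function(values, years, method = c("endpoint", "ols_log")) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), is.numeric(years), length(values) == length(years))
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)
  if (method == "endpoint") {
    n <- length(values)
    (values[n] / values[1])^(1 / (years[n] - years[1])) - 1
  } else {
    exp(unname(stats::coef(stats::lm(log(values) ~ years))[2])) - 1
  }
}

#' Compound a base value at a constant annual rate
#'
#' @param base Positive starting value.
#' @param rate Per-year fractional rate (> -1).
#' @param n_years Non-negative integer number of years.
#' @return `base * (1 + rate)^n_years`.
#' @examples
#' compound(1000, 0.045, 27)
#' @export
compound <- function(base, rate, n_years) {
  stopifnot(is.numeric(base), is.numeric(rate), is.numeric(n_years))
  if (any(base <= 0)) stop("base must be positive", call. = FALSE)
  if (any(rate <= -1)) stop("rate must be > -1", call. = FALSE)
  if (any(n_years < 0)) stop("n_years must be non-negative", call. = FALSE)
  base * (1 + rate)^n_years
}

#' Annualised rate of decline between two incidence levels
#'
#' Returns `r` such that `start * (1 - r)^n_years = end`; positive when the
#' level falls. This is the per-year decline statistic reported for CHE
#' incidence between the base and horizon years.
#'
#' @param start,end Proportions in (0, 1).
#' @param n_years Positive integer horizon.
#' @return Per-year fractional decline rate (may be negative if `end > start`).
#' @examples
#' annualized_decline(0.02, 0.01, 27)
#' @export
annualized_decline <- function(start, end, n_years) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (any(start <= 0 | start >= 1 | end <= 0 | end >= 1)) {
    stop("start and end must be proportions in (0, 1)", call. = FALSE)
  }
  if (any(n_years < 1)) stop("n_years must be >= 1", call. = FALSE)
  1 - (end / start)^(1 / n_years)
}

#' Cumulative fraction removed after compounding a decline rate
#'
#' The total relative reduction over `n_years` of a constant annual decline
#' rate `r`: `1 - (1 - r)^n_years`. Inverse of [annualized_decline()].
#'
#' @param rate Per-year fractional decline (< 1).
#' @param n_years Positive integer horizon.
#' @return Fraction of the starting level removed after `n_years`.
#' @examples
#' cumulative_decline(0.017, 27)  # ~ 0.37
#' @export
cumulative_decline <- function(rate, n_years) {
  stopifnot(is.numeric(rate), is.numeric(n_years))
  if (any(rate >= 1)) stop("rate must be < 1", call. = FALSE)
  if (any(n_years < 1)) stop("n_years must be >= 1", call. = FALSE)
  1 - (1 - rate)^n_years
}
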
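#' Define a counterfactual policy scenario
#'
#' Currently one policy lever is modelled: a cap on the out-of-pocket
#' share of health expenditure (`oop_exp`) at the horizon year, applied to
#' a chosen set of income groups.
#'
#' @param name Scenario label.
#' @param oop_cap Cap on `oop_exp` as a proportion in (0, 1), or `NULL`
#'   for a pass-through scenario.
#' @param applies_to Income groups the cap applies to (default all four).
#' @return A `che_scenario` list.
#' @export
scenario <- function(name, oop_cap = NULL, applies_to = income_groups()) {
  if (!is.null(oop_cap) && (oop_cap <= 0 || oop_cap >= 1)) {
    stop("oop_cap must lie strictly inside (0, 1)", call. = FALSE)
  }
  applies_to <- as.character(applies_to)
  bad <- setdiff(applies_to, income_groups())
  if (length(bad) > 0) stop("unknown income group(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name), oop_cap = oop_cap,
                 applies_to = applies_to), class = "che_scenario")
}

#' Apply an out-of-pocket share cap to a forecast set
#'
#' For every country in a targeted income group, the `oop_exp` forecast
#' mean and both interval bounds are clipped at the cap
#' (`x <- min(x, cap)`), so capped covariates can never be sampled above
#' the cap and the `lo <= mean <= hi` ordering is preserved. Countries
#' outside the targeted groups pass through unchanged; the input forecast
#' set is never mutated.
#'
#' @param forecasts A `che_forecasts`.
#' @param scn A `che_scenario` from [scenario()].
#' @return A new `che_forecasts`.
#' @export
apply_oop_cap <- function(forecasts, scn) {
  stopifnot(inherits(forecasts, "che_forecasts"), inherits(scn, "che_scenario"))
  if (is.null(scn$oop_cap)) return(forecasts)
  out <- forecasts
  hit <- as.character(out$income_group) %in% scn$applies_to
  for (col in c("oop_exp_mean", "oop_exp_lo", "oop_exp_hi")) {
    out[[col]][hit] <- pmin(out[[col]][hit], scn$oop_cap)
  }
  # record the binding cap so Monte Carlo draws can be clipped at it too
  if (is.null(out$oop_exp_cap)) out$oop_exp_cap <- NA_real_
  out$oop_exp_cap[hit] <- pmin(out$oop_exp_cap[hit], scn$oop_cap, na.rm = TRUE)
  forecast_set(out)
}

#' Compare two target reports
#'
#' Tabulates the probability difference (alternative minus base) for every
#' (income group, threshold) cell, and the per-group CHE point-estimate
#' difference. Both reports must cover the same groups and thresholds.
#'
#' @param base,alt `che_target_report` objects with identical structure.
#' @return List with data frames `probabilities` (group, threshold,
#'   `prob_base`, `prob_alt`, `prob_diff`) and `groups` (group,
#'   `point_base`, `point_alt`, `point_diff`).
#' @export
compare_scenarios <- function(base, alt) {
  stopifnot(inherits(base, "che_target_report"),
            inherits(alt, "che_target_report"))
  key <- function(r) paste(r$probabilities$income_group,
                           r$probabilities$threshold)
  if (!identical(sort(key(base)), sort(key(alt))) ||
      !identical(sort(as.character(base$groups$income_group)),
                 sort(as.character(alt$groups$income_group)))) {
    stop("reports cover different groups or thresholds", call. = FALSE)
  }
  pb <- base$probabilities
  pa <- alt$probabilities[match(key(base), key(alt)), , drop = FALSE]
  probs <- data.frame(income_group = pb$income_group,
                      threshold = pb$threshold,
                      prob_base = pb$probability,
                      prob_alt = pa$probability,
                      prob_diff = pa$probability - pb$probability)
  gb <- base$groups
  ga <- alt$groups[match(as.character(gb$income_group),
                         as.character(alt$groups$income_group)), , drop = FALSE]
  groups <- data.frame(income_group = gb$income_group,
                       point_base = gb$che_point,
                       point_alt = ga$che_point,
                       point_diff = ga$che_point - gb$che_point)
  list(probabilities = probs, groups = groups)
}
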
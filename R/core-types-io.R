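#' World Bank income group levels
#'
#' The four income classes used throughout: low (LIC), lower-middle (LMIC),
#' upper-middle (UMIC) and high income (HIC). All grouped outputs follow
#' this ordering.
#'
#' @return Character vector of the four level codes.
#' @export
income_groups <- function() c("LIC", "LMIC", "UMIC", "HIC")

as_income_group <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), income_groups())
  if (length(bad) > 0) {
    stop("unknown income group(s): ", paste(bad, collapse = ", "),
         " (expected LIC, LMIC, UMIC, HIC)", call. = FALSE)
  }
  factor(x, levels = income_groups())
}

clip_proportion <- function(x, eps, what) {
  out_of_range <- !is.na(x) & (x < 0 | x > 1)
  if (any(out_of_range)) {
    stop(what, " has values outside [0, 1]; proportions expected ",
         "(use percent_input = TRUE for percent-scale files)", call. = FALSE)
  }
  at_bound <- !is.na(x) & (x <= eps | x >= 1 - eps)
  if (any(at_bound)) {
    warning(sum(at_bound), " ", what,
            " value(s) at or beyond the (0,1) boundary clipped to [",
            format(eps), ", ", format(1 - eps), "]", call. = FALSE)
    x[at_bound] <- pmin(pmax(x[at_bound], eps), 1 - eps)
  }
  x
}

panel_columns <- c("country_id", "income_group", "year",
                   "che", "oop_exp", "hex_gdp", "gdp_c")

#' Construct a validated country-year panel
#'
#' A `che_panel` is a data frame in long format with one row per country and
#' year, carrying the CHE incidence outcome (`che`, possibly missing) and
#' the three covariates: out-of-pocket share of health expenditure
#' (`oop_exp`), health expenditure share of GDP (`hex_gdp`) and GDP per
#' capita (`gdp_c`). All shares are stored as proportions in (0, 1).
#'
#' @param df Data frame with columns `country_id`, `income_group`, `year`,
#'   `che`, `oop_exp`, `hex_gdp`, `gdp_c`.
#' @param clip_epsilon Proportions equal to 0 or 1 (where the logit is
#'   undefined) are clipped into `(clip_epsilon, 1 - clip_epsilon)` with a
#'   warning.
#' @param provenance Free-text provenance note stored as an attribute.
#' @return A `che_panel` data frame.
#' @export
country_panel <- function(df, clip_epsilon = 1e-6, provenance = "in-memory") {
  missing_cols <- setdiff(panel_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[panel_columns]
  df$country_id <- as.character(df$country_id)
  df$income_group <- as_income_group(df$income_group)
  df$year <- as.integer(df$year)
  dup <- duplicated(df[c("country_id", "year")])
  if (any(dup)) {
    offenders <- unique(paste(df$country_id[dup], df$year[dup], sep = ", "))
    stop("duplicate (country, year) pairs: ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  if (any(is.na(df$gdp_c) | df$gdp_c <= 0)) {
    stop("gdp_c must be positive for every row", call. = FALSE)
  }
  for (col in c("che", "oop_exp", "hex_gdp")) {
    df[[col]] <- clip_proportion(df[[col]], clip_epsilon, col)
  }
  if (any(is.na(df$oop_exp) | is.na(df$hex_gdp))) {
    stop("oop_exp and hex_gdp may not be missing", call. = FALSE)
  }
  df <- df[order(df$country_id, df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("che_panel", "data.frame"))
}

#' Read a country-year panel from CSV
#'
#' @param path CSV file with the columns listed in [country_panel()].
#' @param clip_epsilon Boundary clipping tolerance, see [country_panel()].
#' @param percent_input If `TRUE`, `che`, `oop_exp` and `hex_gdp` are given
#'   on the percent scale (0-100) and divided by 100 on read. The scale is
#'   declared, never guessed from magnitudes.
#' @return A `che_panel` data frame.
#' @export
read_country_panel <- function(path, clip_epsilon = 1e-6, percent_input = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(panel_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("panel CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (percent_input) {
    for (col in c("che", "oop_exp", "hex_gdp")) df[[col]] <- df[[col]] / 100
  }
  country_panel(df, clip_epsilon = clip_epsilon, provenance = path)
}

#' @export
print.che_panel <- function(x, ...) {
  cat("CHE country-year panel:", nrow(x), "rows,",
      length(unique(x$country_id)), "countries,",
      sum(!is.na(x$che)), "CHE observations\n")
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

forecast_columns <- c("country_id", "income_group",
                      "oop_exp_mean", "oop_exp_lo", "oop_exp_hi",
                      "hex_gdp_mean", "hex_gdp_lo", "hex_gdp_hi",
                      "gdp_c_base", "base_year", "horizon_year")

#' Construct a validated horizon-year covariate forecast set
#'
#' One row per country with the forecast mean and 95% uncertainty interval
#' bounds for `oop_exp` and `hex_gdp` at the horizon year, plus the
#' base-year GDP per capita from which GDP is compounded forward.
#'
#' @param df Data frame with columns `country_id`, `income_group`,
#'   `oop_exp_mean/lo/hi`, `hex_gdp_mean/lo/hi`, `gdp_c_base`, `base_year`,
#'   `horizon_year`.
#' @return A `che_forecasts` data frame. Zero-width intervals
#'   (`lo == mean == hi`) are accepted and treated as point forecasts
#'   downstream.
#' @export
forecast_set <- function(df) {
  missing_cols <- setdiff(forecast_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("forecast set is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(forecast_columns, intersect("oop_exp_cap", names(df)))
  df <- as.data.frame(df)[keep]
  df$country_id <- as.character(df$country_id)
  df$income_group <- as_income_group(df$income_group)
  dup <- duplicated(df$country_id)
  if (any(dup)) {
    stop("duplicate forecast countries: ",
         paste(unique(df$country_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (stem in c("oop_exp", "hex_gdp")) {
    m <- df[[paste0(stem, "_mean")]]
    lo <- df[[paste0(stem, "_lo")]]
    hi <- df[[paste0(stem, "_hi")]]
    if (any(c(m, lo, hi) <= 0) || any(c(m, lo, hi) >= 1)) {
      stop(stem, " forecast values must lie strictly inside (0, 1)",
           call. = FALSE)
    }
    bad <- lo > m | m > hi
    if (any(bad)) {
      stop(stem, " interval ordering lo <= mean <= hi violated for: ",
           paste(df$country_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (any(df$gdp_c_base <= 0)) stop("gdp_c_base must be positive", call. = FALSE)
  if (any(df$horizon_year <= df$base_year)) {
    stop("horizon_year must exceed base_year", call. = FALSE)
  }
  df <- df[order(df$country_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("che_forecasts", "data.frame"))
}

#' Read horizon-year covariate forecasts from CSV
#'
#' @param path CSV file with the columns listed in [forecast_set()].
#' @param panel Optional `che_panel`; forecast countries absent from the
#'   panel are kept but flagged with a warning.
#' @return A `che_forecasts` data frame.
#' @export
read_forecasts <- function(path, panel = NULL) {
  fs <- forecast_set(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(panel)) {
    extra <- setdiff(fs$country_id, unique(panel$country_id))
    if (length(extra) > 0) {
      warning("forecast countries absent from panel (retained): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  fs
}

gdp_proj_columns <- c("country_id", "income_group", "year", "gdp_c")

#' Construct / read GDP-per-capita projection runs
#'
#' Long-format multi-year GDP-per-capita series per country (the input to
#' growth annualisation), e.g. IMF projections over 2015-2021.
#'
#' @param df Data frame with columns `country_id`, `income_group`, `year`,
#'   `gdp_c`; per country the years must be strictly increasing with at
#'   least two entries.
#' @return A `che_gdp_proj` data frame.
#' @export
gdp_projections <- function(df) {
  missing_cols <- setdiff(gdp_proj_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("GDP projections missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[gdp_proj_columns]
  df$country_id <- as.character(df$country_id)
  df$income_group <- as_income_group(df$income_group)
  df$year <- as.integer(df$year)
  if (any(df$gdp_c <= 0)) stop("gdp_c must be positive", call. = FALSE)
  df <- df[order(df$country_id, df$year), , drop = FALSE]
  counts <- table(df$country_id)
  if (any(counts < 2)) {
    stop("each country needs >= 2 projection years; offenders: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[c("country_id", "year")])
  if (any(dup)) {
    stop("duplicate (country, year) in GDP projections: ",
         paste(unique(paste(df$country_id[dup], df$year[dup])), collapse = "; "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("che_gdp_proj", "data.frame"))
}

#' @rdname gdp_projections
#' @param path CSV file path.
#' @export
read_gdp_projections <- function(path) {
  gdp_projections(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Full-precision CSV writer: numbers serialised to 15 significant digits so
# read/write round trips preserve >= 12 digits.
write_csv_precise <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write / read a target-attainment report
#'
#' Serialises a `che_target_report` (see [target_probabilities()]) as two
#' CSVs: the main file with one row per (income group, threshold) giving
#' the attainment probability, and a companion file of per-group CHE point
#' estimates, 95% uncertainty intervals, and (when available) gap-closing
#' probabilities. Numeric values survive the round trip to at least 12
#' significant digits.
#'
#' @param report A `che_target_report`.
#' @param path Output CSV path for the probability table.
#' @param companion_path Output path for the per-group summary; default
#'   derives `<path>_groups.csv`.
#' @return `write_target_report()` returns the two paths invisibly;
#'   `read_target_report()` returns a `che_target_report`.
#' @export
write_target_report <- function(report, path,
                                companion_path = default_companion(path)) {
  stopifnot(inherits(report, "che_target_report"))
  write_csv_precise(report$probabilities, path)
  write_csv_precise(report$groups, companion_path)
  invisible(c(path, companion_path))
}

default_companion <- function(path) {
  sub("(\\.[Cc][Ss][Vv])?$", "_groups.csv", path, perl = TRUE)
}

#' @rdname write_target_report
#' @export
read_target_report <- function(path, companion_path = default_companion(path)) {
  probs <- utils::read.csv(path, stringsAsFactors = FALSE)
  groups <- utils::read.csv(companion_path, stringsAsFactors = FALSE)
  if (nrow(probs) > 0) probs$income_group <- as_income_group(probs$income_group)
  if (nrow(groups) > 0) groups$income_group <- as_income_group(groups$income_group)
  structure(list(probabilities = probs, groups = groups,
                 thresholds = sort(unique(probs$threshold))),
            class = "che_target_report")
}

#' @export
print.che_target_report <- function(x, ...) {
  cat("Target attainment probabilities (fraction of Monte Carlo trials",
      "with group CHE below threshold):\n")
  if (nrow(x$probabilities) > 0) {
    wide <- stats::reshape(x$probabilities, idvar = "income_group",
                           timevar = "threshold", direction = "wide")
    names(wide) <- sub("^probability\\.", "CHE < ", names(wide))
    print(wide, row.names = FALSE)
  }
  cat("\nGroup estimates:\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
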
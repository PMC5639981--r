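#' Write the three input tables to CSV
#'
#' Full-precision CSV writers for the panel, forecast and GDP-projection
#' schemas consumed by [read_country_panel()], [read_forecasts()] and
#' [read_gdp_projections()].
#'
#' @param x The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_panel <- function(x, path) {
  stopifnot(inherits(x, "che_panel"))
  write_csv_precise(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_country_panel
#' @export
write_forecasts <- function(x, path) {
  stopifnot(inherits(x, "che_forecasts"))
  write_csv_precise(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_country_panel
#' @export
write_gdp_projections <- function(x, path) {
  stopifnot(inherits(x, "che_gdp_proj"))
  write_csv_precise(as.data.frame(x), path)
  invisible(path)
}

#' Read and normalise a run configuration
#'
#' A YAML file with either a `data:` block (paths to `panel`, `forecasts`,
#' `gdp_projections` CSVs) or a `synthetic:` block ([generator_config()]
#' fields) — exactly one is required — plus optional blocks:
#' `model: {method, use_blup}`, `mc: {n, seed, thresholds, include_hic,
#' decline_baseline}`, `scenarios: [{name, oop_cap, applies_to}, ...]`,
#' and top-level `seed`, `output_dir`, `percent_input`, `annualization`.
#'
#' @param path YAML file path.
#' @return A `che_run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  # YAML 1.1 would read the bare key `n` (as in `mc: {n: ...}`) as boolean
  # FALSE; restrict boolean scalars to true/false spellings
  handlers <- list(
    "bool#no" = function(x) if (tolower(x) == "false") FALSE else x,
    "bool#yes" = function(x) if (tolower(x) == "true") TRUE else x
  )
  raw <- yaml::read_yaml(path, handlers = handlers)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config A plain list with the same structure as the YAML file.
#' @export
as_run_config <- function(config) {
  defaults <- list(
    seed = 1L,
    output_dir = "che_outputs",
    percent_input = FALSE,
    annualization = "endpoint",
    model = list(method = "REML", use_blup = FALSE),
    mc = list(n = 100000L, seed = NULL, thresholds = c(0.005, 0.01, 0.015, 0.02),
              include_hic = FALSE, decline_baseline = "per_trial"),
    scenarios = list()
  )
  cfg <- utils::modifyList(defaults, config)
  # modifyList drops unnamed elements, which a scenario list is made of
  if (!is.null(config$scenarios)) cfg$scenarios <- config$scenarios
  has_data <- !is.null(cfg$data)
  has_synth <- !is.null(cfg$synthetic)
  if (!has_data && !has_synth) {
    stop("config needs either a 'data' block (CSV paths) or a 'synthetic' ",
         "block (generator settings)", call. = FALSE)
  }
  if (is.null(cfg$mc$seed)) cfg$mc$seed <- cfg$seed
  structure(cfg, class = "che_run_config")
}

config_to_generator <- function(cfg) {
  syn <- cfg$synthetic
  args <- list(seed = cfg$seed)
  for (nm in c("n_countries_per_group", "years", "true_beta",
               "random_effect_sd", "residual_sd", "che_missingness",
               "ar1_rho", "horizon_year", "seed")) {
    if (!is.null(syn[[nm]])) args[[nm]] <- unlist(syn[[nm]])
  }
  if (!is.null(syn$years) && length(syn$years) == 2) {
    args$years <- syn$years[1]:syn$years[2]
  }
  do.call(generator_config, args)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full projection pipeline
#'
#' End-to-end driver: load (or generate) the inputs, fit the mixed model,
#' summarise GDP growth, compute the deterministic point projection, run
#' the Monte Carlo uncertainty propagation, evaluate target-attainment
#' probabilities, and re-run every configured policy scenario. All
#' artifacts are written under `output_dir`:
#'
#' * `model.json` — fitted model (coefficients, vcov, variances, BLUPs)
#' * `projection_country.csv` / `projection_group.csv` — point projections
#' * `target_report.csv` / `target_report_groups.csv` / `target_report.json`
#' * `decline_samples.csv` — thinned per-group decline-rate draws
#'   (histogram data)
#' * `gap_scatter.csv` — thinned paired decline draws against the
#'   reference group (scatter data)
#' * `scenario_<name>*.csv` — capped-run reports and comparisons
#' * `run_log.txt` — seed, versions, row counts, stage log
#' * with a synthetic config, the three generated input CSVs
#'
#' @param config A `che_run_config` (or path to a YAML file, or a plain
#'   list).
#' @param mc_n,seed Optional overrides of `mc$n` and the top-level seed.
#' @return Invisibly, a list with the in-memory `model`, `projection`,
#'   `mc`, `report`, `scenario_reports` and the artifact directory.
#' @export
run_pipeline <- function(config, mc_n = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "che_run_config")) config <- as_run_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$mc$seed <- as.integer(seed)
  }
  if (!is.null(mc_n)) config$mc$n <- as.integer(mc_n)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run_log.txt"), open = "wt")
  on.exit(close(log_con))
  log_line(log_con, "cheproj ", as.character(utils::packageVersion("cheproj")),
           " | R ", getRversion(), " | lme4 ",
           as.character(utils::packageVersion("lme4")))
  log_line(log_con, "seed=", config$seed, " mc.n=", config$mc$n,
           " mc.seed=", config$mc$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      gen_cfg <- config_to_generator(config)
      sim <- generate_panel(gen_cfg)
      fc <- generate_forecasts(sim$truth,
                               ui_width_factor = config$synthetic$ui_width_factor %||% 1)
      gp <- generate_gdp_projections(sim$truth)
      write_country_panel(sim$panel, file.path(out_dir, "synthetic_panel.csv"))
      write_forecasts(fc, file.path(out_dir, "synthetic_forecasts.csv"))
      write_gdp_projections(gp, file.path(out_dir, "synthetic_gdp_projections.csv"))
      list(panel = sim$panel, forecasts = fc, gdp = gp, truth = sim$truth)
    } else {
      panel <- read_country_panel(config$data$panel,
                                  percent_input = isTRUE(config$percent_input))
      list(panel = panel,
           forecasts = read_forecasts(config$data$forecasts, panel = panel),
           gdp = read_gdp_projections(config$data$gdp_projections),
           truth = NULL)
    }
  })
  log_line(log_con, "panel rows=", nrow(inputs$panel),
           " forecast countries=", nrow(inputs$forecasts),
           " gdp projection rows=", nrow(inputs$gdp))

  model <- stage("fit", fit_che_model(inputs$panel, method = config$model$method))
  write_model_json(model, file.path(out_dir, "model.json"))
  log_line(log_con, "model fitted: n_obs=", model$n_obs,
           " n_countries=", model$n_countries,
           " R2=", signif(model$r_squared, 4))

  growth <- stage("growth", summarize_growth(inputs$gdp,
                                             method = config$annualization))
  proj <- stage("projection",
                project_group_che(model, inputs$forecasts, growth,
                                  use_blup = isTRUE(config$model$use_blup)))
  write_csv_precise(proj$country, file.path(out_dir, "projection_country.csv"))
  write_csv_precise(proj$group, file.path(out_dir, "projection_group.csv"))

  baseline <- stage("baseline", baseline_covariates(inputs$panel))
  run_mc <- function(fc) {
    run_monte_carlo(model, fc, growth, n = config$mc$n, seed = config$mc$seed,
                    use_blup = isTRUE(config$model$use_blup),
                    baseline = baseline,
                    decline_baseline = config$mc$decline_baseline)
  }
  mc <- stage("monte-carlo", run_mc(inputs$forecasts))
  point <- stats::setNames(proj$group$che_point,
                           as.character(proj$group$income_group))
  report <- stage("targets",
                  target_probabilities(mc, thresholds = config$mc$thresholds,
                                       include_hic = isTRUE(config$mc$include_hic),
                                       point = point))
  write_target_report(report, file.path(out_dir, "target_report.csv"))
  jsonlite::write_json(list(probabilities = report$probabilities,
                            groups = report$groups),
                       file.path(out_dir, "target_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # thinned draw dumps for figures (every k-th trial, deterministic)
  if (!is.null(mc$decline_per_group)) {
    keep <- seq(1, mc$n, length.out = min(1000, mc$n))
    dg <- as.data.frame(mc$decline_per_group[keep, , drop = FALSE])
    dg$trial <- as.integer(keep)
    write_csv_precise(dg, file.path(out_dir, "decline_samples.csv"))
    if ("UMIC" %in% names(dg)) {
      sc <- dg[c("trial", intersect(c("LIC", "LMIC"), names(dg)), "UMIC")]
      write_csv_precise(sc, file.path(out_dir, "gap_scatter.csv"))
    }
  }

  scenario_reports <- list()
  for (s in config$scenarios) {
    scn <- scenario(s$name, oop_cap = s$oop_cap,
                    applies_to = s$applies_to %||% income_groups())
    capped <- stage(paste0("scenario:", scn$name),
                    apply_oop_cap(inputs$forecasts, scn))
    proj_s <- project_group_che(model, capped, growth,
                                use_blup = isTRUE(config$model$use_blup))
    mc_s <- run_mc(capped)
    point_s <- stats::setNames(proj_s$group$che_point,
                               as.character(proj_s$group$income_group))
    rep_s <- target_probabilities(mc_s, thresholds = config$mc$thresholds,
                                  include_hic = isTRUE(config$mc$include_hic),
                                  point = point_s)
    write_target_report(rep_s,
                        file.path(out_dir, paste0("scenario_", scn$name, ".csv")))
    cmp <- compare_scenarios(report, rep_s)
    write_csv_precise(cmp$probabilities,
                      file.path(out_dir, paste0("scenario_", scn$name, "_diff.csv")))
    scenario_reports[[scn$name]] <- rep_s
    log_line(log_con, "scenario ", scn$name, " complete")
  }
  log_line(log_con, "pipeline complete")
  invisible(list(model = model, growth = growth, projection = proj, mc = mc,
                 report = report, scenario_reports = scenario_reports,
                 output_dir = out_dir))
}

#' Render summary tables from pipeline artifacts
#'
#' Reads the artifact files written by [run_pipeline()] and returns (and
#' prints) a groups-by-thresholds attainment probability table and a table
#' of per-group point estimates with 95% uncertainty intervals.
#'
#' @param outputs_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list with `probabilities` (wide data frame) and
#'   `estimates`.
#' @export
make_report_tables <- function(outputs_dir) {
  tr_path <- file.path(outputs_dir, "target_report.csv")
  for (p in c(tr_path, default_companion(tr_path))) {
    if (!file.exists(p)) stop("missing pipeline artifact: ", p, call. = FALSE)
  }
  report <- read_target_report(tr_path)
  wide <- if (nrow(report$probabilities) > 0) {
    w <- stats::reshape(report$probabilities, idvar = "income_group",
                        timevar = "threshold", direction = "wide")
    names(w) <- sub("^probability\\.", "P(CHE < ", names(w))
    names(w)[-1] <- paste0(names(w)[-1], ")")
    rownames(w) <- NULL
    w
  } else {
    data.frame(income_group = character())
  }
  est <- report$groups[c("income_group", "che_point", "che_lo", "che_hi")]
  est$che_pct <- 100 * est$che_point
  est$ui_pct <- sprintf("(%.2f, %.2f)", 100 * est$che_lo, 100 * est$che_hi)
  cat("Target attainment probabilities:\n")
  print(wide, row.names = FALSE)
  cat("\nGroup CHE point estimates and 95% UIs (%):\n")
  print(est[c("income_group", "che_pct", "ui_pct")], row.names = FALSE)
  invisible(list(probabilities = wide, estimates = est))
}
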
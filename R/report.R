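# Reporting surface: configuration-driven reproducible runs with logged
# manifests and publication-style tables. A thin command-line wrapper over
# these functions ships in inst/cli/partsa_hta.R.

#' Assemble a run configuration
#'
#' @param parameter_file path to a parameter file readable by
#'   [load_parameter_set()].
#' @param scenarios list of [scenario_spec()] objects (unique labels).
#' @param seed master seed; overrides the parameter file's.
#' @param n_psa iterations; overrides the parameter file's.
#' @param wtp_thresholds optional WTP override.
#' @param currencies subset of `c("CAD", "USD")` to report.
#' @param output_dir directory for artifacts (created if needed).
#' @return an object of class `run_config`.
#' @export
run_config <- function(parameter_file,
                       scenarios = list(scenario_spec()),
                       seed = NULL, n_psa = NULL,
                       wtp_thresholds = NULL,
                       currencies = c("CAD", "USD"),
                       output_dir = "partsa_output") {
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("validation error: scenario labels must be unique", call. = FALSE)
  }
  currencies <- match.arg(currencies, c("CAD", "USD"), several.ok = TRUE)
  structure(list(parameter_file = parameter_file, scenarios = scenarios,
                 seed = seed, n_psa = n_psa,
                 wtp_thresholds = wtp_thresholds,
                 currencies = currencies, output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys: `parameter_file`, `seed`, `n_psa`, `wtp_thresholds`,
#' `currencies`, `output_dir`, and `scenarios` (list of maps with
#' `extrapolation_policy`, `include_testing`, `label`). Unknown keys fail
#' fast before any computation.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("parameter_file", "scenarios", "seed", "n_psa",
             "wtp_thresholds", "currencies", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("validation error: unknown config fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$parameter_file)) {
    stop("validation error: config needs a parameter_file", call. = FALSE)
  }
  scen <- if (is.null(raw$scenarios)) list(scenario_spec()) else {
    lapply(raw$scenarios, function(s) {
      bad_s <- setdiff(names(s), c("extrapolation_policy",
                                   "include_testing", "label"))
      if (length(bad_s)) {
        stop("validation error: unknown scenario fields: ",
             paste(bad_s, collapse = ", "), call. = FALSE)
      }
      scenario_spec(s$extrapolation_policy %||% "restricted",
                    s$include_testing %||% FALSE, s$label)
    })
  }
  run_config(raw$parameter_file, scen, raw$seed, raw$n_psa,
             raw$wtp_thresholds, raw$currencies %||% c("CAD", "USD"),
             raw$output_dir %||% "partsa_output")
}

summary_row <- function(s) {
  row <- data.frame(level = s$level, currency = s$currency,
                    mean_delta_cost = s$mean_delta_cost,
                    delta_cost_lo = s$ci_delta_cost[1],
                    delta_cost_hi = s$ci_delta_cost[2],
                    mean_delta_qaly = s$mean_delta_qaly,
                    delta_qaly_lo = s$ci_delta_qaly[1],
                    delta_qaly_hi = s$ci_delta_qaly[2],
                    icer = if (is.character(s$icer)) NA_real_
                           else as.numeric(s$icer),
                    icer_label = if (is.character(s$icer)) s$icer else "",
                    stringsAsFactors = FALSE)
  for (w in names(s$inmb_by_wtp)) {
    row[[paste0("inmb_", w)]] <- s$inmb_by_wtp[[w]]$mean
    row[[paste0("prob_ce_", w)]] <- s$inmb_by_wtp[[w]]$prob_ce
  }
  row
}

#' Summary table across levels for one scenario result
#'
#' One row per indication plus a tumor-agnostic row, mirroring a
#' publication-style probabilistic outputs table, at full precision
#' (rounding is left to presentation).
#'
#' @param res a [run_scenario()] result.
#' @param currency `"CAD"` or `"USD"`.
#' @return data frame.
#' @export
scenario_summary_table <- function(res, currency = "CAD") {
  sums <- res$summaries[[currency]]
  out <- do.call(rbind, lapply(sums, summary_row))
  rownames(out) <- NULL
  out
}

#' Execute a configured run and write all artifacts
#'
#' For each scenario: PSA + deterministic run, summary tables per currency,
#' cost-effectiveness-plane and PSA long CSVs, deterministic frontier CSV,
#' EVPI curves CSV; plus a JSON manifest carrying the seed, package
#' version and a checksum of the parameter file so any output can be
#' reproduced exactly.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return invisibly, the list of [run_scenario()] results.
#' @export
cmd_run <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- load_parameter_set(config$parameter_file)
  if (!is.null(config$wtp_thresholds)) {
    p$globals$wtp_thresholds <- as.numeric(config$wtp_thresholds)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  results <- run_scenario_batch(p, config$scenarios,
                                n_psa = config$n_psa, seed = config$seed)
  for (label in names(results)) {
    res <- results[[label]]
    stem <- file.path(config$output_dir, gsub("[^A-Za-z0-9_+-]", "_", label))
    for (cur in config$currencies) {
      utils::write.csv(scenario_summary_table(res, cur),
                       paste0(stem, "_summary_", cur, ".csv"),
                       row.names = FALSE)
    }
    export_ce_plane_csv(res$psa, paste0(stem, "_ce_plane.csv"))
    export_psa_csv(res$psa, paste0(stem, "_psa_draws.csv"))
    export_frontier_csv(indication_frontier(p, res$scenario),
                        paste0(stem, "_frontier.csv"))
    export_evpi_csv(evpi_curves_all(res$psa), paste0(stem, "_evpi.csv"))
  }

  manifest <- list(
    parameter_file = config$parameter_file,
    parameter_checksum = unname(tools::md5sum(config$parameter_file)),
    seed = config$seed %||% p$globals$seed,
    n_psa = config$n_psa %||% p$globals$n_psa,
    scenarios = names(results),
    package_version = as.character(utils::packageVersion("partsaHTA")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Validate a parameter file without running the model
#'
#' Checks file readability, per-field invariants, the prevalence-weight
#' simplex, median ordering (reporting would-be clamps) and distribution
#' validity.
#'
#' @param parameter_file path readable by [load_parameter_set()].
#' @return data frame with columns `check`, `passed`, `detail`.
#' @export
cmd_validate <- function(parameter_file) {
  checks <- data.frame(check = character(0), passed = logical(0),
                       detail = character(0), stringsAsFactors = FALSE)
  add <- function(check, passed, detail = "") {
    rbind(checks, data.frame(check = check, passed = passed,
                             detail = detail, stringsAsFactors = FALSE))
  }
  p <- NULL
  clamp_msgs <- character(0)
  load_err <- NULL
  withCallingHandlers(
    tryCatch(p <- load_parameter_set(parameter_file),
             error = function(e) load_err <<- conditionMessage(e)),
    warning = function(w) {
      clamp_msgs <<- c(clamp_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  checks <- add("file loads and validates", is.null(load_err),
                load_err %||% "")
  if (is.null(p)) return(checks)
  w <- vapply(p$indications, function(i) i$prevalence_weight, numeric(1))
  checks <- add("prevalence weights sum to 1", abs(sum(w) - 1) <= 1e-9,
                sprintf("sum = %.12g", sum(w)))
  checks <- add("median ordering (PFS <= OS)", length(clamp_msgs) == 0,
                paste(clamp_msgs, collapse = "; "))
  dist_err <- tryCatch({
    for (s in p$distributions) validate_distribution_spec(s)
    NULL
  }, error = function(e) conditionMessage(e))
  checks <- add("distribution specs valid", is.null(dist_err),
                dist_err %||% sprintf("%d specs", length(p$distributions)))
  checks
}
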
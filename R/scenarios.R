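# Named analyses: base case, full extrapolation, NGS testing scenario;
# number-needed-to-screen costing and tumor-agnostic aggregation.

#' Number needed to screen for one biomarker-positive patient
#'
#' The reciprocal of the per-tumor gene-fusion prevalence, kept real-valued
#' for cohort-average costing (round up via `nns_round_up` in the globals
#' when budgeting whole tests per patient).
#'
#' @param ntrk_prevalence biomarker prevalence in (0, 1].
#' @return number needed to screen, `1 / prevalence`.
#' @export
#' @examples
#' number_needed_to_screen(0.004)  # 250
number_needed_to_screen <- function(ntrk_prevalence) {
  if (any(!is.finite(ntrk_prevalence) | ntrk_prevalence <= 0 |
          ntrk_prevalence > 1)) {
    stop("prevalence must be in (0, 1]", call. = FALSE)
  }
  1 / ntrk_prevalence
}

#' Prevalence-weighted tumor-agnostic aggregation
#'
#' Per-iteration weighted sums of per-indication incremental outcome
#' vectors.
#'
#' @param per_indication list (one element per indication) of numeric
#'   vectors aligned by iteration.
#' @param weights prevalence weights summing to 1.
#' @return the aggregated vector.
#' @export
aggregate_agnostic <- function(per_indication, weights) {
  if (length(per_indication) != length(weights)) {
    stop("weights and indications do not match", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  lens <- vapply(per_indication, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("iteration vectors are not aligned", call. = FALSE)
  }
  out <- numeric(lens[1])
  for (j in seq_along(weights)) {
    out <- out + weights[j] * per_indication[[j]]
  }
  out
}

#' Run a named scenario end to end
#'
#' Executes the probabilistic analysis under the scenario flags plus a
#' deterministic companion run at parameter point values, and summarizes
#' per-indication and tumor-agnostic results in CAD and USD.
#'
#' @param p a `parameter_set`.
#' @param scenario a [scenario_spec()].
#' @param n_psa,seed overrides passed to [run_psa()].
#' @return a list with elements `scenario`, `psa` (`psa_result`),
#'   `deterministic` (from [run_deterministic()]), and `summaries` (nested
#'   list: currency -> level -> `ce_summary`).
#' @export
run_scenario <- function(p, scenario = scenario_spec(),
                         n_psa = NULL, seed = NULL) {
  psa <- run_psa(p, scenario, n_psa = n_psa, seed = seed)
  det <- run_deterministic(p, scenario)
  levels <- c("agnostic", psa$indications)
  summaries <- lapply(stats::setNames(c("CAD", "USD"), c("CAD", "USD")),
    function(cur) {
      lapply(stats::setNames(levels, levels), function(lv) {
        summarize_ce(psa, p$globals, lv, cur)
      })
    })
  list(scenario = scenario, psa = psa, deterministic = det,
       summaries = summaries)
}

#' Run a batch of scenarios
#'
#' @param p a `parameter_set`.
#' @param scenarios list of [scenario_spec()] objects with unique labels.
#' @param n_psa,seed overrides passed to each [run_psa()].
#' @return named list of [run_scenario()] results keyed by label.
#' @export
run_scenario_batch <- function(p, scenarios, n_psa = NULL, seed = NULL) {
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("scenario labels must be unique", call. = FALSE)
  }
  lapply(stats::setNames(scenarios, labels), function(s) {
    run_scenario(p, s, n_psa = n_psa, seed = seed)
  })
}
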
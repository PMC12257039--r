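# Partitioned-survival engine: state occupancy from OS/PFS curves and
# discounted cost/QALY accumulation on the weekly cycle grid.

#' Discount factor at a time point
#'
#' Annual compounding converted to the weekly clock:
#' `(1 + annual_rate)^(-t / 52.17857)` with 52.17857 = 365.25/7 weeks per
#' year. Both costs and QALYs use the same rate.
#'
#' @param t time in weeks (>= 0), vectorized.
#' @param annual_rate annual discount rate (>= 0).
#' @return discount factors in (0, 1].
#' @export
#' @examples
#' discount_factor(0, 0.015)                 # 1
#' discount_factor(365.25 / 7, 0.015)        # 1/1.015
discount_factor <- function(t, annual_rate) {
  stopifnot(all(t >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-t / WEEKS_PER_YEAR)
}

#' Scenario flags for an engine run
#'
#' @param extrapolation_policy `"restricted"` (treatment waning; base case)
#'   or `"full"` (optimistic).
#' @param include_testing add number-needed-to-screen sequencing costs to
#'   the intervention arm at cycle 0 (comparator untested).
#' @param label scenario label used in outputs.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(extrapolation_policy = c("restricted", "full"),
                          include_testing = FALSE,
                          label = NULL) {
  extrapolation_policy <- match.arg(extrapolation_policy)
  if (is.null(label)) {
    label <- paste0(if (extrapolation_policy == "restricted") "base"
                    else "full_extrapolation",
                    if (include_testing) "+testing" else "")
  }
  structure(list(extrapolation_policy = extrapolation_policy,
                 include_testing = isTRUE(include_testing),
                 label = label),
            class = "scenario_spec")
}

cycle_grid <- function(g) {
  if (g$horizon < g$cycle_length) {
    stop("configuration error: horizon shorter than one cycle",
         call. = FALSE)
  }
  n_cycles <- ceiling(g$horizon / g$cycle_length)
  (seq_len(n_cycles) - 1) * g$cycle_length
}

cycle_weights <- function(n, half_cycle_correction) {
  w <- rep(1, n)
  if (half_cycle_correction && n > 1) w[c(1, n)] <- 0.5
  w
}

#' Run one arm of the partitioned-survival model
#'
#' State occupancy at each cycle start comes straight from the curves:
#' progression-free is the (clamped) PFS curve, progression is OS minus PFS,
#' death is one minus OS. Accumulation per cycle, discounted at the cycle
#' start time:
#' \itemize{
#'   \item QALYs: occupancy times state utility times cycle length in years.
#'   \item Care costs: per-cycle progression-free and progressed care costs
#'     weighted by occupancy.
#'   \item Intervention drug and administration costs: accrue for cycles
#'     starting before the median time to treatment discontinuation (a
#'     10-week TTD buys exactly 10 weekly cycles of drug),
#'     weighted by progression-free occupancy (patients
#'     stop at progression); an unweighted variant is available via
#'     `drug_cost_pf_weighted = FALSE` in the globals.
#'   \item Comparator drug costs: accrue while progression free over the
#'     whole horizon (no discontinuation time is available for standard
#'     care).
#'   \item Adverse-event costs: one-off at cycle 0 per arm.
#'   \item Testing costs: number needed to screen times panel cost, added
#'     to the intervention arm at cycle 0 when the scenario includes
#'     testing; screening precedes treatment, so no discounting applies.
#' }
#'
#' @param curves an `arm_curves` object for this arm.
#' @param ind an [indication_params()] object.
#' @param g a [global_params()] object.
#' @param arm `"intervention"` or `"comparator"`.
#' @param scenario a [scenario_spec()].
#' @return an object of class `state_trace` with per-cycle occupancy and
#'   discounted totals, including a cost breakdown by component.
#' @export
run_arm <- function(curves, ind, g,
                    arm = c("intervention", "comparator"),
                    scenario = scenario_spec()) {
  arm <- match.arg(arm)
  t <- cycle_grid(g)
  occ <- arm_occupancy(curves, t)
  pf <- occ$pfs
  pd <- occ$os - occ$pfs
  dead <- 1 - occ$os

  disc <- discount_factor(t, g$discount_rate)
  # last cycle may extend past the horizon: prorate its accrual so the
  # modelled time is exactly the horizon
  frac <- pmin(g$cycle_length, g$horizon - t) / g$cycle_length
  w <- cycle_weights(length(t), g$half_cycle_correction) * frac
  cyc_yr <- g$cycle_length / WEEKS_PER_YEAR

  qaly_cycle <- (pf * g$utility_pf + pd * g$utility_pd) * cyc_yr * disc * w
  care_cycle <- (pf * ind$cost_pf_care + pd * ind$cost_pd_care) * disc * w

  drug <- admin <- 0
  drug_cycle <- numeric(length(t))
  if (arm == "intervention") {
    # a cycle starting at t covers [t, t + cycle_length): on treatment
    # while the cycle starts before the median discontinuation time
    on_tx <- as.numeric(t < ind$median_ttd)
    exposure <- if (g$drug_cost_pf_weighted) pf * on_tx else on_tx
    drug_cycle <- ind$cost_drug_tx_cycle * exposure * disc * w
    admin_cycle <- ind$cost_admin_tx_cycle * exposure * disc * w
    drug <- sum(drug_cycle)
    admin <- sum(admin_cycle)
    drug_cycle <- drug_cycle + admin_cycle
  } else {
    drug_cycle <- ind$cost_drug_soc_cycle * pf * disc * w
    drug <- sum(drug_cycle)
  }

  ae <- if (arm == "intervention") ind$cost_ae_tx else ind$cost_ae_soc
  testing <- if (arm == "intervention" && scenario$include_testing) {
    nns <- number_needed_to_screen(ind$ntrk_prevalence)
    if (g$nns_round_up) nns <- ceiling(nns)
    nns * ind$cost_ngs_panel
  } else 0

  breakdown <- c(care = sum(care_cycle), drug = drug, admin = admin,
                 adverse_event = ae, testing = testing)
  cost_cycle <- care_cycle + drug_cycle
  cost_cycle[1] <- cost_cycle[1] + ae + testing

  structure(list(
    times = t,
    occupancy = cbind(progression_free = pf, progressed = pd, dead = dead),
    discounted_qalys = sum(qaly_cycle),
    discounted_costs = sum(breakdown),
    cost_breakdown = breakdown,
    qaly_cycle = qaly_cycle,
    cost_cycle = cost_cycle,
    arm = arm
  ), class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("state_trace (%s arm): %d cycles, %.4f QALYs, %.2f cost\n",
              x$arm, length(x$times), x$discounted_qalys,
              x$discounted_costs))
  invisible(x)
}

#' Incremental outcomes between two arm traces
#'
#' Incremental cost and QALYs are intervention minus comparator. Under the
#' small-sample rule the indication contributes no incremental QALYs and
#' only the intervention arm's treatment-cost components (drug,
#' administration, and testing when present).
#'
#' @param tx,soc `state_trace` objects computed on identical grids.
#' @param small_sample logical small-sample flag.
#' @return named numeric vector `c(delta_cost, delta_qaly)`.
#' @export
incremental_outcomes <- function(tx, soc, small_sample = FALSE) {
  if (length(tx$times) != length(soc$times) ||
      any(tx$times != soc$times)) {
    stop("internal error: arm traces computed on different grids",
         call. = FALSE)
  }
  if (small_sample) {
    bd <- tx$cost_breakdown
    return(c(delta_cost = unname(bd["drug"] + bd["admin"] + bd["testing"]),
             delta_qaly = 0))
  }
  c(delta_cost = tx$discounted_costs - soc$discounted_costs,
    delta_qaly = tx$discounted_qalys - soc$discounted_qalys)
}

#' Run both arms for one indication and return incremental outcomes
#'
#' @param ind an [indication_params()] object (its `small_sample` flag, if
#'   set by [apply_small_sample_rule()], is honoured).
#' @param g a [global_params()] object.
#' @param scenario a [scenario_spec()].
#' @param detail return the two `state_trace` objects alongside the deltas.
#' @return named vector `c(delta_cost, delta_qaly)`; with `detail = TRUE`,
#'   a list with elements `delta`, `tx`, `soc`.
#' @export
run_indication <- function(ind, g, scenario = scenario_spec(),
                           detail = FALSE) {
  curves_tx <- build_intervention_curves(ind, g,
                                         scenario$extrapolation_policy)
  curves_soc <- build_comparator_curves(ind, g)
  tx <- run_arm(curves_tx, ind, g, "intervention", scenario)
  soc <- run_arm(curves_soc, ind, g, "comparator", scenario)
  delta <- incremental_outcomes(tx, soc, isTRUE(ind$small_sample))
  if (detail) list(delta = delta, tx = tx, soc = soc) else delta
}

#' Deterministic run over all indications with tumor-agnostic aggregation
#'
#' @param p a `parameter_set` (small-sample rule applied internally).
#' @param scenario a [scenario_spec()].
#' @return list with `per_indication` (data frame of name, weight,
#'   delta_cost, delta_qaly) and `aggregated` (prevalence-weighted
#'   `c(delta_cost, delta_qaly)`).
#' @export
run_deterministic <- function(p, scenario = scenario_spec()) {
  p <- apply_small_sample_rule(p)
  rows <- lapply(p$indications, function(ind) {
    d <- run_indication(ind, p$globals, scenario)
    data.frame(name = ind$name, weight = ind$prevalence_weight,
               delta_cost = d[["delta_cost"]],
               delta_qaly = d[["delta_qaly"]])
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  agg <- c(delta_cost = sum(df$weight * df$delta_cost),
           delta_qaly = sum(df$weight * df$delta_qaly))
  list(per_indication = df, aggregated = agg)
}

#' Export a state trace as CSV for audit
#'
#' @param trace a `state_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = seq_along(trace$times) - 1,
                   time_weeks = trace$times,
                   pf = trace$occupancy[, "progression_free"],
                   pd = trace$occupancy[, "progressed"],
                   dead = trace$occupancy[, "dead"],
                   cost_cycle = trace$cost_cycle,
                   qaly_cycle = trace$qaly_cycle)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
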
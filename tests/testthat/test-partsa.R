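# Partitioned-survival engine: occupancy, discounting, accumulation,
# incremental outcomes.

test_that("discount factor boundary values and the one-year factor", {
  expect_identical(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(c(0, 10, 400), 0), rep(1, 3))
  expect_equal(discount_factor(365.25 / 7, 0.015), 1 / 1.015,
               tolerance = 1e-12)
  expect_equal(discount_factor(365.25 / 7, 0.015), 0.985222,
               tolerance = 1e-6)
})

test_that("immortal cohort over one year accrues exactly the PF utility", {
  ind <- simple_indication(cost_drug_tx_cycle = 0, cost_admin_tx_cycle = 0,
                           cost_pf_care = 0, cost_pd_care = 0,
                           cost_ae_tx = 0, cost_ae_soc = 0)
  g <- global_params(utility_pf = 0.8, discount_rate = 0,
                     horizon = 365.25 / 7)
  curves <- arm_curves(survival_model(0, 0), survival_model(0, 0))
  trace <- run_arm(curves, ind, g, "intervention")
  expect_equal(trace$discounted_qalys, 0.8, tolerance = 1e-12)
  expect_equal(trace$discounted_costs, 0, tolerance = 1e-12)
})

test_that("a 10-week TTD buys exactly 10 weekly cycles of drug cost", {
  ind <- simple_indication(cost_drug_tx_cycle = 100,
                           cost_admin_tx_cycle = 0,
                           cost_pf_care = 0, cost_pd_care = 0,
                           cost_ae_tx = 0, median_ttd = 10)
  g <- global_params(discount_rate = 0, horizon = 104)
  curves <- arm_curves(survival_model(0, 0), survival_model(0, 0))
  trace <- run_arm(curves, ind, g, "intervention")
  expect_equal(unname(trace$cost_breakdown["drug"]), 1000, tolerance = 1e-12)
})

test_that("near-certain immediate death drives totals to zero", {
  ind <- simple_indication()
  g <- fast_globals()
  lam <- 50  # per-week: S(1) = exp(-50)
  curves <- arm_curves(survival_model(0, lam), survival_model(0, lam))
  trace <- run_arm(curves, ind, g, "comparator")
  # start-of-cycle rectangles always accrue the first cycle, so the limit
  # is one cycle's worth of utility and drug/care cost, not zero
  one_cycle_qaly <- g$utility_pf * g$cycle_length / (365.25 / 7)
  expect_lt(trace$discounted_qalys, one_cycle_qaly + 1e-9)
  expect_lt(trace$discounted_costs,
            trace$cost_breakdown["adverse_event"] +
              ind$cost_pf_care + ind$cost_drug_soc_cycle + 1e-9)
  expect_equal(unname(trace$occupancy[length(trace$times), "dead"]), 1,
               tolerance = 1e-12)
})

test_that("occupancy conserves mass and progression is OS minus PFS", {
  set.seed(5)
  for (k in 1:10) {
    p <- generate_fixture(seed = k, n_indications = 1)
    ind <- p$indications[[1]]
    g <- p$globals
    res <- run_indication(ind, g, detail = TRUE)
    for (trace in list(res$tx, res$soc)) {
      sums <- rowSums(trace$occupancy)
      expect_true(all(abs(sums - 1) <= 1e-9))
      expect_true(all(trace$occupancy >= 0 & trace$occupancy <= 1))
      expect_true(all(trace$occupancy[, "progressed"] >= -1e-15))
    }
  }
})

test_that("engine totals match an independent brute-force cycle sum", {
  for (sd in c(21, 22)) {
    p <- generate_fixture(seed = sd, n_indications = 1)
    ind <- p$indications[[1]]
    g <- p$globals
    res <- run_indication(ind, g, detail = TRUE)

    # independent accumulation: scalar loop over cycles, recomputing
    # survival from hazards directly
    lam_os <- log(2) / ind$median_os_soc
    lam_pfs <- log(2) / ind$median_pfs_soc
    qaly <- cost <- 0
    n_cyc <- ceiling(g$horizon / g$cycle_length)
    for (k in seq_len(n_cyc) - 1) {
      t <- k * g$cycle_length
      dur <- min(g$cycle_length, g$horizon - t)
      os <- exp(-lam_os * t)
      pf <- min(exp(-lam_pfs * t), os)
      pd <- os - pf
      disc <- (1 + g$discount_rate)^(-t / (365.25 / 7))
      qaly <- qaly + (pf * g$utility_pf + pd * g$utility_pd) *
        (dur / (365.25 / 7)) * disc
      cost <- cost + (pf * ind$cost_pf_care + pd * ind$cost_pd_care +
                        pf * ind$cost_drug_soc_cycle) *
        (dur / g$cycle_length) * disc
    }
    cost <- cost + ind$cost_ae_soc
    expect_equal(res$soc$discounted_qalys, qaly, tolerance = 1e-9)
    expect_equal(res$soc$discounted_costs, cost, tolerance = 1e-9)
  }
})

test_that("cost components sum to the discounted total", {
  p <- generate_fixture(seed = 31, n_indications = 2)
  for (ind in p$indications) {
    res <- run_indication(ind, p$globals,
                          scenario_spec(include_testing = TRUE),
                          detail = TRUE)
    for (trace in list(res$tx, res$soc)) {
      expect_equal(sum(trace$cost_breakdown), trace$discounted_costs,
                   tolerance = 1e-9)
      expect_equal(sum(trace$cost_cycle), trace$discounted_costs,
                   tolerance = 1e-9)
    }
  }
})

test_that("discounted totals do not increase with the discount rate", {
  ind <- simple_indication()
  rates <- c(0, 0.015, 0.05, 0.2)
  curves <- build_comparator_curves(ind)
  vals <- sapply(rates, function(r) {
    g <- global_params(discount_rate = r)
    trace <- run_arm(curves, ind, g, "comparator")
    c(trace$discounted_qalys, trace$discounted_costs)
  })
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("incremental outcomes subtract, and identical traces give (0,0)", {
  p <- generate_fixture(seed = 8, n_indications = 1)
  res <- run_indication(p$indications[[1]], p$globals, detail = TRUE)
  expect_equal(incremental_outcomes(res$tx, res$tx),
               c(delta_cost = 0, delta_qaly = 0))
  d <- incremental_outcomes(res$tx, res$soc)
  expect_equal(d[["delta_cost"]],
               res$tx$discounted_costs - res$soc$discounted_costs)
  expect_equal(d[["delta_qaly"]],
               res$tx$discounted_qalys - res$soc$discounted_qalys)
})

test_that("small-sample incremental outcomes are treatment costs only", {
  p <- generate_fixture(seed = 9, n_indications = 1)
  res <- run_indication(p$indications[[1]], p$globals, detail = TRUE)
  d <- incremental_outcomes(res$tx, res$soc, small_sample = TRUE)
  expect_identical(d[["delta_qaly"]], 0)
  expect_equal(d[["delta_cost"]],
               unname(res$tx$cost_breakdown["drug"] +
                        res$tx$cost_breakdown["admin"] +
                        res$tx$cost_breakdown["testing"]))
})

test_that("mismatched grids and sub-cycle horizons are rejected", {
  ind <- simple_indication()
  g1 <- global_params(horizon = 104)
  g2 <- global_params(horizon = 52)
  curves <- build_comparator_curves(ind)
  a <- run_arm(curves, ind, g1, "comparator")
  b <- run_arm(curves, ind, g2, "comparator")
  expect_error(incremental_outcomes(a, b), "grid")
  expect_error(run_arm(curves, ind, global_params(horizon = 0.5,
                                                  cycle_length = 0.4)),
               NA)  # one cycle is fine
  expect_error(cycle_grid <- run_arm(curves, ind,
                                     global_params(horizon = 10,
                                                   cycle_length = 20)),
               "horizon")
})

test_that("state trace exports a per-cycle audit CSV", {
  p <- generate_fixture(seed = 13, n_indications = 1)
  res <- run_indication(p$indications[[1]], p$globals, detail = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace_csv(res$tx, path)
  df <- read.csv(path)
  expect_named(df, c("cycle", "time_weeks", "pf", "pd", "dead",
                     "cost_cycle", "qaly_cycle"))
  expect_equal(nrow(df), length(res$tx$times))
  expect_equal(sum(df$qaly_cycle), res$tx$discounted_qalys,
               tolerance = 1e-9)
})
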
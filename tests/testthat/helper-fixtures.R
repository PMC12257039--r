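# Shared helpers: tiny deterministic parameter constructions used across
# the suite. Everything is built in code; no stored fixtures.

# one indication with round numbers, medians in weeks
simple_indication <- function(name = "alpha",
                              weight = 1,
                              median_os_tx = 104, median_pfs_tx = 52,
                              median_os_soc = 52, median_pfs_soc = 26,
                              median_ttd = 30,
                              ntrk_prevalence = 0.01,
                              trial_n = 20, ...) {
  defaults <- list(
    name = name, prevalence_weight = weight,
    ntrk_prevalence = ntrk_prevalence, trial_n = trial_n,
    median_os_tx = median_os_tx, median_pfs_tx = median_pfs_tx,
    median_os_soc = median_os_soc, median_pfs_soc = median_pfs_soc,
    median_ttd = median_ttd,
    cost_pf_care = 100, cost_pd_care = 300,
    cost_ae_tx = 1000, cost_ae_soc = 800,
    cost_drug_tx_cycle = 1500, cost_admin_tx_cycle = 50,
    cost_drug_soc_cycle = 400, cost_ngs_panel = 2000)
  args <- utils::modifyList(defaults, list(...))
  do.call(indication_params, args)
}

# small fast globals: two-year horizon keeps engine loops cheap
fast_globals <- function(...) {
  global_params(horizon = 2 * 365.25 / 7, n_psa = 20, seed = 42, ...)
}

simple_set <- function(n = 2, globals = fast_globals()) {
  inds <- lapply(seq_len(n), function(k) {
    simple_indication(name = paste0("ind", k), weight = 1 / n,
                      median_os_tx = 60 + 10 * k,
                      median_pfs_tx = 30 + 5 * k,
                      median_os_soc = 40 + 5 * k,
                      median_pfs_soc = 20 + 2 * k)
  })
  parameter_set(inds, globals)
}

# collapse every distribution of a set to fixed (degenerate PSA)
all_fixed <- function(p) {
  p$distributions <- lapply(p$distributions,
                            function(s) distribution_spec("fixed"))
  p
}

# hand-built psa_result for metric tests
fake_psa_result <- function(delta_cost, delta_qaly, tag = "fake") {
  structure(list(
    n_iter = length(delta_cost),
    indications = character(0),
    weights = numeric(0),
    per_indication = list(),
    aggregated = list(delta_cost = delta_cost, delta_qaly = delta_qaly),
    seed = 1L, scenario_tag = tag), class = "psa_result")
}

# independent lower-left hull oracle (Andrew's monotone chain on the
# (qaly, cost) cloud, then trimmed to start at the cheapest vertex)
oracle_frontier <- function(q, c) {
  o <- order(q, c)
  q <- q[o]; c <- c[o]
  keep <- !duplicated(data.frame(q, c))
  q <- q[keep]; c <- c[keep]; idx <- o[keep]
  hull <- integer(0)
  cross <- function(i, j, k) {
    (q[j] - q[i]) * (c[k] - c[i]) - (c[j] - c[i]) * (q[k] - q[i])
  }
  for (k in seq_along(q)) {
    while (length(hull) >= 2 &&
           cross(hull[length(hull) - 1], hull[length(hull)], k) <= 0) {
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, k)
  }
  # frontier starts at the globally cheapest hull vertex: anything before
  # it costs more for less effect
  start <- which.min(c[hull])
  hull <- hull[start:length(hull)]
  cbind(delta_qaly = q[hull], delta_cost = c[hull])
}
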
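# Random valid parameter sets for testing and simulation studies.

#' Generate a random valid parameter set
#'
#' Draws a parameter set satisfying every load-time invariant by
#' construction: medians are positive with PFS at most OS within each arm,
#' costs non-negative, prevalence weights on the simplex. Magnitudes mimic
#' an advanced-cancer evaluation (OS medians of months to a few years, drug
#' costs of hundreds to thousands per weekly cycle). Identical seeds yield
#' identical sets.
#'
#' @param seed integer seed.
#' @param n_indications number of indications (>= 1).
#' @param globals optional [global_params()] to attach; defaults mirror the
#'   base-case configuration.
#' @return a validated `parameter_set`.
#' @export
#' @examples
#' p <- generate_fixture(seed = 7, n_indications = 3)
#' sum(sapply(p$indications, function(i) i$prevalence_weight))  # 1
generate_fixture <- function(seed, n_indications, globals = NULL) {
  stopifnot(n_indications >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  w <- stats::rgamma(n_indications, shape = 2)
  w <- w / sum(w)
  inds <- vector("list", n_indications)
  for (k in seq_len(n_indications)) {
    # comparator OS median 6-36 months; intervention typically better
    os_soc <- stats::runif(1, 26, 156)
    os_tx <- os_soc * stats::runif(1, 0.8, 2.5)
    pfs_soc <- os_soc * stats::runif(1, 0.3, 0.9)
    pfs_tx <- os_tx * stats::runif(1, 0.3, 0.9)
    inds[[k]] <- indication_params(
      name = sprintf("ind%02d", k),
      prevalence_weight = w[k],
      ntrk_prevalence = stats::runif(1, 0.001, 0.95),
      trial_n = stats::rpois(1, 12),
      median_os_tx = os_tx, median_pfs_tx = pfs_tx,
      median_os_soc = os_soc, median_pfs_soc = pfs_soc,
      median_ttd = pfs_tx * stats::runif(1, 0.5, 1.2),
      cost_pf_care = stats::runif(1, 50, 400),
      cost_pd_care = stats::runif(1, 200, 900),
      cost_ae_tx = stats::runif(1, 0, 5000),
      cost_ae_soc = stats::runif(1, 0, 5000),
      cost_drug_tx_cycle = stats::runif(1, 500, 3000),
      cost_admin_tx_cycle = stats::runif(1, 0, 200),
      cost_drug_soc_cycle = stats::runif(1, 100, 1500),
      cost_ngs_panel = stats::runif(1, 500, 4000)
    )
  }
  g <- if (is.null(globals)) {
    global_params(seed = as.integer(seed), n_psa = 100)
  } else globals
  parameter_set(inds, g)
}
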
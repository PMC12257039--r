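# Parameter model: indication-level and global inputs, PSA distribution
# specs, validation with clamp-and-warn semantics, and file round-trip.

IND_FIELDS <- c(
  "name", "prevalence_weight", "ntrk_prevalence", "trial_n",
  "median_os_tx", "median_pfs_tx", "median_os_soc", "median_pfs_soc",
  "median_ttd",
  "cost_pf_care", "cost_pd_care", "cost_ae_tx", "cost_ae_soc",
  "cost_drug_tx_cycle", "cost_admin_tx_cycle", "cost_drug_soc_cycle",
  "cost_ngs_panel"
)

IND_MEDIAN_FIELDS <- c("median_os_tx", "median_pfs_tx", "median_os_soc",
                       "median_pfs_soc", "median_ttd")
IND_COST_FIELDS <- c("cost_pf_care", "cost_pd_care", "cost_ae_tx",
                     "cost_ae_soc", "cost_drug_tx_cycle",
                     "cost_admin_tx_cycle", "cost_drug_soc_cycle",
                     "cost_ngs_panel")

#' Per-indication model parameters
#'
#' Bundles everything the engine needs for one tumor indication: basket-trial
#' survival medians for the intervention arm, comparator medians constructed
#' from averaged published medians, time to treatment discontinuation (the
#' cutoff for drug-acquisition costs), per-cycle and one-off costs, the
#' indication's share of the biomarker-positive advanced-cancer population
#' (its prevalence weight), the per-tumor biomarker (NTRK fusion) prevalence
#' used for number-needed-to-screen testing costs, and the trial sample size
#' driving the small-sample rule.
#'
#' All durations are in weeks; all money in the computation currency
#' (2021 CAD for the packaged defaults); per-cycle costs are per weekly cycle.
#'
#' @param name indication label (unique within a parameter set).
#' @param prevalence_weight fraction of the biomarker-positive population.
#' @param ntrk_prevalence per-tumor gene-fusion prevalence, in (0, 1].
#' @param trial_n basket-trial patient count (drives the small-sample rule).
#' @param median_os_tx,median_pfs_tx intervention-arm medians, weeks.
#' @param median_os_soc,median_pfs_soc comparator-arm medians, weeks.
#' @param median_ttd median time to treatment discontinuation, weeks.
#' @param cost_pf_care,cost_pd_care state care costs per cycle.
#' @param cost_ae_tx,cost_ae_soc one-off adverse-event costs per arm.
#' @param cost_drug_tx_cycle,cost_admin_tx_cycle intervention drug and
#'   administration costs per cycle while on treatment.
#' @param cost_drug_soc_cycle comparator drug cost per cycle while
#'   progression free.
#' @param cost_ngs_panel sequencing panel cost per test.
#' @return an object of class `indication_params`.
#' @export
indication_params <- function(name,
                              prevalence_weight,
                              ntrk_prevalence,
                              trial_n,
                              median_os_tx, median_pfs_tx,
                              median_os_soc, median_pfs_soc,
                              median_ttd,
                              cost_pf_care, cost_pd_care,
                              cost_ae_tx, cost_ae_soc,
                              cost_drug_tx_cycle, cost_admin_tx_cycle,
                              cost_drug_soc_cycle,
                              cost_ngs_panel) {
  ind <- list(
    name = as.character(name),
    prevalence_weight = as.numeric(prevalence_weight),
    ntrk_prevalence = as.numeric(ntrk_prevalence),
    trial_n = as.integer(trial_n),
    median_os_tx = as.numeric(median_os_tx),
    median_pfs_tx = as.numeric(median_pfs_tx),
    median_os_soc = as.numeric(median_os_soc),
    median_pfs_soc = as.numeric(median_pfs_soc),
    median_ttd = as.numeric(median_ttd),
    cost_pf_care = as.numeric(cost_pf_care),
    cost_pd_care = as.numeric(cost_pd_care),
    cost_ae_tx = as.numeric(cost_ae_tx),
    cost_ae_soc = as.numeric(cost_ae_soc),
    cost_drug_tx_cycle = as.numeric(cost_drug_tx_cycle),
    cost_admin_tx_cycle = as.numeric(cost_admin_tx_cycle),
    cost_drug_soc_cycle = as.numeric(cost_drug_soc_cycle),
    cost_ngs_panel = as.numeric(cost_ngs_panel)
  )
  structure(ind, class = "indication_params")
}

#' Global (tumor-agnostic) model parameters
#'
#' Health-state utilities are tumor agnostic and identical between arms;
#' progression-free utility must be at least the progressed-state utility.
#' Discounting applies the same annual rate to costs and QALYs. The
#' intervention's effectiveness can be restricted (treatment waning): beyond
#' `restriction_time` its hazard reverts to the comparator hazard.
#'
#' @param utility_pf,utility_pd health-state utilities in `[0, 1]`.
#' @param discount_rate annual discount rate (default 0.015).
#' @param cycle_length cycle length in weeks (default 1).
#' @param horizon model horizon in weeks (default 10 years).
#' @param wtp_thresholds willingness-to-pay thresholds, money per QALY.
#' @param exchange_rate CAD per USD used only at output time.
#' @param restriction_time week at which the intervention hazard reverts to
#'   the comparator hazard under the restricted extrapolation policy.
#' @param n_psa number of probabilistic iterations (default 1000).
#' @param seed master seed for the probabilistic analysis.
#' @param half_cycle_correction logical; trapezoid cycle weights instead of
#'   start-of-cycle rectangles.
#' @param drug_cost_pf_weighted logical; weight on-treatment drug costs by
#'   progression-free occupancy (default) or charge them unweighted.
#' @param nns_round_up logical; round the number needed to screen up to a
#'   whole count instead of cohort-average (real-valued) costing.
#' @return an object of class `global_params`.
#' @export
global_params <- function(utility_pf = 0.75,
                          utility_pd = 0.55,
                          discount_rate = 0.015,
                          cycle_length = 1,
                          horizon = 10 * WEEKS_PER_YEAR,
                          wtp_thresholds = c(50000, 100000),
                          exchange_rate = 1.25349,
                          restriction_time = 130,
                          n_psa = 1000,
                          seed = 20210101,
                          half_cycle_correction = FALSE,
                          drug_cost_pf_weighted = TRUE,
                          nns_round_up = FALSE) {
  g <- list(
    utility_pf = as.numeric(utility_pf),
    utility_pd = as.numeric(utility_pd),
    discount_rate = as.numeric(discount_rate),
    cycle_length = as.numeric(cycle_length),
    horizon = as.numeric(horizon),
    wtp_thresholds = as.numeric(wtp_thresholds),
    exchange_rate = as.numeric(exchange_rate),
    restriction_time = as.numeric(restriction_time),
    n_psa = as.integer(n_psa),
    seed = as.integer(seed),
    half_cycle_correction = isTRUE(half_cycle_correction),
    drug_cost_pf_weighted = isTRUE(drug_cost_pf_weighted),
    nns_round_up = isTRUE(nns_round_up)
  )
  structure(g, class = "global_params")
}

#' PSA distribution specification for one stochastic parameter
#'
#' Families follow standard health-economics practice: gamma for costs,
#' beta for utilities, lognormal for survival medians, normal for
#' unconstrained quantities, dirichlet for a weight simplex, and `fixed`
#' for parameters excluded from the probabilistic analysis. Moment-matched
#' forms are accepted: gamma and lognormal take either natural parameters
#' (`shape`/`rate`, `meanlog`/`sdlog`) or `mean` + `cv`; beta takes
#' `shape1`/`shape2` or `mean` + `sd`.
#'
#' @param family one of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"normal"`, `"dirichlet"`.
#' @param params named list of family parameters (ignored for `fixed`).
#' @param source_tag provenance label, e.g. `"CDA-AMC"`, `"NICE"`,
#'   `"assumed"`.
#' @return an object of class `distribution_spec`.
#' @export
distribution_spec <- function(family,
                              params = list(),
                              source_tag = "assumed") {
  family <- match.arg(family, c("fixed", "beta", "gamma", "lognormal",
                                "normal", "dirichlet"))
  spec <- structure(list(family = family, params = params,
                         source_tag = source_tag),
                    class = "distribution_spec")
  validate_distribution_spec(spec)
  spec
}

validate_distribution_spec <- function(spec) {
  p <- spec$params
  ok <- switch(spec$family,
    fixed = TRUE,
    beta = {
      if (!is.null(p$shape1)) p$shape1 > 0 && p$shape2 > 0
      else !is.null(p$mean) && !is.null(p$sd) &&
        p$mean > 0 && p$mean < 1 && p$sd > 0 &&
        p$sd^2 < p$mean * (1 - p$mean)
    },
    gamma = {
      if (!is.null(p$shape)) p$shape > 0 && p$rate > 0
      else !is.null(p$mean) && !is.null(p$cv) && p$mean > 0 && p$cv > 0
    },
    lognormal = {
      if (!is.null(p$meanlog)) is.finite(p$meanlog) && p$sdlog > 0
      else !is.null(p$mean) && !is.null(p$cv) && p$mean > 0 && p$cv > 0
    },
    normal = !is.null(p$mean) && !is.null(p$sd) && p$sd >= 0,
    dirichlet = !is.null(p$alpha) && all(p$alpha > 0)
  )
  if (!isTRUE(ok)) {
    stop("invalid parameters for distribution family '", spec$family, "'",
         call. = FALSE)
  }
  invisible(spec)
}

#' Assemble a validated parameter set
#'
#' @param indications list of [indication_params()] objects.
#' @param globals a [global_params()] object.
#' @param distributions named list of [distribution_spec()] objects keyed
#'   `"<indication>.<field>"` or `"global.<field>"`. When `NULL`, default
#'   assumed distributions are attached (see [default_distributions()]).
#' @return an object of class `parameter_set` with all invariants enforced;
#'   median-ordering violations are clamped with a warning and recorded in
#'   the `clamp_log` attribute.
#' @export
parameter_set <- function(indications, globals, distributions = NULL) {
  p <- structure(list(indications = indications, globals = globals,
                      distributions = distributions),
                 class = "parameter_set")
  names(p$indications) <- vapply(indications, function(i) i$name, character(1))
  p <- validate_parameter_set(p)
  if (is.null(p$distributions)) {
    # defaults are moment-matched to the validated (clamped) point values
    p$distributions <- default_distributions(p)
  }
  p
}

#' Validate a parameter set, clamping where permitted
#'
#' Hard violations (negative costs, weights not summing to one, utilities
#' out of order, non-positive medians) raise a validation error naming the
#' offending field. A progression-free median exceeding the same arm's
#' overall-survival median is clamped to the OS median with a warning; the
#' events are recorded in the returned object's `clamp_log` attribute.
#'
#' @param p a `parameter_set`.
#' @return the validated (possibly clamped) `parameter_set`.
#' @export
validate_parameter_set <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  g <- p$globals
  if (!(g$utility_pd >= 0 && g$utility_pf >= g$utility_pd &&
        g$utility_pf <= 1)) {
    stop("validation error: utilities must satisfy 0 <= utility_pd <= ",
         "utility_pf <= 1", call. = FALSE)
  }
  if (g$discount_rate < 0) {
    stop("validation error: discount_rate must be >= 0", call. = FALSE)
  }
  if (!(g$horizon > g$cycle_length)) {
    stop("validation error: horizon must exceed cycle_length", call. = FALSE)
  }
  if (g$n_psa < 1) stop("validation error: n_psa must be >= 1", call. = FALSE)

  nm <- vapply(p$indications, function(i) i$name, character(1))
  if (anyDuplicated(nm)) {
    stop("validation error: indication names must be unique", call. = FALSE)
  }
  w <- vapply(p$indications, function(i) i$prevalence_weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop("validation error: prevalence_weight values sum to ",
         format(sum(w), digits = 12), ", not 1", call. = FALSE)
  }

  clamp_log <- character(0)
  for (k in seq_along(p$indications)) {
    ind <- p$indications[[k]]
    for (f in IND_MEDIAN_FIELDS) {
      if (!is.finite(ind[[f]]) || ind[[f]] <= 0) {
        stop("validation error: ", ind$name, "$", f, " must be > 0",
             call. = FALSE)
      }
    }
    for (f in IND_COST_FIELDS) {
      if (!is.finite(ind[[f]]) || ind[[f]] < 0) {
        stop("validation error: ", ind$name, "$", f, " must be >= 0",
             call. = FALSE)
      }
    }
    if (!(ind$ntrk_prevalence > 0 && ind$ntrk_prevalence <= 1)) {
      stop("validation error: ", ind$name,
           "$ntrk_prevalence must be in (0, 1]", call. = FALSE)
    }
    if (ind$trial_n < 0) {
      stop("validation error: ", ind$name, "$trial_n must be >= 0",
           call. = FALSE)
    }
    for (arm in c("tx", "soc")) {
      pfs_f <- paste0("median_pfs_", arm)
      os_f <- paste0("median_os_", arm)
      if (ind[[pfs_f]] > ind[[os_f]]) {
        clamp_log <- c(clamp_log, sprintf(
          "%s: %s (%g) exceeded %s (%g); clamped to the OS median",
          ind$name, pfs_f, ind[[pfs_f]], os_f, ind[[os_f]]))
        ind[[pfs_f]] <- ind[[os_f]]
      }
    }
    p$indications[[k]] <- ind
  }
  if (length(clamp_log)) {
    warning("median ordering clamped: ",
            paste(clamp_log, collapse = "; "), call. = FALSE)
  }

  if (!is.null(p$distributions)) {
    known <- c(paste0("global.", setdiff(names(p$globals), "wtp_thresholds")),
               "global.prevalence_weights",
               unlist(lapply(nm, function(n) {
                 paste0(n, ".", setdiff(IND_FIELDS, "name"))
               })))
    bad <- setdiff(names(p$distributions), known)
    if (length(bad)) {
      stop("validation error: distributions name unknown parameters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (s in p$distributions) validate_distribution_spec(s)
  }
  attr(p, "clamp_log") <- clamp_log
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter_set:", length(x$indications), "indications\n")
  df <- parameter_set_to_df(x)
  print(df[, c("name", "prevalence_weight", "trial_n",
               "median_os_tx", "median_os_soc")], ...)
  cat(sprintf("globals: u_pf=%.3g u_pd=%.3g rate=%.3g horizon=%.4g wk, %d PSA iterations\n",
              x$globals$utility_pf, x$globals$utility_pd,
              x$globals$discount_rate, x$globals$horizon, x$globals$n_psa))
  invisible(x)
}

parameter_set_to_df <- function(p) {
  df <- do.call(rbind, lapply(p$indications, function(i) {
    as.data.frame(unclass(i)[IND_FIELDS], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Flag indications under the small-sample rule
#'
#' Tumor types with five or fewer basket-trial patients contribute only the
#' incremental costs of treatment and no incremental QALYs: downstream, the
#' incremental QALYs of a flagged indication are forced to zero and its
#' incremental costs reduce to the intervention arm's treatment-cost
#' components.
#'
#' @param p a `parameter_set`.
#' @param threshold largest trial size still flagged (default 5).
#' @return `p` with a logical `small_sample` element on each indication.
#' @export
apply_small_sample_rule <- function(p, threshold = 5) {
  stopifnot(inherits(p, "parameter_set"))
  p$indications <- lapply(p$indications, function(ind) {
    ind$small_sample <- ind$trial_n <= threshold
    ind
  })
  p
}

small_sample_flags <- function(p) {
  vapply(p$indications, function(i) isTRUE(i$small_sample), logical(1))
}

#' Restrict a parameter set to a subset of indications
#'
#' Prevalence weights are renormalized over the retained indications so the
#' subset again describes a whole population (the frontier module, by
#' contrast, keeps original weights and zeroes unfunded increments).
#'
#' @param p a `parameter_set`.
#' @param names indication names to keep.
#' @param renormalize renormalize prevalence weights (default `TRUE`).
#' @return a `parameter_set` over the subset.
#' @export
select_indications <- function(p, names, renormalize = TRUE) {
  stopifnot(all(names %in% names(p$indications)))
  inds <- p$indications[names]
  if (renormalize) {
    w <- vapply(inds, function(i) i$prevalence_weight, numeric(1))
    inds <- Map(function(i, wi) { i$prevalence_weight <- wi; i },
                inds, w / sum(w))
  }
  dists <- NULL
  if (!is.null(p$distributions)) {
    keep <- vapply(strsplit(names(p$distributions), ".", fixed = TRUE),
                   function(x) x[1] %in% c("global", names), logical(1))
    dists <- p$distributions[keep]
  }
  parameter_set(inds, p$globals, dists)
}

#' Derive "other"-indication care costs from the named indications
#'
#' The pooled low-prevalence indication inherits care costs equal to the
#' prevalence-weighted average of the remaining indications' care costs.
#'
#' @param p a `parameter_set`.
#' @param other name of the pooled indication (default `"other"`).
#' @return `p` with the pooled indication's `cost_pf_care` and
#'   `cost_pd_care` replaced by weighted averages.
#' @export
derive_other_care_costs <- function(p, other = "other") {
  stopifnot(other %in% names(p$indications))
  rest <- p$indications[setdiff(names(p$indications), other)]
  w <- vapply(rest, function(i) i$prevalence_weight, numeric(1))
  w <- w / sum(w)
  for (f in c("cost_pf_care", "cost_pd_care")) {
    p$indications[[other]][[f]] <-
      sum(w * vapply(rest, function(i) i[[f]], numeric(1)))
  }
  p$indications[[other]]$care_costs_derived <- TRUE
  p
}

# ---- default assumed distributions -----------------------------------------

#' Default assumed PSA distributions for a parameter set
#'
#' Where source HTA documents do not report distributions, standard
#' assumptions are attached: gamma for costs (moment-matched to the point
#' value with a 20 percent coefficient of variation), lognormal for survival
#' medians (same moment matching), and beta for the two utilities
#' (moment-matched with standard deviation 0.05 around the point value).
#' Structural quantities (weights, biomarker prevalence, trial sizes,
#' discount rate, horizon) are `fixed`.
#'
#' @param p a `parameter_set` (distributions ignored).
#' @param cv_cost,cv_median coefficients of variation for cost and median
#'   distributions.
#' @param sd_utility standard deviation for the beta utility distributions.
#' @return named list of [distribution_spec()] objects.
#' @export
default_distributions <- function(p, cv_cost = 0.2, cv_median = 0.2,
                                  sd_utility = 0.05) {
  specs <- list()
  beta_or_fixed <- function(m) {
    if (m > 0 && m < 1 && sd_utility^2 < m * (1 - m)) {
      distribution_spec("beta", list(mean = m, sd = sd_utility))
    } else {
      distribution_spec("fixed")
    }
  }
  specs[["global.utility_pf"]] <- beta_or_fixed(p$globals$utility_pf)
  specs[["global.utility_pd"]] <- beta_or_fixed(p$globals$utility_pd)
  for (ind in p$indications) {
    for (f in IND_MEDIAN_FIELDS) {
      specs[[paste0(ind$name, ".", f)]] <-
        distribution_spec("lognormal", list(mean = ind[[f]], cv = cv_median))
    }
    for (f in IND_COST_FIELDS) {
      specs[[paste0(ind$name, ".", f)]] <- if (ind[[f]] > 0) {
        distribution_spec("gamma", list(mean = ind[[f]], cv = cv_cost))
      } else {
        distribution_spec("fixed")
      }
    }
  }
  specs
}

# ---- file I/O ---------------------------------------------------------------

spec_to_plain <- function(s) {
  list(family = s$family, params = s$params, source_tag = s$source_tag)
}

plain_to_spec <- function(x) {
  distribution_spec(x$family, if (is.null(x$params)) list() else x$params,
                    if (is.null(x$source_tag)) "assumed" else x$source_tag)
}

#' Load a parameter set from YAML, JSON or CSV
#'
#' YAML/JSON files carry `indications` (list of field maps), `globals`, and
#' an optional `distributions` block; a missing block receives the default
#' assumed distributions. An optional top-level `time_unit: months` converts
#' all medians on input (internal unit is weeks). CSV files carry one row
#' per indication with columns named as the indication fields; globals then
#' take their defaults unless supplied via `globals`.
#'
#' @param path file path.
#' @param format `"yaml"`, `"json"` or `"csv"`; default inferred from the
#'   file extension.
#' @param globals optional [global_params()] override (CSV input, or to
#'   replace the file's globals).
#' @return a validated `parameter_set`.
#' @export
load_parameter_set <- function(path, format = c("auto", "yaml", "json", "csv"),
                               globals = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     yml = , yaml = "yaml", json = "json", csv = "csv",
                     stop("cannot infer format from extension of '",
                          path, "'", call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(IND_FIELDS, names(df))
    if (length(missing_cols)) {
      stop("format error: CSV is missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    inds <- lapply(seq_len(nrow(df)), function(r) {
      do.call(indication_params, as.list(df[r, IND_FIELDS]))
    })
    return(parameter_set(inds, if (is.null(globals)) global_params()
                         else globals))
  }

  raw <- tryCatch(
    if (format == "yaml") yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE),
    error = function(e) stop("format error parsing '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(raw$indications)) {
    stop("format error: no 'indications' block in '", path, "'",
         call. = FALSE)
  }

  to_weeks <- identical(raw$time_unit, "months")
  inds <- lapply(raw$indications, function(x) {
    x <- x[intersect(names(x), IND_FIELDS)]
    missing_f <- setdiff(IND_FIELDS, names(x))
    if (length(missing_f)) {
      stop("format error: indication '", x$name %||% "?",
           "' is missing fields: ", paste(missing_f, collapse = ", "),
           call. = FALSE)
    }
    if (to_weeks) {
      for (f in IND_MEDIAN_FIELDS) x[[f]] <- months_to_weeks(x[[f]])
    }
    do.call(indication_params, x)
  })

  g <- if (!is.null(globals)) globals else if (!is.null(raw$globals)) {
    do.call(global_params, raw$globals)
  } else global_params()

  dists <- NULL
  if (!is.null(raw$distributions)) {
    dists <- lapply(raw$distributions, plain_to_spec)
  }
  p <- parameter_set(inds, g, dists)
  if (isTRUE(raw$derive_other_care_costs) && "other" %in% names(p$indications)) {
    p <- derive_other_care_costs(p)
  }
  p
}

#' Save a parameter set to YAML or JSON
#'
#' Writes a file that [load_parameter_set()] reproduces field-for-field
#' (durations in weeks).
#'
#' @param p a `parameter_set`.
#' @param path output path.
#' @param format `"yaml"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(p, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     yml = , yaml = "yaml", json = "json",
                     stop("cannot infer format from extension", call. = FALSE))
  }
  out <- list(
    time_unit = "weeks",
    indications = lapply(unname(p$indications), function(i) {
      unclass(i)[IND_FIELDS]
    }),
    globals = unclass(p$globals),
    distributions = lapply(p$distributions, spec_to_plain)
  )
  if (format == "yaml") {
    yaml::write_yaml(out, path, precision = 15)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Path to the packaged synthetic default parameter file
#'
#' The packaged file describes nine tumor indications (breast, colorectal,
#' NSCLC, pancreatic, thyroid, sarcoma, neuroendocrine, MASC, other) with
#' 121 basket-trial patients in total. Its values are a synthetic,
#' plausibility-checked stand-in constructed from the published study
#' design — the primary-source input tables are not redistributed here —
#' so absolute results from it illustrate the machinery rather than
#' reproduce any published estimate.
#'
#' @return path to `entrectinib_synthetic.yaml` inside the installed package.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "entrectinib_synthetic.yaml", package = "partsaHTA",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
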
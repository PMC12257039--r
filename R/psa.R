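# Probabilistic sensitivity analysis: joint sampling of all stochastic
# parameters and propagation through the deterministic engine.

draw_spec <- function(spec, point) {
  p <- spec$params
  switch(spec$family,
    fixed = point,
    beta = {
      if (is.null(p$shape1)) {
        v <- p$mean * (1 - p$mean) / p$sd^2 - 1
        p$shape1 <- p$mean * v
        p$shape2 <- (1 - p$mean) * v
      }
      stats::rbeta(1, p$shape1, p$shape2)
    },
    gamma = {
      if (is.null(p$shape)) {
        p$shape <- 1 / p$cv^2
        p$rate <- 1 / (p$mean * p$cv^2)
      }
      stats::rgamma(1, shape = p$shape, rate = p$rate)
    },
    lognormal = {
      if (is.null(p$meanlog)) {
        p$sdlog <- sqrt(log(1 + p$cv^2))
        p$meanlog <- log(p$mean) - p$sdlog^2 / 2
      }
      stats::rlnorm(1, p$meanlog, p$sdlog)
    },
    normal = stats::rnorm(1, p$mean, p$sd),
    stop("dirichlet specs are drawn jointly, not per scalar", call. = FALSE)
  )
}

field_valid <- function(field, value) {
  if (!is.finite(value)) return(FALSE)
  if (field %in% IND_MEDIAN_FIELDS) return(value > 0)
  if (field %in% IND_COST_FIELDS) return(value >= 0)
  if (field %in% c("utility_pf", "utility_pd")) {
    return(value >= 0 && value <= 1)
  }
  if (field == "ntrk_prevalence") return(value > 0 && value <= 1)
  TRUE
}

draw_valid <- function(spec, point, field, max_redraws = 100) {
  for (k in seq_len(max_redraws + 1)) {
    v <- draw_spec(spec, point)
    if (field_valid(field, v)) {
      if (k > 1) attr(v, "redraws") <- k - 1
      return(v)
    }
  }
  stop("sampling error: >", max_redraws,
       " consecutive invalid draws for ", field, call. = FALSE)
}

#' Sample one realization of all stochastic parameters
#'
#' All parameters are drawn simultaneously from the attached distribution
#' specs using the current RNG state. Tumor-agnostic parameters (the two
#' utilities) are drawn once and shared across indications; `fixed`
#' parameters pass through unchanged. Invalid draws (for instance a
#' non-positive median from a normal spec) are redrawn, with an error after
#' 100 consecutive failures. Utilities are re-ordered-safe: a draw with
#' `utility_pd > utility_pf` is redrawn jointly. Median-ordering violations
#' (PFS > OS) are clamped as at load time, silently counted in the
#' `clamp_log` attribute.
#'
#' @param p a `parameter_set` with a `distributions` mapping.
#' @return a realized `parameter_set` with all distributions collapsed to
#'   `fixed`.
#' @export
sample_parameters <- function(p) {
  stopifnot(inherits(p, "parameter_set"), !is.null(p$distributions))
  specs <- p$distributions
  q <- p

  # tumor-agnostic draws, shared across indications; redraw jointly if the
  # utility ordering is violated
  for (k in seq_len(101)) {
    for (f in c("utility_pf", "utility_pd")) {
      key <- paste0("global.", f)
      if (!is.null(specs[[key]])) {
        q$globals[[f]] <- as.numeric(
          draw_valid(specs[[key]], p$globals[[f]], f))
      }
    }
    if (q$globals$utility_pd <= q$globals$utility_pf) break
    if (k > 100) stop("sampling error: utility ordering unresolved",
                      call. = FALSE)
  }

  # optional joint dirichlet over prevalence weights
  dw <- specs[["global.prevalence_weights"]]
  if (!is.null(dw) && dw$family == "dirichlet") {
    a <- dw$params$alpha
    stopifnot(length(a) == length(q$indications))
    g <- stats::rgamma(length(a), shape = a)
    w <- g / sum(g)
    for (i in seq_along(q$indications)) {
      q$indications[[i]]$prevalence_weight <- w[i]
    }
  }

  for (i in seq_along(q$indications)) {
    ind <- q$indications[[i]]
    for (f in setdiff(IND_FIELDS, "name")) {
      key <- paste0(ind$name, ".", f)
      if (!is.null(specs[[key]]) && specs[[key]]$family != "fixed") {
        ind[[f]] <- as.numeric(draw_valid(specs[[key]], ind[[f]], f))
      }
    }
    q$indications[[i]] <- ind
  }

  # clamp PFS <= OS quietly (PSA draws cross the boundary routinely)
  clamp_n <- 0L
  for (i in seq_along(q$indications)) {
    for (arm in c("tx", "soc")) {
      pfs_f <- paste0("median_pfs_", arm)
      os_f <- paste0("median_os_", arm)
      if (q$indications[[i]][[pfs_f]] > q$indications[[i]][[os_f]]) {
        q$indications[[i]][[pfs_f]] <- q$indications[[i]][[os_f]]
        clamp_n <- clamp_n + 1L
      }
    }
  }
  q$distributions <- lapply(specs, function(s) distribution_spec("fixed"))
  attr(q, "clamp_log") <- clamp_n
  q
}

iteration_seed <- function(master_seed, iter) {
  # one reproducible stream per iteration, kept inside 32-bit range
  as.integer((as.numeric(master_seed) * 69069 + iter * 101) %% 2147483647L)
}

#' Run the probabilistic sensitivity analysis
#'
#' Each iteration seeds its own RNG stream derived from the master seed and
#' the iteration index (replayable and order-independent), samples all
#' parameters simultaneously, runs the deterministic engine for every
#' indication, applies the small-sample rule, and aggregates tumor-agnostic
#' outcomes as the prevalence-weighted sum of per-indication incremental
#' outcomes.
#'
#' @param p a `parameter_set`.
#' @param scenario a [scenario_spec()].
#' @param n_psa number of iterations (default `p$globals$n_psa`).
#' @param seed master seed (default `p$globals$seed`).
#' @return an object of class `psa_result` with per-indication and
#'   aggregated `delta_cost`/`delta_qaly` vectors of length `n_psa`.
#' @export
run_psa <- function(p, scenario = scenario_spec(),
                    n_psa = NULL, seed = NULL) {
  stopifnot(inherits(p, "parameter_set"))
  n_psa <- as.integer(n_psa %||% p$globals$n_psa)
  seed <- as.integer(seed %||% p$globals$seed)
  stopifnot(n_psa >= 1)
  p <- apply_small_sample_rule(p)
  nm <- names(p$indications)
  w <- vapply(p$indications, function(i) i$prevalence_weight, numeric(1))

  dc <- matrix(NA_real_, n_psa, length(nm), dimnames = list(NULL, nm))
  dq <- dc
  for (it in seq_len(n_psa)) {
    set.seed(iteration_seed(seed, it))
    real <- tryCatch(sample_parameters(p),
                     error = function(e) {
                       stop("PSA iteration ", it, ": ",
                            conditionMessage(e), call. = FALSE)
                     })
    real <- apply_small_sample_rule(real)
    for (j in seq_along(nm)) {
      d <- run_indication(real$indications[[j]], real$globals, scenario)
      dc[it, j] <- d[["delta_cost"]]
      dq[it, j] <- d[["delta_qaly"]]
    }
  }
  structure(list(
    n_iter = n_psa,
    indications = nm,
    weights = w,
    per_indication = lapply(stats::setNames(nm, nm), function(n) {
      list(delta_cost = dc[, n], delta_qaly = dq[, n])
    }),
    aggregated = list(delta_cost = apply(dc, 1, function(r) sum(w * r)),
                      delta_qaly = apply(dq, 1, function(r) sum(w * r))),
    seed = seed,
    scenario_tag = scenario$label
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("psa_result '%s': %d iterations, %d indications (seed %d)\n",
              x$scenario_tag, x$n_iter, length(x$indications), x$seed))
  cat(sprintf("aggregated mean delta_cost %.2f, mean delta_qaly %.5f\n",
              mean(x$aggregated$delta_cost), mean(x$aggregated$delta_qaly)))
  invisible(x)
}

#' Extract the (delta_cost, delta_qaly) draws at a level
#'
#' @param result a `psa_result`.
#' @param level `"agnostic"` or an indication name.
#' @return list with `delta_cost` and `delta_qaly` vectors.
#' @export
psa_draws <- function(result, level = "agnostic") {
  if (identical(level, "agnostic")) return(result$aggregated)
  if (!level %in% result$indications) {
    stop("unknown level '", level, "'", call. = FALSE)
  }
  result$per_indication[[level]]
}

#' Export PSA draws as long-format CSV with a JSON manifest
#'
#' @param result a `psa_result`.
#' @param path CSV output path; the manifest is written next to it with a
#'   `.manifest.json` suffix.
#' @return `path`, invisibly.
#' @export
export_psa_csv <- function(result, path) {
  long <- do.call(rbind, lapply(c(result$indications, "agnostic"),
    function(n) {
      d <- psa_draws(result, if (n == "agnostic") "agnostic" else n)
      data.frame(iteration = seq_len(result$n_iter), indication = n,
                 delta_cost = d$delta_cost, delta_qaly = d$delta_qaly)
    }))
  utils::write.csv(long, path, row.names = FALSE)
  manifest <- list(seed = result$seed, n_iter = result$n_iter,
                   scenario = result$scenario_tag,
                   package_version =
                     as.character(utils::packageVersion("partsaHTA")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
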
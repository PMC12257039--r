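# Deterministic cost-effectiveness frontier over every combination of
# funded tumor indications, with strict and extended dominance.

#' Enumerate funding strategies over indication combinations
#'
#' Every subset of tumor indications is a strategy: funded indications
#' contribute their prevalence-weighted deterministic incremental outcomes
#' (weight `w_i` times per-patient increments), unfunded indications
#' contribute zero. The empty subset is the do-nothing strategy at (0, 0).
#' Weights are not renormalized here — strategies describe the same whole
#' population.
#'
#' @param p a `parameter_set` (at most 20 indications).
#' @param scenario a [scenario_spec()].
#' @return data frame of class `strategy_table` with columns `strategy`
#'   (comma-joined sorted indication names, `"(none)"` for the empty set),
#'   `delta_qaly`, `delta_cost`.
#' @export
enumerate_strategies <- function(p, scenario = scenario_spec()) {
  n <- length(p$indications)
  if (n > 20) {
    stop("more than 20 indications: 2^n enumeration refused ",
         "(a greedy mode is out of scope)", call. = FALSE)
  }
  det <- run_deterministic(p, scenario)$per_indication
  wq <- det$weight * det$delta_qaly
  wc <- det$weight * det$delta_cost

  n_strat <- 2L^n
  out <- data.frame(strategy = character(n_strat),
                    delta_qaly = numeric(n_strat),
                    delta_cost = numeric(n_strat),
                    stringsAsFactors = FALSE)
  for (m in seq_len(n_strat) - 1L) {
    members <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    out$strategy[m + 1L] <- if (length(members)) {
      paste(sort(det$name[members]), collapse = ",")
    } else "(none)"
    out$delta_qaly[m + 1L] <- sum(wq[members])
    out$delta_cost[m + 1L] <- sum(wc[members])
  }
  class(out) <- c("strategy_table", class(out))
  out
}

#' Build the cost-effectiveness frontier
#'
#' Standard frontier construction over a strategy table: sort by increasing
#' incremental QALYs (ties broken by lower cost, then name); drop strictly
#' dominated strategies (another strategy is at least as effective and
#' cheaper, or more effective at no extra cost); then iteratively drop
#' extended-dominated strategies whose incremental ICER exceeds that of the
#' next frontier segment, until incremental ICERs are strictly increasing.
#' The do-nothing point (0, 0) is added if absent; the resulting chain is
#' the lower-left convex hull of the strategy cloud, anchored at do-nothing
#' whenever no strategy saves money at a QALY loss.
#'
#' @param strategies a data frame with columns `strategy`, `delta_qaly`,
#'   `delta_cost` (as from [enumerate_strategies()]).
#' @return an object of class `frontier_result`: list with `frontier`
#'   (data frame ordered by `delta_qaly` with `incremental_icer` of each
#'   segment, `NA` for the origin) and `excluded` (data frame with an
#'   `exclusion_reason` of `"dominated"` or `"extended-dominated"`).
#' @export
build_frontier <- function(strategies) {
  df <- as.data.frame(strategies)[, c("strategy", "delta_qaly", "delta_cost")]
  if (!any(df$delta_qaly == 0 & df$delta_cost == 0)) {
    df <- rbind(data.frame(strategy = "(none)", delta_qaly = 0,
                           delta_cost = 0), df)
  }
  df <- df[order(df$delta_qaly, df$delta_cost, df$strategy), ]
  rownames(df) <- NULL

  n <- nrow(df)
  reason <- rep(NA_character_, n)

  # strict dominance (pairwise): j dominates i if cost_j <= cost_i and
  # qaly_j >= qaly_i with at least one strict; exact duplicates keep the
  # sort-order (tie-break) winner
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !is.na(reason[j])) next
      dq_ge <- df$delta_qaly[j] >= df$delta_qaly[i]
      dc_le <- df$delta_cost[j] <= df$delta_cost[i]
      strict <- df$delta_qaly[j] > df$delta_qaly[i] ||
        df$delta_cost[j] < df$delta_cost[i]
      dup <- !strict && dq_ge && dc_le && j < i
      if ((dq_ge && dc_le && strict) || dup) {
        reason[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: along the surviving chain, remove interior points
  # whose incoming incremental ICER is not strictly below the outgoing one
  repeat {
    idx <- which(is.na(reason))
    if (length(idx) < 3) break
    removed <- FALSE
    for (k in 2:(length(idx) - 1)) {
      a <- idx[k - 1]; b <- idx[k]; cc <- idx[k + 1]
      icer_ab <- (df$delta_cost[b] - df$delta_cost[a]) /
        (df$delta_qaly[b] - df$delta_qaly[a])
      icer_bc <- (df$delta_cost[cc] - df$delta_cost[b]) /
        (df$delta_qaly[cc] - df$delta_qaly[b])
      if (icer_ab >= icer_bc) {
        reason[b] <- "extended-dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  keep <- which(is.na(reason))
  frontier <- df[keep, ]
  frontier$incremental_icer <- c(NA_real_,
    diff(frontier$delta_cost) / diff(frontier$delta_qaly))
  rownames(frontier) <- NULL
  excluded <- df[!is.na(reason), ]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  rownames(excluded) <- NULL
  structure(list(frontier = frontier, excluded = excluded),
            class = "frontier_result")
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("cost-effectiveness frontier:\n")
  print(x$frontier, ...)
  if (nrow(x$excluded)) {
    cat(nrow(x$excluded), "strategies excluded",
        sprintf("(%d dominated, %d extended-dominated)\n",
                sum(x$excluded$exclusion_reason == "dominated"),
                sum(x$excluded$exclusion_reason == "extended-dominated")))
  }
  invisible(x)
}

#' Frontier over all indication combinations of a parameter set
#'
#' Convenience wrapper: [enumerate_strategies()] then [build_frontier()].
#'
#' @inheritParams enumerate_strategies
#' @return a `frontier_result`.
#' @export
indication_frontier <- function(p, scenario = scenario_spec()) {
  build_frontier(enumerate_strategies(p, scenario))
}

#' Export a frontier as CSV
#'
#' One row per strategy with frontier membership, exclusion reason and the
#' incremental ICER of frontier segments.
#'
#' @param fr a `frontier_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_frontier_csv <- function(fr, path) {
  a <- fr$frontier
  a$on_frontier <- TRUE
  a$exclusion_reason <- NA_character_
  b <- fr$excluded
  if (nrow(b)) {
    b$on_frontier <- FALSE
    b$incremental_icer <- NA_real_
  } else {
    b <- a[0, ]
  }
  cols <- c("strategy", "delta_qaly", "delta_cost", "on_frontier",
            "exclusion_reason", "incremental_icer")
  utils::write.csv(rbind(a[, cols], b[, cols]), path, row.names = FALSE)
  invisible(path)
}
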
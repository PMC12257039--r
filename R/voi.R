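# Expected value of perfect information over the two-strategy decision
# space (fund the intervention vs. standard care, whose net benefit is the
# reference zero).

#' Per-person EVPI from INMB draws at one threshold
#'
#' With two strategies and the comparator's net benefit normalized to zero,
#' the expected value of perfect information is the expected net-benefit
#' gain of deciding with foreknowledge of each parameter draw:
#' `mean(pmax(inmb, 0)) - max(mean(inmb), 0)`. It is non-negative by
#' Jensen's inequality and zero exactly when one option is optimal in every
#' draw and on average.
#'
#' @param inmb_draws numeric vector of per-iteration INMB values.
#' @return per-person EVPI in money units.
#' @export
#' @examples
#' evpi_at(c(-10, 10))  # 5
evpi_at <- function(inmb_draws) {
  if (!length(inmb_draws)) stop("empty INMB draws", call. = FALSE)
  mean(pmax(inmb_draws, 0)) - max(mean(inmb_draws), 0)
}

#' EVPI curve over a willingness-to-pay grid
#'
#' Recomputes INMB per grid point from the stored incremental cost and QALY
#' draws and evaluates [evpi_at()] at each.
#'
#' @param result a `psa_result`.
#' @param level `"agnostic"` or an indication name.
#' @param wtp_grid thresholds (default 0 to 200,000 by 5,000).
#' @return an object of class `evpi_curve`: data frame with columns `wtp`,
#'   `evpi`, `level`, `scenario`.
#' @export
evpi_curve <- function(result, level = "agnostic",
                       wtp_grid = seq(0, 200000, by = 5000)) {
  if (!length(wtp_grid)) stop("empty WTP grid", call. = FALSE)
  d <- psa_draws(result, level)
  out <- data.frame(
    wtp = wtp_grid,
    evpi = vapply(wtp_grid, function(w) {
      evpi_at(inmb(d$delta_cost, d$delta_qaly, w))
    }, numeric(1)),
    level = level,
    scenario = result$scenario_tag)
  class(out) <- c("evpi_curve", class(out))
  out
}

#' EVPI curves for every level of a PSA result
#'
#' @param result a `psa_result`.
#' @param wtp_grid thresholds passed to [evpi_curve()].
#' @return row-bound `evpi_curve` data frame over `"agnostic"` and every
#'   indication.
#' @export
evpi_curves_all <- function(result, wtp_grid = seq(0, 200000, by = 5000)) {
  out <- do.call(rbind, lapply(c("agnostic", result$indications),
                               function(lv) evpi_curve(result, lv, wtp_grid)))
  rownames(out) <- NULL
  out
}

#' Export EVPI curves as CSV
#'
#' @param curves an `evpi_curve` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_evpi_csv <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}
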
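# Cost-effectiveness metrics: INMB, ICER with dominance labels, PSA
# summaries (intervals, CEAC probabilities, CE-plane quadrants), currency
# conversion.

#' Incremental net monetary benefit
#'
#' `INMB = WTP * delta_qaly - delta_cost`. Positive INMB means the
#' intervention is cost-effective at that willingness-to-pay threshold.
#'
#' @param delta_cost incremental cost (vectorized).
#' @param delta_qaly incremental QALYs (vectorized).
#' @param wtp willingness-to-pay threshold, money per QALY (>= 0).
#' @return INMB in money units.
#' @export
#' @examples
#' inmb(10000, 0.5, 50000)  # 15000
inmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_qaly - delta_cost
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' Returns the ratio `delta_cost / delta_qaly` in the ordinary (northeast)
#' case. Quadrant rules: the intervention is `"dominant"` (cheaper, at least
#' as effective) when `delta_cost <= 0` and `delta_qaly > 0` — or costs
#' strictly less at equal effect; `"dominated"` when `delta_cost >= 0` and
#' `delta_qaly < 0`, or strictly more costly at equal effect;
#' `"equivalent"` when both increments are zero. In the southwest quadrant
#' (cheaper and less effective) the ratio is returned with a quadrant
#' attribute, since there a *larger* ICER favours the intervention.
#'
#' @param delta_cost incremental cost.
#' @param delta_qaly incremental QALYs.
#' @return a number (possibly with a `quadrant` attribute) or a dominance
#'   label string.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("equivalent")
  if (delta_qaly > 0 && delta_cost <= 0) return("dominant")
  if (delta_qaly < 0 && delta_cost >= 0) return("dominated")
  if (delta_qaly == 0) return(if (delta_cost > 0) "dominated" else "dominant")
  r <- delta_cost / delta_qaly
  if (delta_qaly < 0) attr(r, "quadrant") <- "southwest"
  r
}

percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}

#' Summarize a PSA result at one level
#'
#' Means with 95 percent percentile intervals (2.5th-97.5th), the
#' ratio-of-means ICER (with `icer_mean_of_ratios` alongside, for
#' comparison with summaries computed per iteration), mean INMB with
#' intervals at each willingness-to-pay threshold, probability
#' cost-effective (fraction of iterations with strictly positive INMB),
#' and cost-effectiveness-plane quadrant shares.
#'
#' @param result a `psa_result`.
#' @param g a [global_params()] object (supplies WTP thresholds and the
#'   exchange rate).
#' @param level `"agnostic"` or an indication name.
#' @param currency `"CAD"` (computation currency) or `"USD"` (divided by
#'   `g$exchange_rate` at output time).
#' @return an object of class `ce_summary`.
#' @export
summarize_ce <- function(result, g, level = "agnostic",
                         currency = c("CAD", "USD")) {
  currency <- match.arg(currency)
  d <- psa_draws(result, level)
  if (!length(d$delta_cost)) stop("empty PSA draws", call. = FALSE)
  fx <- if (currency == "USD") g$exchange_rate else 1
  dc <- d$delta_cost / fx
  dq <- d$delta_qaly
  wtps <- g$wtp_thresholds / fx

  inmb_by_wtp <- lapply(stats::setNames(wtps, format(wtps, scientific = FALSE,
                                                     trim = TRUE)),
    function(w) {
      v <- inmb(dc, dq, w)
      list(mean = mean(v), ci = percentile_ci(v),
           prob_ce = mean(v > 0))
    })

  quad <- c(ne = mean(dc > 0 & dq > 0),
            se = mean(dc <= 0 & dq > 0),
            nw = mean(dc > 0 & dq <= 0),
            sw = mean(dc <= 0 & dq <= 0))

  mdc <- mean(dc); mdq <- mean(dq)
  ratios <- ifelse(dq == 0, NA_real_, dc / dq)
  structure(list(
    level = level,
    currency = currency,
    n_iter = result$n_iter,
    mean_delta_cost = mdc,
    ci_delta_cost = percentile_ci(dc),
    mean_delta_qaly = mdq,
    ci_delta_qaly = percentile_ci(dq),
    icer = icer(mdc, mdq),
    icer_mean_of_ratios = mean(ratios, na.rm = TRUE),
    inmb_by_wtp = inmb_by_wtp,
    prob_ce_by_wtp = vapply(inmb_by_wtp, function(x) x$prob_ce, numeric(1)),
    quadrant_shares = quad,
    scenario_tag = result$scenario_tag
  ), class = "ce_summary")
}

#' @export
print.ce_summary <- function(x, ...) {
  f <- function(v) format(round(v), big.mark = ",", trim = TRUE)
  cat(sprintf("ce_summary [%s, %s, scenario '%s', %d iterations]\n",
              x$level, x$currency, x$scenario_tag, x$n_iter))
  cat(sprintf("  delta cost  %s (95%% CI %s, %s)\n", f(x$mean_delta_cost),
              f(x$ci_delta_cost[1]), f(x$ci_delta_cost[2])))
  cat(sprintf("  delta QALY  %.3f (95%% CI %.3f, %.3f)\n",
              x$mean_delta_qaly, x$ci_delta_qaly[1], x$ci_delta_qaly[2]))
  cat("  ICER (ratio of means) ",
      if (is.character(x$icer)) x$icer else f(x$icer), "\n", sep = "")
  for (w in names(x$inmb_by_wtp)) {
    e <- x$inmb_by_wtp[[w]]
    cat(sprintf("  INMB @ %s: %s (95%% CI %s, %s), P(CE) = %.3f\n",
                w, f(e$mean), f(e$ci[1]), f(e$ci[2]), e$prob_ce))
  }
  invisible(x)
}

#' Convert computation-currency (CAD) amounts to USD
#'
#' Division by the CAD-per-USD rate; applied at output time only, never
#' inside the engine.
#'
#' @param x amount in CAD (vectorized).
#' @param rate CAD per USD (> 0); default 1.25349, the packaged 2021 rate.
#' @return amount in USD.
#' @export
convert_currency <- function(x, rate = 1.25349) {
  if (!is.finite(rate) || rate <= 0) {
    stop("exchange rate must be > 0", call. = FALSE)
  }
  x / rate
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of positive INMB over a willingness-to-pay grid.
#'
#' @param result a `psa_result`.
#' @param level `"agnostic"` or an indication name.
#' @param wtp_grid thresholds (default 0 to 200,000 by 5,000).
#' @return data frame with columns `wtp`, `probability`.
#' @export
ceac <- function(result, level = "agnostic",
                 wtp_grid = seq(0, 200000, by = 5000)) {
  d <- psa_draws(result, level)
  data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) {
      mean(inmb(d$delta_cost, d$delta_qaly, w) > 0)
    }, numeric(1)))
}

#' Export per-iteration cost-effectiveness-plane coordinates
#'
#' @param result a `psa_result`.
#' @param path CSV output path.
#' @param level `"agnostic"` or an indication name.
#' @return `path`, invisibly.
#' @export
export_ce_plane_csv <- function(result, path, level = "agnostic") {
  d <- psa_draws(result, level)
  utils::write.csv(data.frame(iteration = seq_len(result$n_iter),
                              delta_qaly = d$delta_qaly,
                              delta_cost = d$delta_cost),
                   path, row.names = FALSE)
  invisible(path)
}
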
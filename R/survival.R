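# Piecewise-exponential survival models fitted through median OS/PFS.
#
# A survival_model is a step-hazard curve: segments of constant hazard
# starting at strictly increasing times from 0, evaluated as
# S(t) = exp(-sum over segments of lambda_j * overlap(t, segment_j)),
# which is continuous in t by construction.

#' Constant-hazard rate from a survival median
#'
#' Fitting an exponential curve through a median survival time m means
#' solving S(m) = exp(-lambda * m) = 1/2, so lambda = log(2)/m.
#'
#' @param median median survival time in weeks (> 0).
#' @return the weekly hazard rate log(2)/median.
#' @export
#' @examples
#' rate_from_median(12)      # 0.0577...
#' rate_from_median(log(2))  # exactly 1
rate_from_median <- function(median) {
  if (any(!is.finite(median) | median <= 0)) {
    stop("median must be positive and finite", call. = FALSE)
  }
  log(2) / median
}

#' Construct a piecewise-exponential survival model
#'
#' @param start_times segment start times in weeks, strictly increasing,
#'   first element 0.
#' @param hazards per-week hazard rates, one per segment, each >= 0.
#' @return an object of class `survival_model`.
#' @export
survival_model <- function(start_times, hazards) {
  start_times <- as.numeric(start_times)
  hazards <- as.numeric(hazards)
  stopifnot(length(start_times) == length(hazards),
            length(start_times) >= 1)
  if (start_times[1] != 0 || is.unsorted(start_times, strictly = TRUE)) {
    stop("segment start times must strictly increase from 0", call. = FALSE)
  }
  if (any(!is.finite(hazards) | hazards < 0)) {
    stop("hazard rates must be finite and >= 0", call. = FALSE)
  }
  structure(list(start_times = start_times, hazards = hazards),
            class = "survival_model")
}

#' Evaluate a survival model
#'
#' @param model a `survival_model`.
#' @param t vector of times in weeks (>= 0).
#' @return S(t), the survival probability at each time.
#' @export
surv_eval <- function(model, t) {
  stopifnot(inherits(model, "survival_model"))
  starts <- model$start_times
  ends <- c(starts[-1], Inf)
  H <- numeric(length(t))
  for (j in seq_along(starts)) {
    H <- H + model$hazards[j] * pmax(0, pmin(t, ends[j]) - starts[j])
  }
  exp(-H)
}

#' Mean survival time (area under the curve) of a model
#'
#' Closed form: each constant-hazard segment contributes
#' S(start) * (1 - exp(-lambda * d)) / lambda over its duration d, and the
#' final open-ended segment contributes S(start)/lambda. Infinite when the
#' last hazard is zero.
#'
#' @param model a `survival_model`.
#' @param upper upper limit in weeks (default `Inf`).
#' @return mean survival in weeks.
#' @export
surv_mean <- function(model, upper = Inf) {
  starts <- model$start_times
  ends <- c(starts[-1], Inf)
  ends <- pmin(ends, upper)
  total <- 0
  for (j in seq_along(starts)) {
    if (ends[j] <= starts[j]) next
    s0 <- surv_eval(model, starts[j])
    lam <- model$hazards[j]
    d <- ends[j] - starts[j]
    total <- total + if (lam == 0) {
      if (is.infinite(d)) return(Inf) else s0 * d
    } else if (is.infinite(d)) s0 / lam else s0 * (1 - exp(-lam * d)) / lam
  }
  total
}

#' @export
print.survival_model <- function(x, ...) {
  cat("survival_model with", length(x$hazards), "segment(s):\n")
  print(data.frame(start_week = x$start_times, hazard = x$hazards))
  invisible(x)
}

#' Bundle OS and PFS models for one arm
#'
#' Progression-free survival can never exceed overall survival; any
#' violation is resolved pointwise at evaluation time by
#' [arm_occupancy()]'s clamp `pfs <- pmin(pfs, os)`.
#'
#' @param os,pfs `survival_model` objects.
#' @return an object of class `arm_curves`.
#' @export
arm_curves <- function(os, pfs) {
  stopifnot(inherits(os, "survival_model"), inherits(pfs, "survival_model"))
  structure(list(os = os, pfs = pfs), class = "arm_curves")
}

#' Intervention-arm curves under an extrapolation policy
#'
#' Under the `full` (optimistic) policy the trial hazard, fitted through the
#' intervention median, applies over the whole horizon. Under the
#' `restricted` (conservative, treatment-waning) policy the intervention
#' hazard applies on `[0, restriction_time)` and reverts to the comparator
#' hazard thereafter; the curve is continuous at the junction because
#' piecewise-exponential survival accumulates hazard.
#'
#' @param ind an [indication_params()] object.
#' @param g a [global_params()] object (supplies `restriction_time`).
#' @param policy `"restricted"` or `"full"`.
#' @return an `arm_curves` object.
#' @export
build_intervention_curves <- function(ind, g,
                                      policy = c("restricted", "full")) {
  policy <- match.arg(policy)
  lam <- list(os_tx = rate_from_median(ind$median_os_tx),
              pfs_tx = rate_from_median(ind$median_pfs_tx),
              os_soc = rate_from_median(ind$median_os_soc),
              pfs_soc = rate_from_median(ind$median_pfs_soc))
  if (policy == "full") {
    return(arm_curves(os = survival_model(0, lam$os_tx),
                      pfs = survival_model(0, lam$pfs_tx)))
  }
  rt <- g$restriction_time
  if (!is.finite(rt) || rt <= 0) {
    stop("configuration error: restriction_time must be > 0 under the ",
         "restricted policy", call. = FALSE)
  }
  arm_curves(
    os = survival_model(c(0, rt), c(lam$os_tx, lam$os_soc)),
    pfs = survival_model(c(0, rt), c(lam$pfs_tx, lam$pfs_soc))
  )
}

#' Comparator-arm curves
#'
#' Single-segment exponentials through the comparator OS and PFS medians
#' (averaged medians of established therapies), extrapolated over the full
#' horizon.
#'
#' @param ind an [indication_params()] object.
#' @param g a [global_params()] object (unused; kept for interface symmetry).
#' @return an `arm_curves` object.
#' @export
build_comparator_curves <- function(ind, g = NULL) {
  arm_curves(
    os = survival_model(0, rate_from_median(ind$median_os_soc)),
    pfs = survival_model(0, rate_from_median(ind$median_pfs_soc))
  )
}

#' Evaluate arm curves on a grid with the PFS <= OS clamp
#'
#' @param curves an `arm_curves` object.
#' @param t times in weeks.
#' @return data frame with columns `time_weeks`, `os`, `pfs` (clamped).
#' @export
arm_occupancy <- function(curves, t) {
  os <- surv_eval(curves$os, t)
  pfs <- pmin(surv_eval(curves$pfs, t), os)
  data.frame(time_weeks = t, os = os, pfs = pfs)
}

#' Export survival curves as a two-column CSV for plotting or audit
#'
#' @param model a `survival_model`.
#' @param path output path.
#' @param t evaluation grid in weeks (default weekly to 10 years).
#' @return `path`, invisibly.
#' @export
export_curve_csv <- function(model, path,
                             t = seq(0, 10 * WEEKS_PER_YEAR, by = 1)) {
  utils::write.csv(data.frame(time_weeks = t, survival = surv_eval(model, t)),
                   path, row.names = FALSE)
  invisible(path)
}
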
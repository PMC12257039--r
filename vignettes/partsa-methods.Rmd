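---
title: "Methods: a partitioned-survival engine for tumor-agnostic cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned-survival engine for tumor-agnostic cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partsaHTA)
```

## The decision problem

Tumor-agnostic therapies such as NTRK-fusion inhibitors are authorized on
basket trials that pool small cohorts across many cancer types, usually
without a randomized comparator. Health technology assessment then has to
answer two questions at once: is the therapy good value for the pooled
(tumor-agnostic) population, and does that value hide large heterogeneity
across tumor indications? partsaHTA implements the standard machinery for
this problem — a three-state partitioned survival model run per indication,
prevalence-weighted into a tumor-agnostic result — plus the uncertainty
layers a life-cycle assessment needs: probabilistic sensitivity analysis,
extrapolation-scenario envelopes, companion-diagnostic testing costs,
funding-combination frontiers, and expected value of perfect information.

## Model structure

Each arm of each indication is a partitioned survival analysis (PartSA)
with three health states: progression-free, progressed, and dead. State
occupancy is read directly off the survival curves rather than from
transition probabilities:

* progression-free share at time $t$: $PFS(t)$ (clamped to $OS(t)$ from
  above),
* progressed share: $OS(t) - PFS(t)$,
* dead share: $1 - OS(t)$.

Because only median OS and PFS are publicly reported for most basket-trial
strata and for the comparator constructed from previously recommended
therapies, curves are exponential fits through the medians:
$\lambda = \ln 2 / m$, so that $S(m) = 1/2$ exactly. Where a trial median
was never reached, the parameter file simply stores the time at which half
the population remained at risk; no separate code path exists. The engine
supports piecewise-constant hazards, which is how extrapolation policies
are expressed.

### Extrapolation policies

Long-term effectiveness of a conditionally authorized therapy is the
dominant structural uncertainty. Two policies bound it:

* **restricted** (the base case, a treatment-waning assumption): the
  intervention hazard applies on $[0, t_R)$ and reverts to the comparator
  hazard afterwards, with the survival curve continuous at the junction.
  `restriction_time` ($t_R$) defaults to 130 weeks (about 30 months, a
  plausible basket-trial follow-up) and is deliberately exposed as a
  tunable global, since published reviews rarely print the cut-off they
  used;
* **full** (optimistic, sponsor-style): the fitted intervention hazard is
  extrapolated over the whole horizon.

Run under both policies, the pair of results brackets an envelope of
plausible cost-effectiveness; the comparator is always extrapolated with
its single fitted hazard.

## Accumulation

The clock is a weekly cycle over a 10-year horizon (522 cycles; the final
cycle is prorated so the modelled time equals the horizon exactly).
Accrual is start-of-cycle rectangles without half-cycle correction;
`half_cycle_correction = TRUE` switches to trapezoid end weights for
sensitivity analysis. Per cycle, discounted at $(1+r)^{-t/52.17857}$ with
$r = 1.5\%$ annually for both costs and QALYs:

* QALYs: occupancy × tumor-agnostic state utility × cycle length in years.
  Utilities are identical between arms by assumption, so incremental QALYs
  derive purely from survival differences.
* Care costs: per-cycle progression-free and progressed-state costs,
  occupancy-weighted. The pooled "other" indication takes the
  prevalence-weighted average of the named indications' care costs.
* Intervention drug + administration costs: time-dependent — they accrue
  only for cycles starting before the median time to treatment
  discontinuation, weighted by progression-free occupancy (treatment stops
  at progression; an unweighted variant is a configuration switch).
* Comparator drug costs: accrue while progression-free over the whole
  horizon, since no discontinuation time is published for standard care.
* Adverse-event costs: one-off per arm at cycle 0 (reviews report totals,
  not time profiles).
* Testing costs (scenario): number needed to screen, $1/p$ for per-tumor
  fusion prevalence $p$, times the panel cost, charged to the intervention
  arm at cycle 0 undiscounted because screening precedes treatment. The
  comparator arm is untested. NNS is real-valued (cohort-average costing);
  `nns_round_up` switches to whole tests per identified patient.

Indications with five or fewer basket-trial patients are too small to
support effect estimates: under the small-sample rule they contribute zero
incremental QALYs and only the intervention arm's treatment-cost
components (drug, administration, and testing when present).

Tumor-agnostic results are prevalence-weighted sums of per-indication
incremental outcomes, weight $w_i$ being each indication's share of the
fusion-positive advanced-cancer population. When a user subsets
indications with `select_indications()`, weights are renormalized; the
frontier module instead keeps original weights and zeroes unfunded
increments, because its strategies describe the same whole population.

## Probabilistic analysis

`run_psa()` samples all stochastic parameters simultaneously each
iteration (default 1,000) and pushes each realization through the
deterministic engine. Design choices:

* One RNG stream per iteration, derived from the master seed and the
  iteration index: results are replayable per iteration and independent of
  execution order.
* Tumor-agnostic parameters (the two utilities) are drawn once per
  iteration and shared across indications; survival and cost parameters
  are drawn independently per indication, as no correlation structure is
  published.
* Where source documents do not state distributions, defaults follow
  standard health-economics practice and are configurable per parameter:
  gamma for costs (moment-matched, 20% coefficient of variation),
  lognormal for medians (same moment matching), beta for utilities
  (moment-matched, SD 0.05). Structural quantities are held fixed.
* Invalid draws are redrawn (100 consecutive failures abort); sampled PFS
  medians exceeding the OS median are clamped to it, mirroring load-time
  behaviour.
* Reported 95% intervals are percentile (2.5th–97.5th) intervals; the
  interval method behind published tables is typically unstated, and
  percentile intervals are the conventional PSA report.
* The headline ICER is the ratio of mean incremental costs to mean
  incremental QALYs; a mean-of-ratios variant is reported alongside
  because per-iteration ratio summaries are unstable when incremental
  QALYs change sign, and published "mean ICERs" are sometimes of that
  kind.
* The probability of cost-effectiveness counts iterations with strictly
  positive INMB; ties have probability zero under continuous
  distributions.

CAD is the computation currency; USD is derived only at output time by
dividing costs and thresholds by the CAD-per-USD rate (default 1.25349),
which cannot change the sign of any INMB or the cost-effectiveness
decision.

## Decision frontier

`enumerate_strategies()` scores every combination of funded indications
($2^n$ subsets, guarded at $n \le 20$) with deterministic point-estimate
outcomes; `build_frontier()` removes strictly dominated strategies, then
iteratively removes extended-dominated ones until incremental ICERs
strictly increase. The result is the lower-left convex hull of the
strategy cloud, anchored at the do-nothing origin whenever no combination
saves money at a QALY loss; the suite verifies hull equality against an
independent monotone-chain oracle on a thousand random instances.
Extended dominance is applied to every segment including the first: a
first funded step whose ICER exceeds the following segment's is itself
extended-dominated, which is what keeps the reported ICER sequence
meaningful for a willingness-to-pay sweep. Ties in QALYs break by lower
cost, then name, so output is deterministic. The frontier uses
deterministic outcomes by default (probabilistic means can disagree on
which strategies are dominated); pass the PSA means explicitly to
`build_frontier()` to build that variant.

## Value of information

EVPI is computed per person on the two-strategy decision (fund vs. not,
comparator net benefit normalized to zero):
$\mathrm{EVPI}(\lambda) = E[\max(\mathrm{INMB}, 0)] -
\max(E[\mathrm{INMB}], 0)$, evaluated over a WTP grid (default 0–200,000
in 5,000 steps) by recomputing INMB from the stored incremental cost and
QALY draws. Population scaling by incidence and decision horizon is
deliberately out of scope. EVPI is non-negative by construction and zero
wherever one option dominates every draw.

## The packaged parameter set, and what the tests do and do not show

`default_parameter_file()` points to a nine-indication parameter set
(breast, colorectal, NSCLC, pancreatic, thyroid, sarcoma, neuroendocrine,
MASC, other; 121 trial patients in total) whose values are **synthetic**:
magnitudes are plausible for an NTRK-inhibitor evaluation (weekly drug
cost near CAD 1,925, NGS panel CAD 2,790, fusion prevalence from 0.05% in
breast to 90% in MASC), but they are constructed stand-ins, not
transcriptions of any HTA document. Absolute numbers computed from it
demonstrate the machinery; they are not estimates for any real therapy.

The fixture generator (`generate_fixture()`) draws random valid parameter
sets with advanced-cancer magnitudes. It emulates the *structure* of real
evidence — median-only survival summaries, PFS bounded by OS, simplex
weights — but not its correlations (costs and effectiveness are drawn
independently) nor non-exponential hazard shapes. Passing tests therefore
certify the arithmetic and the decision logic, not the fit of an
exponential through any particular trial's medians.

## Numerical choices and degenerate inputs

* 522 weekly cycles for 10 years; final-cycle proration makes one modelled
  year accrue exactly one utility-weighted year at zero hazard.
* PFS > OS inputs are clamped (with a warning and a log) rather than
  rejected, to keep user-supplied evidence updates usable; hard
  impossibilities (negative costs, weights off the simplex) are errors
  naming the field.
* A month, where used for input conversion, is 4.348125 weeks (one
  twelfth of the 365.2425-day Gregorian year); the model-clock year for
  discounting is 365.25/7 weeks.
* Zero hazards are admitted for degenerate tests (immortal cohorts);
  `icer()` returns labels ("dominant", "dominated", "equivalent") instead
  of undefined ratios, and flags the southwest quadrant where a larger
  ratio is better.
* Exact duplicate strategies collapse to the tie-break winner.

## Known limitations

Three-state PartSA cannot represent treatment sequencing or post-trial
care pathways; comparator medians averaged across therapies blur
first/second-line distinctions; exponential fits through a single median
ignore hazard shape; independent sampling may understate joint
uncertainty. These are properties of the evidence base this engine is
designed to consume — median-level, publicly reported summaries — and are
the reason its outputs are best read as a reproducible index estimate and
an uncertainty envelope, to be revisited as trial follow-up and real-world
data accrue.
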
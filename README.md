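# partsaHTA

A partitioned-survival cost-effectiveness engine for tumor-agnostic
therapies, built for life-cycle health technology assessment (HTA).

Tumor-agnostic oncology products — therapies approved for a genomic
biomarker (here, NTRK gene fusions) irrespective of cancer site — are
typically authorized on single-arm basket trials pooling small cohorts
across many tumor types. HTA bodies then need per-indication and pooled
value estimates built from the only evidence publicly available: median
overall survival (OS) and progression-free survival (PFS), list prices,
and review-level cost summaries. partsaHTA provides a reusable,
reproducible engine for exactly that setting, intended for health
economists and HTA analysts who want an index model that can be re-run as
evidence matures.

## What it computes

For each tumor indication, a three-state partitioned survival model
(progression-free / progressed / dead) on a weekly cycle over a 10-year
horizon. State occupancy comes straight from the survival curves:
progression-free is $PFS(t)$, progression is $OS(t) - PFS(t)$, death is
$1 - OS(t)$. Curves are exponential fits through reported medians,
$\lambda = \ln 2 / m$, with two extrapolation policies for the
intervention: *restricted* (hazard reverts to the comparator's at a
configurable waning time; the conservative base case) and *full*
(optimistic). Discounted costs and QALYs accumulate per cycle at 1.5%
annually; drug costs are time-dependent, stopping at the median time to
treatment discontinuation.

On top of the engine:

* **PSA** — all parameters sampled simultaneously (default 1,000
  iterations), per-iteration RNG streams for exact replay;
* **CE metrics** — ICER with dominance labels, incremental net monetary
  benefit $\mathrm{INMB} = \lambda \Delta E - \Delta C$ at CAD 50,000 and
  100,000/QALY, acceptability curves, CE-plane quadrant shares, CAD→USD
  conversion at output time;
* **Scenarios** — NGS companion-diagnostic testing costs via number
  needed to screen ($1/p$ per-tumor fusion prevalence), charged to the
  intervention arm at cycle 0;
* **Decision frontier** — every combination of funded indications
  ($2^n$), strict and extended dominance, strictly increasing incremental
  ICERs;
* **EVPI** — per-person expected value of perfect information,
  $E[\max(\mathrm{INMB},0)] - \max(E[\mathrm{INMB}],0)$, over a WTP grid;
* **Small-sample rule** — indications with ≤ 5 trial patients contribute
  treatment costs but no incremental QALYs.

The packaged default parameter set
(`default_parameter_file()`) is **synthetic**: it mirrors the structure of
a real nine-indication NTRK-inhibitor evaluation (121 basket-trial
patients; breast, colorectal, NSCLC, pancreatic, thyroid, sarcoma,
neuroendocrine, MASC, other) with plausible magnitudes, but its values are
constructed stand-ins, so results from it exercise the machinery rather
than estimate any real product's value.

## Worked example

```r
library(partsaHTA)

p <- load_parameter_set(default_parameter_file())
res <- run_psa(p, n_psa = 200, seed = 42)
summarize_ce(res, p$globals)
#> ce_summary [agnostic, CAD, scenario 'base', 200 iterations]
#>   delta cost  40,182 (95% CI 26,449, 54,303)
#>   delta QALY  0.283 (95% CI 0.126, 0.429)
#>   ICER (ratio of means) 141,872
#>   INMB @ 50000: -26,021 (95% CI -39,072, -14,527), P(CE) = 0.000
#>   INMB @ 100000: -11,859 (95% CI -26,465, 4,017), P(CE) = 0.065
```

Read: funding the therapy across all indications costs about CAD 40,000
more per patient than standard care for about 0.28 extra
quality-adjusted life years — an ICER of roughly CAD 142,000/QALY, above
both thresholds, hence the negative INMB (the monetized net loss per
patient at each willingness-to-pay) and the low probability (6.5% at CAD
100,000/QALY) that the therapy is cost-effective.

Which indications *would* be worth funding, and in what order, is the
frontier's job:

```r
fr <- indication_frontier(p)
fr$frontier[, c("strategy", "delta_qaly", "incremental_icer")]
#>                                             strategy delta_qaly incremental_icer
#> 1                                             (none)     0.0000               NA
#> 2                                              NSCLC     0.0942            92393
#> 3                                   colorectal,NSCLC     0.1454           117975
#> 4                             colorectal,NSCLC,other     0.1744           122630
#> ...
#> 8 breast,colorectal,MASC,NSCLC,other,sarcoma,thyroid     0.2985           388315
```

NSCLC is the first-best funding step (CAD 92,393 per additional QALY over
funding nothing); each later row adds an indication at a strictly higher
incremental ICER, so a decision-maker's threshold picks a point on this
chain. Indications that never appear (pancreatic, neuroendocrine — the
small-sample indications — and thyroid on intermediate rows) are dominated
or extended-dominated.

Scenario envelopes and value of information follow the same pattern:

```r
full <- run_psa(p, scenario_spec("full"), n_psa = 200, seed = 42)       # optimistic extrapolation
test <- run_psa(p, scenario_spec(include_testing = TRUE), n_psa = 200,
                seed = 42)                                              # add NGS screening costs
evpi_curve(res, "agnostic", wtp_grid = seq(0, 2e5, 5e3))                # per-person EVPI
```

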
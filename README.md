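# s1switch

Cost-effectiveness analysis of switching to S-1-based chemotherapy after
fluoropyrimidine-induced hand-foot syndrome (HFS) or cardiovascular
toxicity (CVT) in metastatic colorectal cancer.

When HFS or CVT occurs on capecitabine or i.v. 5-FU, the clinician can
continue at reduced dose, discontinue first-line treatment until
progression, or switch to the oral fluoropyrimidine S-1 (alone or as SOX /
IRIS combinations). `s1switch` quantifies what each option costs and
yields in quality-adjusted life years (QALYs), for health-economics
analysts and modellers who want to rerun, perturb or extend the analysis.

## The model

A five-state Markov cohort model with 1-week cycles follows a closed
cohort from the switch to death: first-line treatment, progression (one
transient week, after which 80% start second-line treatment), second-line
treatment, progressed without treatment, and death. Weekly transition
probabilities come from Weibull survival models — overall survival
S(t) = exp(−(t/79.4)^1.473), time-to-progression with shape 1.560 and
scale 53.9 weeks — with strategy effects applied as relative risks on the
weekly probabilities (S-1: RR 0.93 on death; discontinuation: RR 1.50 on
death and progression). Costs (3%/year discount) accrue from per-cycle
drug and administration prices; QALYs (1.5%/year discount) from state
utilities (0.83 first line, −0.15 on second-line treatment, −0.10
untreated progression) and adverse-event disutilities.

Strategies are compared by incremental cost-effectiveness ratios
(ICER = Δcost/ΔQALY) on PSA-mean outcomes, a dominance frontier with
strict and extended dominance, and cost-effectiveness acceptability
curves from net monetary benefit (WTP × QALYs − cost) across 1000
probabilistic parameter draws. A synthetic-trial module simulates
individual-patient OS/TTP data at trial scale and refits exponential and
Weibull models by censored maximum likelihood (including the left-truncated
9-week-survivor refit used in sensitivity analysis).

See `vignettes/model-methods.Rmd` for the full model description and the
reasoning behind every numerical choice.

## Worked example

```r
library(s1switch)

cfg <- load_scenario("capox")          # toxicity occurred on CAPOX
psa <- run_psa(cfg$scenario, cfg$settings, n_runs = 1000, seed = 42)
psa
#> <psa_results> capox - 1000 runs, seed 42
#>       strategy total_cost  qalys
#> 1     stop_iri       6871 0.7936
#> 2 redCAPOX_iri      22059 1.0355
#> 3      SOX_iri      24808 1.0896
#> 4     SOX_IRIS      24825 1.0896

frontier(psa$summary, reference = "stop_iri")
#>       strategy mean_cost mean_qalys             status icer_vs_previous icer_vs_reference
#> 1     stop_iri      6871     0.7936          reference               NA                NA
#> 2 redCAPOX_iri     22059     1.0355 extended_dominated               NA             62788
#> 3      SOX_iri     24808     1.0896        on_frontier            60601             60601
#> 4     SOX_IRIS     24825     1.0896          dominated               NA             60658

ceac_turning_point(ceac(psa))
#> [1] 62000
```

Reading: discontinuing CAPOX and moving to irinotecan at progression is
cheapest but yields the fewest QALYs (0.79). Continuing reduced-dose
CAPOX is weakly (extended-) dominated: switching to SOX buys its extra
QALYs at a lower price per QALY (~€60 600 vs ~€62 800 per QALY against
the discontinuation reference). SOX → IRIS is indistinguishable from
SOX → irinotecan (€17 more, equal QALYs). Below the Dutch €80 000/QALY
threshold for high-burden disease, switching to SOX is cost-effective;
the acceptability curves flip from favouring discontinuation to favouring
SOX at a willingness to pay of about €60 000 per QALY.

Other entry points: `run_strategy()` for a single deterministic
evaluation, `run_sensitivity()` for the discontinuation-RR (1.2/1.8) and
9-week-landmark variants, `simulate_ipd()` / `fit_parametric()` /
`bootstrap_shape_scale_corr()` for the synthetic-trial machinery, and
`cea_run()` / `cea_sensitivity()` / `cea_simulate()` (or
`inst/cli/s1switch.R`) to write the full table bundle with a
reproducibility manifest.

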
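# footcea

Decision-tree cost-effectiveness analysis of secondary prevention of
diabetic foot ulceration.

Diabetic foot — neuropathy-driven foot ulceration in diabetes — is largely
preventable, yet its gravest outcomes (amputation and post-amputation
death) are common where preventive foot care is weak. `footcea` implements
a one-year, prevalence-based decision-tree model for a high-risk cohort
(severe neuropathy) that quantifies, for three prevention strategies —
sub-optimal (usual) care, guideline-based standard care, and standard care
plus daily foot-temperature self-monitoring — the cost of illness, the
deaths and major amputations averted, and the incremental
cost-effectiveness of stepping up prevention. It is written for health
economists and epidemiologists who want a tested, reusable implementation
of this class of model: every computation is a package function, the
analysis is a set of thin scripts over them, and all headline quantities
are locked by tests.

## The model

A strategy with effectiveness *e* reduces the baseline one-year ulcer
prevalence *c* to *c*(1 − *e*). Ulcerated patients split into outpatient
wound management (probability 1 − *d*, heal) and hospital care (*d*);
hospitalized patients heal with debridement (*g*), heal after amputation
(*f*), or die after amputation (*h*), with *f* + *g* + *h* = 1 and
amputations split major/minor (*f₁*/*f₂*). Direct costs are
ingredients-based (prevention for the whole cohort plus per-episode
treatment); premature death is valued by the human-capital approach as the
discounted minimum-wage earnings lost to retirement (annuity-due, so a
death costs PV = Σₜ 12 w/x (1+r)⁻ᵗ, t = 0..L−1). Strategies are compared
by the incremental cost-effectiveness ratio ICER = ΔC/ΔE (US$ per death
averted), with cost-saving/dominated classification and a 3×-GDP-per-capita
threshold; uncertainty is assessed by multiple one-way sensitivity analysis
ordered as a tornado. See `vignettes/diabetic-foot-cea.Rmd` for the full
account, including the derivations the bundled Peru-2012 parameter set
performs at load time.

## Worked example

```r
library(footcea)

ps <- peru_2012_fixture()          # Peru 2012: 942,000 diabetics, 21.9 % high risk
high_risk_population(ps)
#> [1] 206298

fl <- compute_flows(ps, "sub_optimal")
round_half_up(fl$n_ulcerated)      # persons ulcerating in one year
#> [1] 45761
round_half_up(summarize_outcomes(fl)$deaths)
#> [1] 1757

round_half_up(total_direct_cost(ps, "sub_optimal")$direct_total / 1e6, 1)
#> [1] 74.5                         # million US$, prevention + treatment

compare_strategies(ps, "standard_plus_temp", "sub_optimal")
#> <strategy_comparison: standard_plus_temp vs sub_optimal>
#>   delta cost (direct):            US$ 22,316,737
#>   delta cost (direct + indirect): US$ 13,011,868
#>   deaths averted: 1,385; major amputations averted: 3,656
#>   ICER = 16,115 (direct); ICER = 9,396 (direct + indirect)
#>   cost-effective at threshold US$ 19,704 per death averted: TRUE

run_owsa(ps, owsa_spec("standard", "sub_optimal"))$parameter[1]
#> [1] "prevention_standard"        # prevention cost dominates the tornado
```

Interpretation: under usual care, diabetic foot costs ≈ US$74.5M/year and
causes 1,757 deaths in the high-risk cohort. Standard care is cost-saving
while averting 791 deaths; adding temperature monitoring averts 1,385
deaths at ≈ US$16,100 per death averted (≈ US$9,400 once avoided
productivity losses are counted), under the US$19,704 threshold.

## The analysis, step by step

The `analysis/` scripts run the full study over the installed package and
write their tables to `results/`:

```sh
Rscript analysis/01_cohort_flows.R        # decision-tree person counts
Rscript analysis/02_cost_of_illness.R     # direct costs + report bundle
Rscript analysis/03_cost_effectiveness.R  # ICERs and dominance
Rscript analysis/04_sensitivity.R         # tornado tables and figures
```

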
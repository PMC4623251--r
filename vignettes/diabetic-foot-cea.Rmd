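---
title: "Modelling the cost-effectiveness of diabetic-foot prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of diabetic-foot prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footcea)
```

## The model

`footcea` implements a one-year, prevalence-based decision-tree model of
secondary prevention of diabetic foot ulceration in a high-risk cohort
(people with type 2 diabetes and severe neuropathy). The cohort is closed:
no recurrence, no re-entry, and — because everything happens within a single
year — no discounting of costs or health outcomes.

Three prevention strategies are compared:

* **sub-optimal care** — an annual physician and podiatrist visit with
  routine tests; the comparator representing usual care;
* **standard care** — guideline-based foot care (frequent consultations,
  education, protective footwear);
* **standard care plus temperature monitoring** — standard care plus daily
  self-measurement of foot skin temperature with nurse-assisted phone
  follow-up.

Each strategy acts solely by reducing the one-year ulcer prevalence in the
high-risk cohort: a strategy with effectiveness $e$ yields prevalence
$c\,(1-e)$, where $c$ is the baseline (sub-optimal) prevalence. Downstream
of ulceration the clinical course is identical across strategies:

1. an ulcerated patient receives outpatient wound management (probability
   $1-d$) and heals, or hospital care (probability $d$);
2. a hospitalized patient heals with debridement ($g$), heals after an
   amputation ($f$), or dies after an amputation ($h$), with
   $f + g + h = 1$;
3. amputations (among both the healed and the deceased) are major with
   probability $f_1$ and minor with $f_2 = 1 - f_1$. Every death is assumed
   to follow an amputation in the same year, which is why the mortality
   branch is split major/minor with the same conditional probabilities.

Person counts are carried as fractional persons at full precision through
the whole pipeline; integers appear only when a table is rendered (and then
by rounding halves away from zero, `round_half_up()`). This matters: the
headline aggregates only reproduce from unrounded chains, and several
published integers differ by one unit from what rounding the printed
intermediate values would give.

## Parameters and their anchors

The bundled base case (`peru_2012_fixture()`, stored as
`inst/extdata/peru_2012.yaml`) describes Peru in 2012: 942,000 people with
type 2 diabetes, of whom 21.9 % are at high risk, giving a cohort of
206,298. Branch probabilities come from a Brazilian public-hospital cohort
($d = 0.30$, $g = 0.3945$, $f = 0.4775$, $h = 0.128$, $f_1 = 0.558$).

Two derivations are done at load time rather than stored rounded, because
the person counts only reproduce at full precision:

* the **baseline prevalence** is back-calculated from a trial anchor: a
  standard-care prevalence of 12.2 % together with a 45 % effectiveness
  gives $c = 0.122 / 0.55 = 0.2218\overline{18}$ (displayed as 22.18 %);
* the **temperature-monitoring effectiveness** is back-calculated from its
  trial prevalence of 4.7 %: $e = 1 - 0.047/c = 0.78811\ldots$ (displayed
  as 78.81 %).

Per-person prevention costs are likewise stored as the published strategy
**totals** (13,350,763 / 38,129,966 / 83,849,832 US$) and divided by the
cohort size at load, implying 64.7159 / 184.8295 / 406.4500 US$ per person.
The rounded integers 65 / 185 / 406 are retained as display metadata only;
using them in computation would shift the totals by up to 0.4 %.

Treatment unit costs are per episode (wound management 79, debridement
1,022, minor amputation 5,153, major amputation 7,360 US$). A patient who
dies is costed at the amputation admission they underwent, with no
additional death-specific cost. The ingredient bundles shipped in
`inst/extdata/cost_bundles_synthetic.csv` illustrate the ingredients-based
costing structurally; only their aggregate sums are authoritative (they are
calibrated to the published unit costs — line prices are synthetic), and the
model consumes the aggregates.

One published inconsistency is deliberately left alone: the outpatient
wound-management line total implies a unit cost of 78.51 rather than the
printed 79. We use the printed 79; the discrepancy is below 0.1 % of the
treatment total and explains most of the small residuals discussed below.

## Costing and the indirect cost of death

Direct cost of a strategy = prevention (delivered to the whole high-risk
cohort, regardless of endpoint — consistent with the published tables) +
treatment (persons at each endpoint times the episode cost).

Indirect costs value premature mortality with the **human-capital
approach**: each death loses the years between the mean age at death (63)
and retirement (65), valued at the minimum wage (PEN 750/month at 2.64
PEN/US$) and discounted at 3 %/year. The discounting convention is
**annuity-due**: the first lost year is undiscounted,

$$\text{PV} = \sum_{t=0}^{L-1} \frac{12\,w/x}{(1+r)^t},$$

which reproduces the published US$6,719 exactly (6,718.888…). The
ordinary-annuity alternative (first year discounted once) gives ≈ 6,523 and
is rejected; the convention is locked by a unit test. The monthly wage is
kept as PEN 750 / 2.64 = 284.09 US$, not the rounded 284.

## Incremental analysis

For an intervention vs a comparator the package reports incremental direct
cost, incremental direct + indirect cost, deaths averted and major
amputations averted — all from unrounded quantities — and classifies the
pair:

* **cost_saving** when the intervention costs less and averts more deaths
  (no ratio is reported; a negative ICER is never printed);
* **dominated** when it costs more without averting any;
* otherwise the **ICER** $\Delta C / \Delta E$ in US$ per death averted.

"Major amputations" counts every patient who underwent one, whether they
healed or died — the published differences only reproduce under this
definition. Equal effects never cause a division by zero: with
$\Delta E = 0$ the pair is labelled `dominated` (if more costly) or
`undefined` (if cheaper — a corner the base case never reaches).

Including indirect costs credits an intervention with the productivity
losses its averted deaths avoid, i.e. it lowers $\Delta C$ by
$\Delta E \times \text{PV}$.

The willingness-to-pay threshold is the conventional multiple of GDP per
capita (3 × 6,568 = 19,704 US$ for the base case), compared **inclusively**
(an ICER exactly at the threshold passes); the source analysis only uses the
threshold informally, so the boundary convention is ours.

ICERs computed from full-precision quantities differ from the published
ones by ≲ 0.1 % (e.g. our 16,114.5 vs the printed 16,124 for temperature
monitoring vs sub-optimal care). The residual stems from the published
rounded per-episode unit costs and the outpatient inconsistency above; we
report our computed value and do not force the printed one.

## One-way sensitivity analysis

`run_owsa()` varies one parameter at a time to the low and high bounds of
its range (published bounds where available, otherwise
`default_range(point, 0.30)`), recomputes the chosen outcome, and orders
parameters by the absolute swing. Ties are broken by parameter name so the
ordering is fully deterministic; a perturbation that breaks a hard model
constraint flags the entry rather than clamping it.

The source analysis never states how linked probabilities are kept
consistent during one-way variation; our rules, chosen to preserve the
sum-to-one constraints while mirroring the published complementary
hospital/outpatient bounds, are:

* varying $d$ (hospitalization) sets the outpatient share to $1-d$, and
  vice versa;
* varying $f$ (amputation-heal) holds mortality $h$ fixed and rebalances
  $g = 1 - f - h$, and symmetrically for $g$; varying $h$ rebalances $g$.
  Holding mortality fixed when varying the healing split keeps the death
  toll interpretable as a function of hospitalization alone;
* varying the baseline prevalence keeps effectiveness fixed (strategy
  prevalences re-derive), and varying an effectiveness keeps the baseline
  fixed — matching the listing of all three as separate sensitivity
  variables.

The tornado outcome is likewise unstated in the source; we default to the
direct-cost ICER ("the resulting change in cost-effectiveness"). When an
excursion crosses into the cost-saving regime the signed ratio
$\Delta C/\Delta E$ is reported with a regime label, so tornado bars remain
plottable rather than dropping to a non-numeric "Cost-saving".

With these conventions the published rankings reproduce: the intervention's
prevention cost dominates both tornados; for standard care the next-ranked
parameters are its effectiveness, the baseline ulcer prevalence and
hospital utilization; for temperature monitoring, baseline prevalence and
hospital utilization rank ahead of its effectiveness.

## Synthetic scenarios

`generate_parameter_set()` draws random parameter sets that are valid by
construction, for property-based testing: hospital endpoint probabilities
$(f, g, h)$ are sampled on the simplex by normalizing independent gamma
draws (a Dirichlet draw; concentration 2 by default), complements are
constructed rather than checked, and by default the strategies keep the
base-case regime (more intensive ⇒ more effective and more expensive), so
dominance tests exercise the same quadrant as the base case
(`ordered_strategies = FALSE` lifts this). Draws use R's default
Mersenne-Twister generator under `set.seed(seed)`, and the generator
restores the caller's RNG state.

Default magnitudes are chosen to look like national-scale diabetes
epidemiology (populations 200k–3M, high-risk fractions 5–40 %, prevalences
5–35 %, treatment costs in the hundreds-to-tens-of-thousands of US$); they
are test distributions, not inference priors. What the generator does *not*
emulate: correlated uncertainty between parameters, multi-year dynamics,
heterogeneous sub-populations, or utilization below 100 %. Passing
property tests therefore demonstrate internal consistency of the arithmetic
(conservation, linearity, antisymmetry, telescoping), not external validity
of any scenario.

## Numerical choices

* Fractional persons and US$ at double precision throughout; no
  intermediate rounding.
* Display rounding: half away from zero; persons and dollars to integers,
  millions to one decimal.
* Sum-to-one constraints validated to 1e−9; conservation tested to 1e−6
  persons; oracle equivalence (tree-path enumeration vs closed-form flows)
  to 1e−9 relative.
* Validation reports every violation in a single pass, so a config can be
  fixed in one round.
* Test problem sizes: 1,000 synthetic scenarios for the conservation/oracle
  sweep, 200 for construction-validity, 20–50 for the algebraic-identity
  loops — enough to exercise the full parameter space while keeping the
  suite around 15 s on one core.

## Limitations

The model inherits the source analysis's scope: one year, a closed cohort,
100 % healthcare utilization, no ulcer recurrence, no rural/urban
stratification, no travel or waiting-time costs, and deaths averted (not
QALYs/DALYs) as the health outcome. Probabilistic sensitivity analysis,
multi-way analyses and Markov extensions are out of scope; the one-way
analysis here is the only uncertainty assessment, and it understates joint
parameter uncertainty.
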
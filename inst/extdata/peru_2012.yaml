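# Peru 2012 base-case parameter set for the diabetic-foot decision-tree model.
# All proportions are decimals; monetary amounts are 2012 US$ except
# economics.minimum_wage_local (PEN/month).
#
# Derived at load time (full precision, never stored rounded):
#   baseline_ulcer_prevalence = reference_prevalence / (1 - reference_effectiveness)
#                             = 0.122 / 0.55 = 0.221818... (printed 22.18 %)
#   standard_plus_temp effectiveness = 1 - 0.047 / baseline = 0.788115 (printed 78.81 %)
#   per-person prevention cost = prevention_cost_total / high-risk population
#     (implied 64.7159 / 184.8295 / 406.4500; printed integers kept as display)
epidemiology:
  total_diabetes_population: 942000
  high_risk_fraction: 0.219
  reference_prevalence: 0.122        # ulcer prevalence under standard care (trial)
  reference_effectiveness: 0.45      # standard care vs sub-optimal baseline
  p_hospital: 0.30
  p_outpatient: 0.70
  p_amputation_heal: 0.4775
  p_major_given_amputation: 0.558
  p_minor_given_amputation: 0.442
  p_debridement_heal: 0.3945
  p_death: 0.128

strategies:
  sub_optimal:
    effectiveness: 0.0
    prevention_cost_total: 13350763
    prevention_cost_display: 65
  standard:
    effectiveness: 0.45
    prevention_cost_total: 38129966
    prevention_cost_display: 185
  standard_plus_temp:
    target_prevalence: 0.047
    prevention_cost_total: 83849832
    prevention_cost_display: 406

treatment_costs:            # per episode, US$
  wound_management: 79
  debridement: 1022
  minor_amputation: 5153
  major_amputation: 7360

economics:
  minimum_wage_local: 750   # PEN/month
  exchange_rate: 2.64       # PEN per US$, 2012 average
  discount_rate: 0.03
  retirement_age: 65
  mean_age_at_death: 63
  gdp_per_capita: 6568      # US$, 2012
  gdp_multiplier: 3

# Published low/high bounds for the one-way sensitivity analysis, stored
# verbatim (most are +/-30 % of the point; the outpatient bounds are the
# complements of the hospital bounds and are kept as printed).
ranges:
  baseline_ulcer_prevalence: [0.1553, 0.2884]
  effectiveness_standard: [0.30, 0.60]
  effectiveness_standard_plus_temp: [0.65, 0.85]
  p_hospital: [0.21, 0.39]
  p_outpatient: [0.61, 0.79]
  p_amputation_heal: [0.3343, 0.6208]
  p_debridement_heal: [0.2512, 0.5377]
  prevention_sub_optimal: [45, 84]
  prevention_standard: [129, 240]
  prevention_standard_plus_temp: [285, 528]
  cost_major_amputation: [5152, 9568]
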
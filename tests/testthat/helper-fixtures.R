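# Shared fixtures: a small handcrafted parameter set with simple round
# numbers, used where the Peru base case would obscure the arithmetic.

simple_econ <- function(...) {
  args <- list(minimum_wage_local = 1000, exchange_rate = 2,
               discount_rate = 0.05, retirement_age = 65,
               mean_age_at_death = 60, gdp_per_capita = 5000,
               gdp_multiplier = 3)
  args[names(list(...))] <- list(...)
  do.call(economic_assumptions, args)
}

simple_ps <- function(...) {
  args <- list(
    total_diabetes_population = 100000,
    high_risk_fraction = 0.2,
    baseline_ulcer_prevalence = 0.25,
    effectiveness = c(sub_optimal = 0, standard = 0.4,
                      standard_plus_temp = 0.8),
    p_hospital = 0.4,
    p_amputation_heal = 0.5,
    p_major_given_amputation = 0.6,
    p_debridement_heal = 0.3,
    p_death = 0.2,
    prevention_cost_per_person = c(sub_optimal = 10, standard = 50,
                                   standard_plus_temp = 100),
    cost_wound_management = 100,
    cost_debridement = 1000,
    cost_minor_amputation = 4000,
    cost_major_amputation = 8000,
    economic = simple_econ()
  )
  args[names(list(...))] <- list(...)
  do.call(parameter_set, args)
}

# Peru base case, loaded once per test run
peru <- peru_2012_fixture()
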
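#' @title Synthetic scenarios
#' @description Seeded generation of random, internally consistent parameter
#'   sets so every pipeline stage can be property-tested without external
#'   data, plus the bundled Peru-2012 base case.
#' @name synthetic
NULL

#' Specify a synthetic-scenario generator
#'
#' Controls for [generate_parameter_set()]. Defaults emulate the scale of the
#' base-case analysis: a national type-2-diabetes population in the hundreds
#' of thousands to low millions, ulcer prevalence in the tens of percent,
#' hospital endpoint probabilities drawn on the simplex, strategy
#' effectiveness and prevention costs increasing with intensity, and
#' plus/minus 30 % auto-generated sensitivity bounds.
#'
#' @param seed integer; fixes the entire draw (Mersenne-Twister via
#'   [set.seed()]).
#' @param population_range `c(min, max)` persons with diabetes.
#' @param high_risk_range `c(min, max)` high-risk fraction.
#' @param prevalence_range `c(min, max)` baseline ulcer prevalence.
#' @param effectiveness_range `c(min, max)` pooled range from which the two
#'   active strategies' effectiveness values are drawn (then ordered).
#' @param branch_probability_concentration Dirichlet-style concentration for
#'   the hospital endpoint simplex (gamma shape of the normalized draws);
#'   larger means closer to uniform thirds.
#' @param cost_ranges named list of `c(min, max)` US$ for `prevention`
#'   (per person), `wound_management`, `debridement`, `minor_amputation`,
#'   `major_amputation`.
#' @param range_halfwidth half-width of auto-generated sensitivity ranges.
#' @param ordered_strategies if `TRUE` (default) the generated scenario keeps
#'   the base-case regime: more intensive strategies are both more effective
#'   and more expensive; set `FALSE` to allow dominated configurations.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L,
                          population_range = c(2e5, 3e6),
                          high_risk_range = c(0.05, 0.40),
                          prevalence_range = c(0.05, 0.35),
                          effectiveness_range = c(0.20, 0.90),
                          branch_probability_concentration = 2,
                          cost_ranges = list(
                            prevention = c(20, 600),
                            wound_management = c(30, 300),
                            debridement = c(300, 3000),
                            minor_amputation = c(1500, 12000),
                            major_amputation = c(3000, 20000)
                          ),
                          range_halfwidth = 0.30,
                          ordered_strategies = TRUE) {
  ranges_ok <- vapply(c(list(population_range, high_risk_range,
                             prevalence_range, effectiveness_range),
                        cost_ranges),
                      function(r) is.numeric(r) && length(r) == 2L &&
                        r[1] <= r[2], TRUE)
  if (!all(ranges_ok)) stop("every (min, max) must satisfy min <= max",
                            call. = FALSE)
  structure(
    list(seed = as.integer(seed),
         population_range = population_range,
         high_risk_range = high_risk_range,
         prevalence_range = prevalence_range,
         effectiveness_range = effectiveness_range,
         branch_probability_concentration = branch_probability_concentration,
         cost_ranges = cost_ranges,
         range_halfwidth = range_halfwidth,
         ordered_strategies = ordered_strategies),
    class = "scenario_spec"
  )
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Generate a random, internally consistent parameter set
#'
#' Draws a scenario that passes [validate_parameters()] by construction:
#' hospital/outpatient complementary, the hospital endpoint triplet sampled
#' on the simplex by normalizing positive gamma draws, major/minor
#' amputation shares complementary, the two active strategies' effectiveness
#' ordered (unless `ordered_strategies = FALSE`), and every sensitivity
#' range bracketing its point estimate (probability ranges clipped to
#' \[0, 1\]).
#'
#' @param spec a [scenario_spec()].
#' @return a validated `parameter_set`.
#' @export
#' @examples
#' ps1 <- generate_parameter_set(scenario_spec(seed = 42))
#' ps2 <- generate_parameter_set(scenario_spec(seed = 42))
#' identical(ps1, ps2)  # TRUE
generate_parameter_set <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  pop <- round(runif1(spec$population_range))
  hr <- runif1(spec$high_risk_range)
  baseline <- runif1(spec$prevalence_range)

  effs <- sort(stats::runif(2, spec$effectiveness_range[1],
                            spec$effectiveness_range[2]))
  if (!spec$ordered_strategies) effs <- sample(effs)
  effectiveness <- c(sub_optimal = 0, standard = effs[1],
                     standard_plus_temp = effs[2])

  p_hosp <- stats::runif(1, 0.1, 0.6)
  # hospital endpoint simplex: normalized gamma draws (Dirichlet)
  g <- stats::rgamma(3, shape = spec$branch_probability_concentration)
  simplex <- g / sum(g)
  p_major <- stats::runif(1, 0.3, 0.7)

  pc <- sort(stats::runif(3, spec$cost_ranges$prevention[1],
                          spec$cost_ranges$prevention[2]))
  if (!spec$ordered_strategies) pc <- sample(pc)
  prevention <- c(sub_optimal = pc[1], standard = pc[2],
                  standard_plus_temp = pc[3])

  costs <- vapply(c("wound_management", "debridement", "minor_amputation",
                    "major_amputation"),
                  function(nm) runif1(spec$cost_ranges[[nm]]), 0)

  econ <- economic_assumptions(
    minimum_wage_local = stats::runif(1, 300, 3000),
    exchange_rate = stats::runif(1, 0.5, 10),
    discount_rate = stats::runif(1, 0, 0.10),
    retirement_age = 65,
    mean_age_at_death = stats::runif(1, 55, 64),
    gdp_per_capita = stats::runif(1, 1000, 30000),
    gdp_multiplier = 3
  )

  hw <- spec$range_halfwidth
  prob_range <- function(p) pmin(pmax(default_range(p, hw), 0), 1)
  ranges <- list(
    baseline_ulcer_prevalence = prob_range(baseline),
    effectiveness_standard = prob_range(effectiveness[["standard"]]),
    effectiveness_standard_plus_temp =
      prob_range(effectiveness[["standard_plus_temp"]]),
    p_hospital = prob_range(p_hosp),
    p_amputation_heal = prob_range(simplex[1]),
    p_debridement_heal = prob_range(simplex[2]),
    prevention_sub_optimal = default_range(prevention[["sub_optimal"]], hw),
    prevention_standard = default_range(prevention[["standard"]], hw),
    prevention_standard_plus_temp =
      default_range(prevention[["standard_plus_temp"]], hw),
    cost_major_amputation = default_range(unname(costs["major_amputation"]), hw)
  )

  parameter_set(
    total_diabetes_population = pop,
    high_risk_fraction = hr,
    baseline_ulcer_prevalence = baseline,
    effectiveness = effectiveness,
    p_hospital = p_hosp,
    p_amputation_heal = simplex[1],
    p_major_given_amputation = p_major,
    p_debridement_heal = simplex[2],
    p_death = simplex[3],
    prevention_cost_per_person = prevention,
    cost_wound_management = unname(costs["wound_management"]),
    cost_debridement = unname(costs["debridement"]),
    cost_minor_amputation = unname(costs["minor_amputation"]),
    cost_major_amputation = unname(costs["major_amputation"]),
    economic = econ,
    ranges = ranges
  )
}

#' The Peru-2012 base-case parameter set
#'
#' Loads the bundled configuration of the base-case analysis: the 2012
#' Peruvian type-2-diabetes population, the high-risk (severe neuropathy)
#' fraction, trial-anchored ulcer prevalence and strategy effectiveness,
#' Brazilian-cohort hospital outcome probabilities, local prevention and
#' treatment unit costs, wage/exchange/discount assumptions, and the
#' published sensitivity ranges. Byte-identical across calls.
#'
#' @return a validated `parameter_set`.
#' @export
#' @examples
#' ps <- peru_2012_fixture()
#' ps$total_diabetes_population  # 942000
peru_2012_fixture <- function() {
  load_parameters(system.file("extdata", "peru_2012.yaml",
                              package = "footcea", mustWork = TRUE))
}
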
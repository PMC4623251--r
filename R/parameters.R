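#' @title Model parameter sets
#' @description Constructors, validation and derivations for the full
#'   epidemiological and economic parameter set of the diabetic-foot
#'   decision-tree model.
#' @name parameters
NULL

#' Strategy identifiers
#'
#' The three secondary-prevention strategies compared by the model:
#' `sub_optimal` (usual care, the comparator), `standard` (guideline-based
#' foot care), and `standard_plus_temp` (standard care plus daily
#' self-monitoring of foot skin temperature).
#'
#' @return character vector of the three strategy ids, in increasing order of
#'   intensity.
#' @export
strategies <- function() c("sub_optimal", "standard", "standard_plus_temp")

match_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1L ||
      !strategy %in% strategies()) {
    stop("unknown strategy: ", paste(format(strategy), collapse = ", "),
         " (must be one of ", paste(strategies(), collapse = ", "), ")",
         call. = FALSE)
  }
  strategy
}

#' Economic assumptions
#'
#' Wage, currency, discounting and threshold assumptions used for indirect
#' costs (human-capital valuation of premature death) and the GDP-multiple
#' cost-effectiveness threshold.
#'
#' @param minimum_wage_local monthly minimum wage in local currency (PEN/month).
#' @param exchange_rate local currency units per US$ (PEN per US$).
#' @param discount_rate annual discount rate as a proportion (e.g. 0.03).
#' @param retirement_age retirement age in years.
#' @param mean_age_at_death mean age at premature death in years.
#' @param gdp_per_capita GDP per capita in US$.
#' @param gdp_multiplier multiple of GDP per capita defining the
#'   willingness-to-pay threshold (conventionally 3).
#' @return an object of class `economic_assumptions`.
#' @export
economic_assumptions <- function(minimum_wage_local,
                                 exchange_rate,
                                 discount_rate,
                                 retirement_age,
                                 mean_age_at_death,
                                 gdp_per_capita,
                                 gdp_multiplier = 3) {
  econ <- structure(
    list(
      minimum_wage_local = minimum_wage_local,
      exchange_rate = exchange_rate,
      discount_rate = discount_rate,
      retirement_age = retirement_age,
      mean_age_at_death = mean_age_at_death,
      gdp_per_capita = gdp_per_capita,
      gdp_multiplier = gdp_multiplier
    ),
    class = "economic_assumptions"
  )
  problems <- validate_economic(econ)
  if (length(problems)) {
    stop("invalid economic assumptions:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  econ
}

validate_economic <- function(econ) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(econ$exchange_rate) && econ$exchange_rate > 0,
      "exchange_rate must be > 0")
  chk(is.numeric(econ$discount_rate) && econ$discount_rate >= 0 &&
        econ$discount_rate < 1,
      "discount_rate must be in [0, 1)")
  chk(is.numeric(econ$minimum_wage_local) && econ$minimum_wage_local >= 0,
      "minimum_wage_local must be >= 0")
  chk(is.numeric(econ$retirement_age) && is.numeric(econ$mean_age_at_death) &&
        econ$retirement_age > econ$mean_age_at_death,
      "retirement_age must exceed mean_age_at_death")
  chk(is.numeric(econ$gdp_per_capita) && econ$gdp_per_capita >= 0,
      "gdp_per_capita must be >= 0")
  chk(is.numeric(econ$gdp_multiplier) && econ$gdp_multiplier > 0,
      "gdp_multiplier must be > 0")
  problems
}

#' Construct a parameter set
#'
#' Assembles and validates the full parameter set of the model: cohort size,
#' branch probabilities of the decision tree, strategy effectiveness,
#' per-person prevention costs, per-episode treatment costs, economic
#' assumptions, and low/high ranges for one-way sensitivity analysis.
#'
#' Probability complements may be omitted and are filled in:
#' `p_outpatient = 1 - p_hospital` and
#' `p_minor_given_amputation = 1 - p_major_given_amputation`.
#'
#' @param total_diabetes_population persons with type 2 diabetes.
#' @param high_risk_fraction proportion of them at high risk of ulceration.
#' @param baseline_ulcer_prevalence one-year ulcer prevalence in the high-risk
#'   group under the sub-optimal (comparator) strategy.
#' @param effectiveness named numeric vector over [strategies()]: proportional
#'   reduction of the baseline ulcer prevalence achieved by each strategy
#'   (0 for the comparator).
#' @param p_hospital probability an ulcerated patient is hospitalized.
#' @param p_outpatient probability of outpatient wound management
#'   (complement of `p_hospital`).
#' @param p_amputation_heal probability a hospitalized patient heals after
#'   amputation.
#' @param p_major_given_amputation probability an amputation is major
#'   (above-ankle).
#' @param p_minor_given_amputation complement of `p_major_given_amputation`.
#' @param p_debridement_heal probability a hospitalized patient heals with
#'   debridement only.
#' @param p_death probability a hospitalized patient dies after amputation.
#' @param prevention_cost_per_person named numeric vector over [strategies()]:
#'   annual prevention cost per high-risk person, US$.
#' @param cost_wound_management,cost_debridement,cost_minor_amputation,cost_major_amputation
#'   per-episode treatment unit costs, US$.
#' @param economic an [economic_assumptions()] object.
#' @param ranges named list of `c(low, high)` sensitivity ranges; each name
#'   must be a perturbable parameter (see [run_owsa()]).
#' @param prevention_cost_display optional named vector of rounded per-person
#'   prevention costs kept for display only (never used in computation).
#' @return a validated object of class `parameter_set`.
#' @seealso [load_parameters()], [peru_2012_fixture()], [validate_parameters()]
#' @export
parameter_set <- function(total_diabetes_population,
                          high_risk_fraction,
                          baseline_ulcer_prevalence,
                          effectiveness,
                          p_hospital,
                          p_outpatient = NULL,
                          p_amputation_heal,
                          p_major_given_amputation,
                          p_minor_given_amputation = NULL,
                          p_debridement_heal,
                          p_death,
                          prevention_cost_per_person,
                          cost_wound_management,
                          cost_debridement,
                          cost_minor_amputation,
                          cost_major_amputation,
                          economic,
                          ranges = list(),
                          prevention_cost_display = NULL) {
  p_outpatient <- p_outpatient %||% (1 - p_hospital)
  p_minor_given_amputation <- p_minor_given_amputation %||%
    (1 - p_major_given_amputation)
  effectiveness <- effectiveness[strategies()]
  prevention_cost_per_person <- prevention_cost_per_person[strategies()]
  ps <- structure(
    list(
      total_diabetes_population = total_diabetes_population,
      high_risk_fraction = high_risk_fraction,
      baseline_ulcer_prevalence = baseline_ulcer_prevalence,
      effectiveness = effectiveness,
      p_hospital = p_hospital,
      p_outpatient = p_outpatient,
      p_amputation_heal = p_amputation_heal,
      p_major_given_amputation = p_major_given_amputation,
      p_minor_given_amputation = p_minor_given_amputation,
      p_debridement_heal = p_debridement_heal,
      p_death = p_death,
      prevention_cost_per_person = prevention_cost_per_person,
      cost_wound_management = cost_wound_management,
      cost_debridement = cost_debridement,
      cost_minor_amputation = cost_minor_amputation,
      cost_major_amputation = cost_major_amputation,
      economic = economic,
      ranges = ranges,
      prevention_cost_display = prevention_cost_display
    ),
    class = "parameter_set"
  )
  problems <- validate_parameters(ps)
  if (length(problems)) {
    stop("invalid parameter set:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  ps
}

#' Validate a parameter set
#'
#' Checks every structural constraint of the model in a single pass and
#' returns all violations, not just the first: proportions in \[0, 1\], costs
#' and counts non-negative, the three sum-to-one branch constraints
#' (hospital/outpatient, amputation-heal/debridement-heal/death,
#' major/minor amputation, each to 1e-9), and every sensitivity range
#' bracketing its point estimate.
#'
#' @param ps a `parameter_set` (possibly not yet known to be valid).
#' @param tol tolerance for the sum-to-one constraints.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_parameters <- function(ps, tol = 1e-9) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  prop_fields <- c("high_risk_fraction", "baseline_ulcer_prevalence",
                   "p_hospital", "p_outpatient", "p_amputation_heal",
                   "p_major_given_amputation", "p_minor_given_amputation",
                   "p_debridement_heal", "p_death")
  for (f in prop_fields) {
    v <- ps[[f]]
    chk(is.numeric(v) && length(v) == 1L && !is.na(v) && v >= 0 && v <= 1,
        sprintf("%s must be a proportion in [0, 1] (got %s)", f,
                paste(format(v), collapse = ",")))
  }
  chk(is.numeric(ps$total_diabetes_population) &&
        ps$total_diabetes_population >= 0,
      "total_diabetes_population must be a count >= 0")

  eff <- ps$effectiveness
  chk(is.numeric(eff) && length(eff) == 3L &&
        identical(names(eff), strategies()) && !anyNA(eff),
      "effectiveness must be a named vector over the three strategies")
  if (is.numeric(eff) && !anyNA(eff)) {
    chk(all(eff >= 0 & eff <= 1), "all effectiveness values must be in [0, 1]")
  }

  prev <- ps$prevention_cost_per_person
  chk(is.numeric(prev) && length(prev) == 3L &&
        identical(names(prev), strategies()) && !anyNA(prev),
      "prevention_cost_per_person must be a named vector over the three strategies")
  if (is.numeric(prev) && !anyNA(prev)) {
    chk(all(prev >= 0), "prevention costs must be >= 0")
  }
  for (f in c("cost_wound_management", "cost_debridement",
              "cost_minor_amputation", "cost_major_amputation")) {
    chk(is.numeric(ps[[f]]) && length(ps[[f]]) == 1L && !is.na(ps[[f]]) &&
          ps[[f]] >= 0,
        sprintf("%s must be a cost >= 0", f))
  }

  num_ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  if (num_ok(ps$p_hospital) && num_ok(ps$p_outpatient)) {
    chk(abs(ps$p_hospital + ps$p_outpatient - 1) <= tol,
        "p_hospital + p_outpatient must sum to 1")
  }
  if (num_ok(ps$p_amputation_heal) && num_ok(ps$p_debridement_heal) &&
      num_ok(ps$p_death)) {
    chk(abs(ps$p_amputation_heal + ps$p_debridement_heal + ps$p_death - 1) <= tol,
        "p_amputation_heal + p_debridement_heal + p_death must sum to 1")
  }
  if (num_ok(ps$p_major_given_amputation) && num_ok(ps$p_minor_given_amputation)) {
    chk(abs(ps$p_major_given_amputation + ps$p_minor_given_amputation - 1) <= tol,
        "p_major_given_amputation + p_minor_given_amputation must sum to 1")
  }

  chk(inherits(ps$economic, "economic_assumptions"),
      "economic must be an economic_assumptions object")
  if (inherits(ps$economic, "economic_assumptions")) {
    problems <- c(problems, validate_economic(ps$economic))
  }

  if (length(ps$ranges)) {
    chk(!is.null(names(ps$ranges)) && all(nzchar(names(ps$ranges))),
        "every sensitivity range must be named")
    for (nm in names(ps$ranges)) {
      rng <- ps$ranges[[nm]]
      if (!is.numeric(rng) || length(rng) != 2L || anyNA(rng)) {
        problems <- c(problems,
                      sprintf("range for %s must be a numeric pair (low, high)", nm))
        next
      }
      point <- tryCatch(parameter_value(ps, nm), error = function(e) NA_real_)
      if (is.na(point)) {
        problems <- c(problems,
                      sprintf("range refers to unknown parameter: %s", nm))
      } else {
        chk(rng[1] <= point + tol && point <= rng[2] + tol,
            sprintf("range for %s (%g, %g) must bracket the point estimate %g",
                    nm, rng[1], rng[2], point))
      }
    }
  }
  problems
}

#' Back-calculate the baseline ulcer prevalence
#'
#' The comparator-strategy (sub-optimal care) ulcer prevalence is not observed
#' directly; it is anchored by a trial prevalence observed under a strategy of
#' known effectiveness: `baseline = reference_prevalence /
#' (1 - reference_effectiveness)`. The result is kept at full precision;
#' two-decimal percentages are presentation rounding.
#'
#' @param reference_prevalence ulcer prevalence observed under the reference
#'   strategy, proportion in \[0, 1\].
#' @param reference_effectiveness proportional prevalence reduction of the
#'   reference strategy relative to baseline, in \[0, 1).
#' @return the baseline prevalence, a proportion.
#' @export
#' @examples
#' derive_baseline_prevalence(0.122, 0.45)  # 0.2218182 (22.18 %)
derive_baseline_prevalence <- function(reference_prevalence,
                                       reference_effectiveness) {
  stopifnot_scalar(reference_prevalence, "reference_prevalence")
  stopifnot_scalar(reference_effectiveness, "reference_effectiveness")
  if (reference_prevalence < 0 || reference_prevalence > 1) {
    stop("reference_prevalence must be in [0, 1]", call. = FALSE)
  }
  if (reference_effectiveness < 0 || reference_effectiveness >= 1) {
    stop("reference_effectiveness must be in [0, 1); an effectiveness of 1 ",
         "makes the baseline prevalence undefined (division by zero)",
         call. = FALSE)
  }
  reference_prevalence / (1 - reference_effectiveness)
}

#' Ulcer prevalence under a prevention strategy
#'
#' A strategy of effectiveness e reduces the baseline one-year ulcer
#' prevalence multiplicatively: `baseline * (1 - e)`.
#'
#' @param baseline baseline ulcer prevalence, proportion.
#' @param effectiveness proportional prevalence reduction, in \[0, 1\].
#' @return prevalence under the strategy, in \[0, baseline\].
#' @export
#' @examples
#' strategy_prevalence(0.122 / 0.55, 0.45)  # 0.122
strategy_prevalence <- function(baseline, effectiveness) {
  stopifnot_scalar(baseline, "baseline")
  stopifnot_scalar(effectiveness, "effectiveness")
  if (baseline < 0 || baseline > 1 || effectiveness < 0 || effectiveness > 1) {
    stop("baseline and effectiveness must be proportions in [0, 1]",
         call. = FALSE)
  }
  baseline * (1 - effectiveness)
}

#' Size of the high-risk cohort
#'
#' Persons at high risk of foot ulceration (severe neuropathy):
#' `total_diabetes_population * high_risk_fraction`, at full precision.
#'
#' @param ps a `parameter_set`.
#' @return number of high-risk persons (possibly fractional; presentation
#'   rounding happens only in reports).
#' @export
high_risk_population <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  ps$total_diabetes_population * ps$high_risk_fraction
}

# Point estimate addressed by a sensitivity-range / OWSA parameter name.
# Names: plain parameter_set fields, effectiveness_<strategy>,
# prevention_<strategy>.
parameter_value <- function(ps, name) {
  if (name %in% c("total_diabetes_population", "high_risk_fraction",
                  "baseline_ulcer_prevalence", "p_hospital", "p_outpatient",
                  "p_amputation_heal", "p_major_given_amputation",
                  "p_minor_given_amputation", "p_debridement_heal", "p_death",
                  "cost_wound_management", "cost_debridement",
                  "cost_minor_amputation", "cost_major_amputation")) {
    return(ps[[name]])
  }
  if (grepl("^effectiveness_", name)) {
    s <- match_strategy(sub("^effectiveness_", "", name))
    return(unname(ps$effectiveness[s]))
  }
  if (grepl("^prevention_", name)) {
    s <- match_strategy(sub("^prevention_", "", name))
    return(unname(ps$prevention_cost_per_person[s]))
  }
  stop("unknown parameter name: ", name, call. = FALSE)
}

#' Load a parameter set from a YAML configuration
#'
#' Reads a structured-text configuration with sections `epidemiology`,
#' `strategies`, `treatment_costs`, `economics` and `ranges`, applies the
#' documented derivations, validates, and returns a `parameter_set`.
#'
#' Derivations performed at load time (all optional in the file):
#' * `baseline_ulcer_prevalence` may instead be given by the pair
#'   `reference_prevalence` / `reference_effectiveness`
#'   (see [derive_baseline_prevalence()]).
#' * a strategy's `effectiveness` may instead be given as `target_prevalence`,
#'   back-converted as `1 - target_prevalence / baseline`.
#' * a strategy's `prevention_cost_per_person` may instead be given as
#'   `prevention_cost_total`, divided by the high-risk population.
#' * `p_outpatient` and `p_minor_given_amputation` default to complements.
#'
#' All proportions in the file are decimals (0.219, not 21.9). Monetary
#' amounts are US$ except the economics section's `minimum_wage_local` (PEN).
#'
#' @param config_source path to a YAML file, or an already-parsed nested list
#'   with the same structure.
#' @return a validated `parameter_set`.
#' @export
#' @examples
#' ps <- load_parameters(system.file("extdata", "peru_2012.yaml",
#'                                   package = "footcea"))
#' high_risk_population(ps)  # 206298
load_parameters <- function(config_source) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("configuration file not found: ", config_source, call. = FALSE)
    }
    yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a file path or a list", call. = FALSE)
  }

  need <- function(section, field, value) {
    if (is.null(value)) {
      stop(sprintf("configuration error: missing field `%s` in section `%s`",
                   field, section), call. = FALSE)
    }
    value
  }
  epi <- need("(top level)", "epidemiology", cfg$epidemiology)
  str_cfg <- need("(top level)", "strategies", cfg$strategies)
  tc <- need("(top level)", "treatment_costs", cfg$treatment_costs)
  ec <- need("(top level)", "economics", cfg$economics)

  baseline <- epi$baseline_ulcer_prevalence
  if (is.null(baseline)) {
    baseline <- derive_baseline_prevalence(
      need("epidemiology", "reference_prevalence", epi$reference_prevalence),
      need("epidemiology", "reference_effectiveness", epi$reference_effectiveness)
    )
  }

  pop_total <- need("epidemiology", "total_diabetes_population",
                    epi$total_diabetes_population)
  hr_frac <- need("epidemiology", "high_risk_fraction", epi$high_risk_fraction)
  hr_pop <- pop_total * hr_frac

  eff <- numeric(0)
  prev_cost <- numeric(0)
  prev_disp <- numeric(0)
  for (s in strategies()) {
    sc <- need("strategies", s, str_cfg[[s]])
    e <- sc$effectiveness
    if (is.null(e)) {
      tp <- need(paste0("strategies/", s),
                 "effectiveness (or target_prevalence)", sc$target_prevalence)
      if (baseline <= 0) {
        stop("target_prevalence requires a positive baseline prevalence",
             call. = FALSE)
      }
      e <- 1 - tp / baseline
    }
    eff[s] <- e
    pc <- sc$prevention_cost_per_person
    if (is.null(pc)) {
      tot <- need(paste0("strategies/", s),
                  "prevention_cost_per_person (or prevention_cost_total)",
                  sc$prevention_cost_total)
      if (hr_pop <= 0) {
        stop("prevention_cost_total requires a positive high-risk population",
             call. = FALSE)
      }
      pc <- tot / hr_pop
    }
    prev_cost[s] <- pc
    prev_disp[s] <- sc$prevention_cost_display %||% NA_real_
  }

  econ <- economic_assumptions(
    minimum_wage_local = need("economics", "minimum_wage_local",
                              ec$minimum_wage_local),
    exchange_rate = need("economics", "exchange_rate", ec$exchange_rate),
    discount_rate = need("economics", "discount_rate", ec$discount_rate),
    retirement_age = need("economics", "retirement_age", ec$retirement_age),
    mean_age_at_death = need("economics", "mean_age_at_death",
                             ec$mean_age_at_death),
    gdp_per_capita = need("economics", "gdp_per_capita", ec$gdp_per_capita),
    gdp_multiplier = ec$gdp_multiplier %||% 3
  )

  ranges <- lapply(cfg$ranges %||% list(), function(r) as.numeric(unlist(r)))

  parameter_set(
    total_diabetes_population = pop_total,
    high_risk_fraction = hr_frac,
    baseline_ulcer_prevalence = baseline,
    effectiveness = eff,
    p_hospital = need("epidemiology", "p_hospital", epi$p_hospital),
    p_outpatient = epi$p_outpatient,
    p_amputation_heal = need("epidemiology", "p_amputation_heal",
                             epi$p_amputation_heal),
    p_major_given_amputation = need("epidemiology", "p_major_given_amputation",
                                    epi$p_major_given_amputation),
    p_minor_given_amputation = epi$p_minor_given_amputation,
    p_debridement_heal = need("epidemiology", "p_debridement_heal",
                              epi$p_debridement_heal),
    p_death = need("epidemiology", "p_death", epi$p_death),
    prevention_cost_per_person = prev_cost,
    cost_wound_management = need("treatment_costs", "wound_management",
                                 tc$wound_management),
    cost_debridement = need("treatment_costs", "debridement", tc$debridement),
    cost_minor_amputation = need("treatment_costs", "minor_amputation",
                                 tc$minor_amputation),
    cost_major_amputation = need("treatment_costs", "major_amputation",
                                 tc$major_amputation),
    economic = econ,
    ranges = ranges,
    prevention_cost_display = if (!all(is.na(prev_disp))) prev_disp else NULL
  )
}

#' Serialize a parameter set back to the configuration structure
#'
#' Inverse of [load_parameters()]: produces the nested list form of the
#' configuration, suitable for `yaml::write_yaml()`. Loading the result yields
#' an identical parameter set (round-trip identity).
#'
#' @param ps a `parameter_set`.
#' @return nested list mirroring the configuration schema.
#' @export
as_config <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  strategies_cfg <- lapply(strategies(), function(s) {
    out <- list(
      effectiveness = unname(ps$effectiveness[s]),
      prevention_cost_per_person = unname(ps$prevention_cost_per_person[s])
    )
    if (!is.null(ps$prevention_cost_display) &&
        !is.na(ps$prevention_cost_display[s])) {
      out$prevention_cost_display <- unname(ps$prevention_cost_display[s])
    }
    out
  })
  names(strategies_cfg) <- strategies()
  list(
    epidemiology = list(
      total_diabetes_population = ps$total_diabetes_population,
      high_risk_fraction = ps$high_risk_fraction,
      baseline_ulcer_prevalence = ps$baseline_ulcer_prevalence,
      p_hospital = ps$p_hospital,
      p_outpatient = ps$p_outpatient,
      p_amputation_heal = ps$p_amputation_heal,
      p_major_given_amputation = ps$p_major_given_amputation,
      p_minor_given_amputation = ps$p_minor_given_amputation,
      p_debridement_heal = ps$p_debridement_heal,
      p_death = ps$p_death
    ),
    strategies = strategies_cfg,
    treatment_costs = list(
      wound_management = ps$cost_wound_management,
      debridement = ps$cost_debridement,
      minor_amputation = ps$cost_minor_amputation,
      major_amputation = ps$cost_major_amputation
    ),
    economics = unclass(ps$economic),
    ranges = lapply(ps$ranges, as.numeric)
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  diabetes population: %s; high-risk fraction: %.1f %% (%s persons)\n",
              format(x$total_diabetes_population, big.mark = ","),
              100 * x$high_risk_fraction,
              format(round_half_up(high_risk_population(x)), big.mark = ",")))
  cat(sprintf("  baseline ulcer prevalence: %.2f %%\n",
              100 * x$baseline_ulcer_prevalence))
  for (s in strategies()) {
    cat(sprintf("  %-22s effectiveness %5.2f %% -> prevalence %5.2f %%; prevention US$%.2f/person\n",
                s, 100 * x$effectiveness[s],
                100 * strategy_prevalence(x$baseline_ulcer_prevalence,
                                          x$effectiveness[s]),
                x$prevention_cost_per_person[s]))
  }
  cat(sprintf("  branch probabilities: hospital %.3f / outpatient %.3f; amputation-heal %.4f (major %.3f), debridement-heal %.4f, death %.3f\n",
              x$p_hospital, x$p_outpatient, x$p_amputation_heal,
              x$p_major_given_amputation, x$p_debridement_heal, x$p_death))
  cat(sprintf("  sensitivity ranges for %d parameters\n", length(x$ranges)))
  invisible(x)
}
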
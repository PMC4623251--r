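#' @title Cost of illness
#' @description Ingredients-based direct costing of prevention and treatment,
#'   and human-capital valuation of premature death.
#' @name costing
NULL

# Canonical endpoint labels, matching the cost-of-illness table rows.
endpoint_labels <- function() {
  c(debridement = "Healing with debridement",
    heal_major = "Healing with major amputation",
    heal_minor = "Healing with minor amputation",
    death_major = "Death with major amputation",
    death_minor = "Death with minor amputation",
    outpatient_wound = "Healing with outpatient visit")
}

#' Build a cost bundle from ingredient lines
#'
#' An ingredients-based unit cost is assembled from resource lines, each a
#' quantity times a unit price (consultations, bed-days, tests, drugs,
#' supplies, rehabilitation sessions and so on).
#'
#' @param name bundle name (e.g. "debridement", "major amputation").
#' @param lines data.frame with columns `label`, `quantity`, `unit_price`
#'   (US$); may have zero rows.
#' @return object of class `cost_bundle`.
#' @export
cost_bundle <- function(name, lines) {
  stopifnot(is.character(name), nzchar(name))
  if (is.null(lines) || nrow(lines) == 0L) {
    lines <- data.frame(label = character(), quantity = numeric(),
                        unit_price = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "quantity", "unit_price") %in% names(lines)))
  if (any(lines$quantity < 0) || any(lines$unit_price < 0)) {
    stop("ingredient quantities and unit prices must be >= 0", call. = FALSE)
  }
  structure(list(name = name, lines = lines), class = "cost_bundle")
}

#' Unit cost of a bundle
#'
#' Sum of quantity times unit price over the ingredient lines.
#'
#' @param bundle a `cost_bundle`.
#' @return unit cost in US$.
#' @export
unit_cost_from_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "cost_bundle"))
  if (nrow(bundle$lines) == 0L) return(0)
  sum(bundle$lines$quantity * bundle$lines$unit_price)
}

#' Load the bundled ingredient bundles
#'
#' Reads the resource bundles shipped with the package (outpatient wound
#' management, debridement, minor/major amputation). Line items are
#' synthetic illustrations calibrated so each bundle's total equals the
#' published aggregate unit cost; the aggregate, not the line prices, is what
#' the model consumes.
#'
#' @param path CSV of ingredient lines; defaults to the installed fixture.
#' @return named list of `cost_bundle` objects.
#' @export
load_cost_bundles <- function(path = system.file("extdata",
                                                 "cost_bundles_synthetic.csv",
                                                 package = "footcea")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bundle", "label", "quantity", "unit_price") %in% names(df)))
  out <- lapply(split(df, df$bundle), function(d) {
    cost_bundle(d$bundle[1], d[c("label", "quantity", "unit_price")])
  })
  out[unique(df$bundle)]
}

#' Total prevention cost of a strategy
#'
#' Prevention is delivered to the entire high-risk cohort regardless of
#' clinical endpoint: cohort size times the per-person annual cost.
#'
#' @param ps a `parameter_set`.
#' @param strategy one of [strategies()].
#' @return total prevention cost, US$.
#' @export
prevention_cost <- function(ps, strategy) {
  stopifnot(inherits(ps, "parameter_set"))
  strategy <- match_strategy(strategy)
  high_risk_population(ps) * unname(ps$prevention_cost_per_person[strategy])
}

#' Treatment cost by clinical endpoint
#'
#' Persons at each terminal node times the per-episode unit cost. Patients
#' who die are costed at the amputation admission they underwent (major death
#' at the major-amputation cost, minor death at the minor-amputation cost);
#' there is no additional death-specific cost.
#'
#' @param flows a `cohort_flows` object.
#' @param ps the `parameter_set` the flows were computed from.
#' @return named numeric vector of endpoint costs (US$) with names
#'   `debridement`, `heal_major`, `heal_minor`, `death_major`, `death_minor`,
#'   `outpatient_wound`.
#' @export
treatment_cost <- function(flows, ps) {
  stopifnot(inherits(flows, "cohort_flows"), inherits(ps, "parameter_set"))
  c(debridement = flows$n_debridement_heal * ps$cost_debridement,
    heal_major = flows$n_heal_major_amputation * ps$cost_major_amputation,
    heal_minor = flows$n_heal_minor_amputation * ps$cost_minor_amputation,
    death_major = flows$n_death_major_amputation * ps$cost_major_amputation,
    death_minor = flows$n_death_minor_amputation * ps$cost_minor_amputation,
    outpatient_wound = flows$n_outpatient_heal * ps$cost_wound_management)
}

#' Indirect cost of one premature death (human-capital approach)
#'
#' Values the productive years lost between the mean age at death and the
#' retirement age at the minimum wage, discounted as an annuity-due: the
#' first lost year is undiscounted, each further year is discounted once.
#' With monthly wage w (local currency), exchange rate x, discount rate r and
#' L = retirement_age - mean_age_at_death years lost:
#' \deqn{\sum_{t=0}^{L-1} \frac{12\, w / x}{(1+r)^t}}
#'
#' @param econ an [economic_assumptions()] object.
#' @return present value of lost earnings per death, US$.
#' @export
#' @examples
#' econ <- economic_assumptions(750, 2.64, 0.03, 65, 63, 6568)
#' indirect_cost_per_death(econ)  # 6718.888 -> US$6,719
indirect_cost_per_death <- function(econ) {
  stopifnot(inherits(econ, "economic_assumptions"))
  years_lost <- econ$retirement_age - econ$mean_age_at_death
  if (years_lost <= 0) {
    warning("no productive years lost; indirect cost is 0")
    return(0)
  }
  annual <- (econ$minimum_wage_local / econ$exchange_rate) * 12
  sum(annual / (1 + econ$discount_rate)^(seq_len(years_lost) - 1))
}

#' Full cost breakdown of one strategy
#'
#' Composes [compute_flows()], [prevention_cost()], [treatment_cost()] and
#' [indirect_cost_per_death()] into the strategy's complete cost-of-illness
#' account: prevention, per-endpoint treatment, direct total, and indirect
#' (productivity-loss) total.
#'
#' @param ps a `parameter_set`.
#' @param strategy one of [strategies()].
#' @return object of class `cost_breakdown`: list with `strategy`,
#'   `prevention_total`, `treatment_by_endpoint`, `treatment_total`,
#'   `direct_total`, `indirect_total`, and the underlying `flows`.
#' @export
#' @examples
#' cb <- total_direct_cost(peru_2012_fixture(), "sub_optimal")
#' round_half_up(cb$direct_total / 1e6, 1)  # 74.5
total_direct_cost <- function(ps, strategy) {
  stopifnot(inherits(ps, "parameter_set"))
  strategy <- match_strategy(strategy)
  flows <- compute_flows(ps, strategy)
  by_endpoint <- treatment_cost(flows, ps)
  prevention_total <- prevention_cost(ps, strategy)
  treatment_total <- sum(by_endpoint)
  deaths <- summarize_outcomes(flows)$deaths
  structure(
    list(
      strategy = strategy,
      prevention_total = prevention_total,
      treatment_by_endpoint = by_endpoint,
      treatment_total = treatment_total,
      direct_total = prevention_total + treatment_total,
      indirect_total = deaths * indirect_cost_per_death(ps$economic),
      flows = flows
    ),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown: %s>\n", x$strategy))
  cat(sprintf("  prevention  US$ %15s\n",
              format(round_half_up(x$prevention_total), big.mark = ",")))
  for (ep in names(x$treatment_by_endpoint)) {
    cat(sprintf("  %-17s US$ %13s\n", ep,
                format(round_half_up(x$treatment_by_endpoint[[ep]]),
                       big.mark = ",")))
  }
  cat(sprintf("  treatment   US$ %15s\n",
              format(round_half_up(x$treatment_total), big.mark = ",")))
  cat(sprintf("  direct total US$ %14s  (indirect US$ %s)\n",
              format(round_half_up(x$direct_total), big.mark = ","),
              format(round_half_up(x$indirect_total), big.mark = ",")))
  invisible(x)
}
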
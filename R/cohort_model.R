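#' @title Decision-tree cohort model
#' @description One-year closed-cohort evaluation of the diabetic-foot
#'   decision tree: ulceration, care setting (outpatient vs hospital), and
#'   clinical endpoint (debridement heal, amputation heal, death).
#' @name cohort_model
NULL

#' Propagate the high-risk cohort through the decision tree
#'
#' Computes person counts at every node of the tree for one strategy. The
#' high-risk cohort either develops an ulcer (at the strategy's prevalence)
#' or not; ulcerated patients receive either outpatient wound management
#' (healing) or hospital care; hospitalized patients heal with debridement,
#' heal after a minor/major amputation, or die after a minor/major amputation.
#' Every patient who dies is assumed to have undergone an amputation in the
#' same year, so deaths are split major/minor with the same conditional
#' probabilities as healed amputees.
#'
#' Counts are fractional persons kept at full precision; rounding is purely a
#' reporting concern.
#'
#' @param ps a `parameter_set`.
#' @param strategy one of [strategies()].
#' @return an object of class `cohort_flows`: a list with the strategy id,
#'   `population_high_risk`, and the node counts `n_ulcerated`, `n_no_ulcer`,
#'   `n_outpatient_heal`, `n_hospital`, `n_debridement_heal`,
#'   `n_heal_major_amputation`, `n_heal_minor_amputation`,
#'   `n_death_major_amputation`, `n_death_minor_amputation`.
#' @export
#' @examples
#' ps <- peru_2012_fixture()
#' fl <- compute_flows(ps, "sub_optimal")
#' round_half_up(fl$n_ulcerated)  # 45761
compute_flows <- function(ps, strategy) {
  stopifnot(inherits(ps, "parameter_set"))
  strategy <- match_strategy(strategy)
  pop <- high_risk_population(ps)
  prevalence <- strategy_prevalence(ps$baseline_ulcer_prevalence,
                                    unname(ps$effectiveness[strategy]))
  n_ulcerated <- pop * prevalence
  n_hospital <- n_ulcerated * ps$p_hospital
  n_amputation_heal <- n_hospital * ps$p_amputation_heal
  n_death <- n_hospital * ps$p_death
  structure(
    list(
      strategy = strategy,
      population_high_risk = pop,
      n_ulcerated = n_ulcerated,
      n_no_ulcer = pop - n_ulcerated,
      n_outpatient_heal = n_ulcerated * ps$p_outpatient,
      n_hospital = n_hospital,
      n_debridement_heal = n_hospital * ps$p_debridement_heal,
      n_heal_major_amputation = n_amputation_heal * ps$p_major_given_amputation,
      n_heal_minor_amputation = n_amputation_heal * ps$p_minor_given_amputation,
      n_death_major_amputation = n_death * ps$p_major_given_amputation,
      n_death_minor_amputation = n_death * ps$p_minor_given_amputation
    ),
    class = "cohort_flows"
  )
}

#' Summarize clinical outcomes of a strategy
#'
#' Aggregates terminal counts into the model's two health outcomes:
#' deaths (major + minor amputation deaths) and major amputations, where a
#' "major amputation" counts every patient who underwent one, whether they
#' healed or died. Minor amputations are reported the same way.
#'
#' @param flows a `cohort_flows` object.
#' @return list with `deaths`, `major_amputations`, `minor_amputations`
#'   (fractional persons).
#' @export
summarize_outcomes <- function(flows) {
  stopifnot(inherits(flows, "cohort_flows"))
  list(
    deaths = flows$n_death_major_amputation + flows$n_death_minor_amputation,
    major_amputations = flows$n_heal_major_amputation +
      flows$n_death_major_amputation,
    minor_amputations = flows$n_heal_minor_amputation +
      flows$n_death_minor_amputation
  )
}

#' Enumerate every root-to-terminal path of the decision tree
#'
#' Brute-force expansion of the tree used as an independent oracle for
#' [compute_flows()]: each path carries the product of its branch
#' probabilities and the persons reaching its terminal. Path probabilities
#' sum to 1 (law of total probability).
#'
#' @param ps a `parameter_set`.
#' @param strategy one of [strategies()].
#' @return data.frame with columns `path` (slash-separated node labels),
#'   `probability`, `persons`.
#' @export
enumerate_tree_paths <- function(ps, strategy) {
  stopifnot(inherits(ps, "parameter_set"))
  strategy <- match_strategy(strategy)
  pop <- high_risk_population(ps)
  prevalence <- strategy_prevalence(ps$baseline_ulcer_prevalence,
                                    unname(ps$effectiveness[strategy]))

  # (label, conditional probability) children of each node
  ulcer_split <- list(no_ulcer = 1 - prevalence, ulcer = prevalence)
  care_split <- list(outpatient_heal = ps$p_outpatient,
                     hospital = ps$p_hospital)
  endpoint_split <- list(debridement_heal = ps$p_debridement_heal,
                         amputation_heal = ps$p_amputation_heal,
                         death = ps$p_death)
  amp_split <- list(major = ps$p_major_given_amputation,
                    minor = ps$p_minor_given_amputation)

  paths <- list()
  add <- function(labels, prob) {
    paths[[length(paths) + 1L]] <<- data.frame(
      path = paste(labels, collapse = "/"),
      probability = prob,
      stringsAsFactors = FALSE
    )
  }

  add("no_ulcer", ulcer_split$no_ulcer)
  add(c("ulcer", "outpatient_heal"),
      ulcer_split$ulcer * care_split$outpatient_heal)
  for (ep in names(endpoint_split)) {
    p_ep <- ulcer_split$ulcer * care_split$hospital * endpoint_split[[ep]]
    if (ep == "debridement_heal") {
      add(c("ulcer", "hospital", ep), p_ep)
    } else {
      for (amp in names(amp_split)) {
        add(c("ulcer", "hospital", ep, amp), p_ep * amp_split[[amp]])
      }
    }
  }
  out <- do.call(rbind, paths)
  out$persons <- out$probability * pop
  out
}

#' @export
print.cohort_flows <- function(x, ...) {
  cat(sprintf("<cohort_flows: %s>\n", x$strategy))
  nodes <- c("population_high_risk", "n_ulcerated", "n_no_ulcer",
             "n_outpatient_heal", "n_hospital", "n_debridement_heal",
             "n_heal_major_amputation", "n_heal_minor_amputation",
             "n_death_major_amputation", "n_death_minor_amputation")
  for (nm in nodes) {
    cat(sprintf("  %-26s %10s\n", nm,
                format(round_half_up(x[[nm]]), big.mark = ",")))
  }
  invisible(x)
}

#' Flows for all strategies as a data.frame
#'
#' Convenience tabulation of [compute_flows()] across the three strategies,
#' one row per (strategy, node), full-precision counts.
#'
#' @param ps a `parameter_set`.
#' @return data.frame with columns `strategy`, `node`, `persons`.
#' @export
flows_table <- function(ps) {
  rows <- lapply(strategies(), function(s) {
    fl <- compute_flows(ps, s)
    nodes <- setdiff(names(fl), "strategy")
    data.frame(strategy = s, node = nodes,
               persons = as.numeric(unlist(fl[nodes])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
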
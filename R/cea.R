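#' @title Incremental cost-effectiveness analysis
#' @description Pairwise strategy comparisons: incremental costs, deaths and
#'   major amputations averted, ICERs, dominance classification and a
#'   GDP-multiple willingness-to-pay threshold.
#' @name cea
NULL

# Dominance classification for one (delta cost, delta effect) pair.
# Returns list(label, icer): exactly one of icer numeric / label in
# {"cost_saving", "dominated", "undefined"} is meaningful; label == "icer"
# signals a reportable numeric ratio.
classify_increment <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    # never divide by zero; equal effects make the ratio meaningless
    label <- if (delta_cost > 0) "dominated" else "undefined"
    return(list(label = label, icer = NA_real_))
  }
  if (delta_cost < 0 && delta_effect > 0) {
    return(list(label = "cost_saving", icer = NA_real_))
  }
  if (delta_cost > 0 && delta_effect < 0) {
    return(list(label = "dominated", icer = NA_real_))
  }
  list(label = "icer", icer = delta_cost / delta_effect)
}

#' Compare two prevention strategies
#'
#' Incremental analysis of `intervention` against `comparator`: differences
#' in total direct cost (and direct + indirect), deaths averted, major
#' amputations averted, and the resulting ICER or dominance label. ICERs are
#' computed from unrounded costs and unrounded deaths averted; an
#' intervention that costs less and averts more deaths is labelled
#' `cost_saving` rather than given a negative ratio, and one that costs more
#' while averting none is `dominated`. Equal effects never produce a division
#' by zero (label `dominated`/`undefined` by the sign of the cost difference).
#'
#' Including indirect costs credits the intervention with the productivity
#' losses its averted deaths avoid.
#'
#' @param ps a `parameter_set`.
#' @param intervention,comparator distinct strategy ids.
#' @param include_indirect if `TRUE` the threshold verdict
#'   (`cost_effective_at_threshold`) is based on the direct + indirect ICER;
#'   both ICERs are always computed.
#' @return object of class `strategy_comparison`: intervention, comparator,
#'   `delta_cost_direct`, `delta_cost_with_indirect`, `deaths_averted`,
#'   `major_amputations_averted`, `icer_direct`, `icer_with_indirect`,
#'   `label_direct`, `label_with_indirect`, `cost_effective_at_threshold`,
#'   `threshold`.
#' @export
#' @examples
#' ps <- peru_2012_fixture()
#' cmp <- compare_strategies(ps, "standard", "sub_optimal")
#' cmp$label_direct                    # "cost_saving"
#' round_half_up(cmp$deaths_averted)   # 791
compare_strategies <- function(ps, intervention, comparator,
                               include_indirect = FALSE) {
  stopifnot(inherits(ps, "parameter_set"))
  intervention <- match_strategy(intervention)
  comparator <- match_strategy(comparator)
  if (identical(intervention, comparator)) {
    stop("intervention and comparator must differ", call. = FALSE)
  }

  cb_i <- total_direct_cost(ps, intervention)
  cb_c <- total_direct_cost(ps, comparator)
  out_i <- summarize_outcomes(cb_i$flows)
  out_c <- summarize_outcomes(cb_c$flows)

  delta_cost_direct <- cb_i$direct_total - cb_c$direct_total
  delta_cost_with_indirect <- (cb_i$direct_total + cb_i$indirect_total) -
    (cb_c$direct_total + cb_c$indirect_total)
  deaths_averted <- out_c$deaths - out_i$deaths
  major_averted <- out_c$major_amputations - out_i$major_amputations

  direct <- classify_increment(delta_cost_direct, deaths_averted)
  with_ind <- classify_increment(delta_cost_with_indirect, deaths_averted)

  active <- if (include_indirect) with_ind else direct
  threshold <- ps$economic$gdp_multiplier * ps$economic$gdp_per_capita
  cost_effective <- if (active$label == "cost_saving") {
    TRUE
  } else if (active$label == "icer") {
    threshold_check(active$icer, ps$economic)
  } else {
    FALSE
  }

  structure(
    list(
      intervention = intervention,
      comparator = comparator,
      include_indirect = include_indirect,
      delta_cost_direct = delta_cost_direct,
      delta_cost_with_indirect = delta_cost_with_indirect,
      deaths_averted = deaths_averted,
      major_amputations_averted = major_averted,
      icer_direct = direct$icer,
      label_direct = direct$label,
      icer_with_indirect = with_ind$icer,
      label_with_indirect = with_ind$label,
      cost_effective_at_threshold = cost_effective,
      threshold = threshold
    ),
    class = "strategy_comparison"
  )
}

#' Willingness-to-pay threshold check
#'
#' An ICER is deemed cost-effective when it does not exceed the configured
#' multiple of GDP per capita (inclusive comparison).
#'
#' @param icer numeric ICER, US$ per death averted.
#' @param econ an [economic_assumptions()] object.
#' @return logical.
#' @export
#' @examples
#' econ <- economic_assumptions(750, 2.64, 0.03, 65, 63, 6568)
#' threshold_check(16124, econ)  # TRUE: 16,124 <= 3 x 6,568
threshold_check <- function(icer, econ) {
  stopifnot(inherits(econ, "economic_assumptions"))
  stopifnot_scalar(icer, "icer")
  icer <= econ$gdp_multiplier * econ$gdp_per_capita
}

#' All pairwise comparisons of the three strategies
#'
#' The three comparisons of the cost-effectiveness table: standard vs
#' sub-optimal, standard-plus-temperature-monitoring vs sub-optimal, and
#' standard-plus-temperature-monitoring vs standard. Each row carries both
#' the direct-cost and the direct + indirect results.
#'
#' @param ps a `parameter_set`.
#' @return list of `strategy_comparison` objects, named
#'   `"<intervention> vs <comparator>"`.
#' @export
full_comparison_table <- function(ps) {
  pairs <- list(c("standard", "sub_optimal"),
                c("standard_plus_temp", "sub_optimal"),
                c("standard_plus_temp", "standard"))
  out <- lapply(pairs, function(p) compare_strategies(ps, p[1], p[2]))
  names(out) <- vapply(pairs, function(p) paste(p[1], "vs", p[2]), "")
  out
}

format_icer <- function(label, icer) {
  switch(label,
         cost_saving = "Cost-saving",
         dominated = "Dominated",
         undefined = "Undefined",
         icer = sprintf("ICER = %s", format(round_half_up(icer),
                                            big.mark = ",")))
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison: %s vs %s>\n", x$intervention, x$comparator))
  cat(sprintf("  delta cost (direct):            US$ %s\n",
              format(round_half_up(x$delta_cost_direct), big.mark = ",")))
  cat(sprintf("  delta cost (direct + indirect): US$ %s\n",
              format(round_half_up(x$delta_cost_with_indirect), big.mark = ",")))
  cat(sprintf("  deaths averted: %s; major amputations averted: %s\n",
              format(round_half_up(x$deaths_averted), big.mark = ","),
              format(round_half_up(x$major_amputations_averted), big.mark = ",")))
  cat(sprintf("  %s (direct); %s (direct + indirect)\n",
              format_icer(x$label_direct, x$icer_direct),
              format_icer(x$label_with_indirect, x$icer_with_indirect)))
  cat(sprintf("  cost-effective at threshold US$ %s per death averted: %s\n",
              format(x$threshold, big.mark = ","),
              x$cost_effective_at_threshold))
  invisible(x)
}
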
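#' @title One-way deterministic sensitivity analysis
#' @description Vary one parameter at a time across its plausible range,
#'   recompute a comparison outcome, and order parameters by the magnitude of
#'   the outcome swing (tornado ordering).
#' @name sensitivity
NULL

owsa_outcomes <- function() {
  c("icer_direct", "icer_with_indirect", "delta_cost", "deaths_averted")
}

#' Specify a one-way sensitivity analysis
#'
#' @param intervention,comparator strategy ids for the comparison analysed.
#' @param outcome one of `icer_direct`, `icer_with_indirect`, `delta_cost`
#'   (direct by default, with indirect if `include_indirect`), or
#'   `deaths_averted`.
#' @param parameters named list of `c(low, high)` ranges; defaults to every
#'   range configured in the parameter set.
#' @param include_indirect whether `delta_cost` means direct + indirect.
#' @return object of class `owsa_spec`.
#' @export
owsa_spec <- function(intervention, comparator,
                      outcome = "icer_direct",
                      parameters = NULL,
                      include_indirect = FALSE) {
  outcome <- match.arg(outcome, owsa_outcomes())
  structure(
    list(intervention = match_strategy(intervention),
         comparator = match_strategy(comparator),
         outcome = outcome,
         parameters = parameters,
         include_indirect = include_indirect),
    class = "owsa_spec"
  )
}

#' Symmetric sensitivity range around a point estimate
#'
#' The conventional plus/minus band used where published uncertainty ranges
#' are unavailable: `(point * (1 - fraction), point * (1 + fraction))`.
#'
#' @param point non-negative point estimate.
#' @param fraction half-width as a proportion of the point (e.g. 0.30).
#' @return numeric `c(low, high)`.
#' @export
#' @examples
#' default_range(0.30, 0.30)  # c(0.21, 0.39)
default_range <- function(point, fraction) {
  stopifnot_scalar(point, "point")
  stopifnot_scalar(fraction, "fraction")
  if (point < 0 || fraction < 0 || fraction >= 1) {
    stop("need point >= 0 and 0 <= fraction < 1", call. = FALSE)
  }
  c(point * (1 - fraction), point * (1 + fraction))
}

#' Perturb one parameter, keeping the tree consistent
#'
#' Sets a single parameter to `value` and applies the linked-parameter rules
#' that preserve the sum-to-one branch constraints:
#' * `p_hospital` and `p_outpatient` adjust each other's complement;
#' * `p_amputation_heal` holds `p_death` fixed and rebalances
#'   `p_debridement_heal` (and symmetrically for `p_debridement_heal`);
#'   `p_death` rebalances `p_debridement_heal` likewise;
#' * `p_major_given_amputation`/`p_minor_given_amputation` adjust each other;
#' * `baseline_ulcer_prevalence` leaves effectiveness untouched (strategy
#'   prevalences re-derive downstream); `effectiveness_<strategy>` leaves the
#'   baseline untouched;
#' * `prevention_<strategy>` and unit costs set the value directly.
#'
#' The perturbed set is re-validated; a violated hard constraint (e.g. a
#' rebalanced probability falling below 0) raises an error rather than being
#' clamped.
#'
#' @param ps a `parameter_set`.
#' @param name parameter name (see above).
#' @param value new value.
#' @return a validated, perturbed `parameter_set`.
#' @export
perturb_parameter <- function(ps, name, value) {
  stopifnot(inherits(ps, "parameter_set"))
  stopifnot_scalar(value, name)
  raw <- unclass(ps)
  if (name %in% c("total_diabetes_population", "high_risk_fraction",
                  "baseline_ulcer_prevalence",
                  "cost_wound_management", "cost_debridement",
                  "cost_minor_amputation", "cost_major_amputation")) {
    raw[[name]] <- value
  } else if (name == "p_hospital") {
    raw$p_hospital <- value
    raw$p_outpatient <- 1 - value
  } else if (name == "p_outpatient") {
    raw$p_outpatient <- value
    raw$p_hospital <- 1 - value
  } else if (name == "p_amputation_heal") {
    raw$p_amputation_heal <- value
    raw$p_debridement_heal <- 1 - value - raw$p_death
  } else if (name == "p_debridement_heal") {
    raw$p_debridement_heal <- value
    raw$p_amputation_heal <- 1 - value - raw$p_death
  } else if (name == "p_death") {
    raw$p_death <- value
    raw$p_debridement_heal <- 1 - raw$p_amputation_heal - value
  } else if (name == "p_major_given_amputation") {
    raw$p_major_given_amputation <- value
    raw$p_minor_given_amputation <- 1 - value
  } else if (name == "p_minor_given_amputation") {
    raw$p_minor_given_amputation <- value
    raw$p_major_given_amputation <- 1 - value
  } else if (grepl("^effectiveness_", name)) {
    s <- match_strategy(sub("^effectiveness_", "", name))
    raw$effectiveness[s] <- value
  } else if (grepl("^prevention_", name)) {
    s <- match_strategy(sub("^prevention_", "", name))
    raw$prevention_cost_per_person[s] <- value
  } else {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  # perturbed sets keep their own ranges out of validation: the point moved
  raw$ranges <- list()
  do.call(parameter_set, raw)
}

# Outcome of the analysed comparison for one parameter set. ICER outcomes
# are the signed ratio delta cost / deaths averted so that cost-saving
# excursions stay plottable; the accompanying label records the regime.
owsa_outcome <- function(ps, spec) {
  cmp <- compare_strategies(ps, spec$intervention, spec$comparator,
                            include_indirect = spec$include_indirect)
  switch(spec$outcome,
    icer_direct = list(
      value = cmp$delta_cost_direct / cmp$deaths_averted,
      label = cmp$label_direct),
    icer_with_indirect = list(
      value = cmp$delta_cost_with_indirect / cmp$deaths_averted,
      label = cmp$label_with_indirect),
    delta_cost = list(
      value = if (spec$include_indirect) cmp$delta_cost_with_indirect
              else cmp$delta_cost_direct,
      label = "value"),
    deaths_averted = list(value = cmp$deaths_averted, label = "value")
  )
}

#' Run a multiple one-way sensitivity analysis
#'
#' For each parameter in the analysis specification, recomputes the chosen
#' comparison outcome with that parameter set to its low and then its high
#' bound (all others at base), records the excursion, and returns the entries
#' ordered by descending swing (see [order_tornado()]). A perturbation that
#' violates a hard model constraint flags the entry (`flagged = TRUE`,
#' outcomes `NA`) instead of silently clamping.
#'
#' ICER outcomes are reported as the signed ratio even when an excursion
#' crosses into the cost-saving regime; `label_low`/`label_high` record the
#' regime of each endpoint.
#'
#' @param ps a `parameter_set` (the base case).
#' @param spec an [owsa_spec()]; if its `parameters` is `NULL`, `ps$ranges`
#'   is used.
#' @return data.frame of class `tornado`, one row per parameter, ordered by
#'   descending swing: `parameter`, `base_value`, `low_value`, `high_value`,
#'   `outcome_at_low`, `outcome_at_high`, `outcome_at_base`, `swing`,
#'   `label_low`, `label_high`, `flagged`.
#' @export
#' @examples
#' ps <- peru_2012_fixture()
#' tor <- run_owsa(ps, owsa_spec("standard", "sub_optimal"))
#' tor$parameter[1]  # "prevention_standard": prevention cost dominates
run_owsa <- function(ps, spec) {
  stopifnot(inherits(ps, "parameter_set"), inherits(spec, "owsa_spec"))
  params <- spec$parameters %||% ps$ranges
  if (!length(params)) stop("no parameters with ranges to vary", call. = FALSE)
  missing_rng <- names(params)[!vapply(params, function(r)
    is.numeric(r) && length(r) == 2L, TRUE)]
  if (length(missing_rng)) {
    stop("malformed range for: ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }

  base <- owsa_outcome(ps, spec)

  rows <- lapply(names(params), function(nm) {
    rng <- as.numeric(params[[nm]])
    base_value <- parameter_value(ps, nm)
    at <- function(v) {
      tryCatch({
        o <- owsa_outcome(perturb_parameter(ps, nm, v), spec)
        list(value = o$value, label = o$label, ok = TRUE)
      }, error = function(e) list(value = NA_real_, label = "invalid", ok = FALSE))
    }
    lo <- at(rng[1])
    hi <- at(rng[2])
    data.frame(
      parameter = nm,
      base_value = base_value,
      low_value = rng[1],
      high_value = rng[2],
      outcome_at_low = lo$value,
      outcome_at_high = hi$value,
      outcome_at_base = base$value,
      swing = abs(hi$value - lo$value),
      label_low = lo$label,
      label_high = hi$label,
      flagged = !(lo$ok && hi$ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome") <- spec$outcome
  attr(out, "comparison") <- paste(spec$intervention, "vs", spec$comparator)
  order_tornado(out)
}

#' Order sensitivity entries as a tornado
#'
#' Stable sort by descending swing; ties (including flagged entries with
#' undefined swing, placed last) broken by parameter name so the ordering is
#' fully deterministic.
#'
#' @param entries data.frame of tornado entries from [run_owsa()].
#' @return the same data.frame, reordered, class `tornado`.
#' @export
order_tornado <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("parameter", "swing") %in% names(entries)))
  key <- ifelse(is.na(entries$swing), -Inf, entries$swing)
  out <- entries[order(-key, entries$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's outcome excursion around the
#' base-case outcome, widest swing on top. Base graphics; intended for the
#' analysis scripts.
#'
#' @param x a `tornado` data.frame.
#' @param main plot title.
#' @param xlab x-axis label; defaults to the analysed outcome.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.tornado <- function(x, main = attr(x, "comparison"),
                         xlab = attr(x, "outcome") %||% "outcome", ...) {
  d <- x[!x$flagged & !is.na(x$swing) & x$swing > 0, , drop = FALSE]
  if (!nrow(d)) {
    warning("nothing to plot: all entries flagged or zero-swing")
    return(invisible(x))
  }
  d <- d[rev(seq_len(nrow(d))), ]
  lo <- pmin(d$outcome_at_low, d$outcome_at_high)
  hi <- pmax(d$outcome_at_low, d$outcome_at_high)
  old <- graphics::par(mar = c(5, 14, 3, 2))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, d$outcome_at_base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = xlab, ylab = "", main = main)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "grey70", border = "grey30")
  graphics::abline(v = d$outcome_at_base[1], lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
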
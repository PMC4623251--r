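#' @title Report rendering
#' @description Tables mirroring the published cost-of-illness and
#'   cost-effectiveness layouts, tornado tables, and CSV/JSON/markdown
#'   writers. Rendering is pure: it never mutates model results.
#' @name report
NULL

#' Cost-of-illness table (one row block per strategy)
#'
#' Full-precision person counts and costs per strategy and endpoint,
#' mirroring the published cost-of-illness table: total prevention cost, the
#' six endpoint rows with persons and cost, treatment total, and grand total.
#'
#' @param ps a `parameter_set`.
#' @return data.frame with columns `strategy`, `row`, `unit_cost`, `persons`,
#'   `cost` (full precision; round for display).
#' @export
coi_table <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  labels <- endpoint_labels()
  unit_costs <- c(debridement = ps$cost_debridement,
                  heal_major = ps$cost_major_amputation,
                  heal_minor = ps$cost_minor_amputation,
                  death_major = ps$cost_major_amputation,
                  death_minor = ps$cost_minor_amputation,
                  outpatient_wound = ps$cost_wound_management)
  persons_at <- function(fl) c(debridement = fl$n_debridement_heal,
                               heal_major = fl$n_heal_major_amputation,
                               heal_minor = fl$n_heal_minor_amputation,
                               death_major = fl$n_death_major_amputation,
                               death_minor = fl$n_death_minor_amputation,
                               outpatient_wound = fl$n_outpatient_heal)
  blocks <- lapply(strategies(), function(s) {
    cb <- total_direct_cost(ps, s)
    fl <- cb$flows
    persons <- persons_at(fl)
    rows <- data.frame(
      strategy = s,
      row = c("Total cost of prevention", unname(labels),
              "Total cost of treatment", "Total cost"),
      unit_cost = c(unname(ps$prevention_cost_per_person[s]),
                    unname(unit_costs), NA, NA),
      persons = c(fl$population_high_risk, unname(persons),
                  fl$n_ulcerated, NA),
      cost = c(cb$prevention_total,
               unname(cb$treatment_by_endpoint[names(labels)]),
               cb$treatment_total, cb$direct_total),
      stringsAsFactors = FALSE
    )
    rows
  })
  do.call(rbind, blocks)
}

#' Cost-effectiveness table (the three pairwise comparisons)
#'
#' @param ps a `parameter_set`.
#' @return data.frame, one row per comparison: incremental costs with and
#'   without indirect costs, deaths and major amputations averted, ICERs or
#'   dominance labels, and the threshold verdicts.
#' @export
cea_table <- function(ps) {
  comparisons <- full_comparison_table(ps)
  rows <- lapply(comparisons, function(cmp) {
    data.frame(
      comparison = paste(cmp$intervention, "vs", cmp$comparator),
      delta_cost_direct = cmp$delta_cost_direct,
      delta_cost_with_indirect = cmp$delta_cost_with_indirect,
      deaths_averted = cmp$deaths_averted,
      major_amputations_averted = cmp$major_amputations_averted,
      icer_direct = cmp$icer_direct,
      label_direct = cmp$label_direct,
      icer_with_indirect = cmp$icer_with_indirect,
      label_with_indirect = cmp$label_with_indirect,
      threshold = cmp$threshold,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fmt_money <- function(x) {
  ifelse(is.na(x), "",
         paste0(ifelse(x < 0, "-US$", "US$"),
                format(abs(round_half_up(x)), big.mark = ",",
                       scientific = FALSE, trim = TRUE)))
}
fmt_persons <- function(x) {
  ifelse(is.na(x), "",
         format(round_half_up(x), big.mark = ",", scientific = FALSE,
                trim = TRUE))
}

md_table <- function(df) {
  esc <- function(x) gsub("\\|", "\\\\|", as.character(x))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(esc(r), collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

coi_markdown <- function(tab) {
  disp <- data.frame(
    Strategy = tab$strategy,
    Description = tab$row,
    `Cost per unit` = fmt_money(tab$unit_cost),
    `No. of people` = fmt_persons(tab$persons),
    `Total cost` = fmt_money(tab$cost),
    check.names = FALSE
  )
  md_table(disp)
}

cea_markdown <- function(tab) {
  disp <- data.frame(
    Comparison = tab$comparison,
    `Direct costs` = fmt_money(tab$delta_cost_direct),
    `Direct + indirect costs` = fmt_money(tab$delta_cost_with_indirect),
    `Deaths averted` = fmt_persons(tab$deaths_averted),
    `Major amputations averted` = fmt_persons(tab$major_amputations_averted),
    `ICER (direct)` = mapply(format_icer, tab$label_direct, tab$icer_direct),
    `ICER (direct + indirect)` = mapply(format_icer, tab$label_with_indirect,
                                        tab$icer_with_indirect),
    check.names = FALSE
  )
  md_table(disp)
}

config_fingerprint <- function(ps) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(as_config(ps), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Render the full report bundle
#'
#' Computes the cost-of-illness table, the cost-effectiveness table and a
#' tornado table per comparison, and writes them in the requested formats.
#' CSV/JSON carry plain full-precision numbers; markdown applies the
#' presentation rounding (persons and dollars half-up to integers) and
#' currency formatting.
#'
#' @param ps a `parameter_set`.
#' @param out_dir output directory (created if missing); `NULL` renders
#'   in-memory only.
#' @param formats subset of `c("csv", "json", "markdown")`.
#' @param tornado_outcome outcome passed to [run_owsa()] for the tornado
#'   tables.
#' @return invisibly, a `report_bundle`: `coi_table`, `cea_table`,
#'   `tornado_tables` (one per comparison against the comparator strategy),
#'   `metadata` (config fingerprint, package version, timestamp), and the
#'   paths written.
#' @export
render_reports <- function(ps, out_dir = NULL,
                           formats = c("csv", "json", "markdown"),
                           tornado_outcome = "icer_direct") {
  stopifnot(inherits(ps, "parameter_set"))
  formats <- match.arg(formats, c("csv", "json", "markdown"),
                       several.ok = TRUE)
  coi <- coi_table(ps)
  cea <- cea_table(ps)
  tornado_tables <- list()
  if (length(ps$ranges)) {
    for (s in c("standard", "standard_plus_temp")) {
      nm <- paste(s, "vs sub_optimal")
      tornado_tables[[nm]] <- run_owsa(
        ps, owsa_spec(s, "sub_optimal", outcome = tornado_outcome))
    }
  }
  bundle <- structure(
    list(coi_table = coi, cea_table = cea, tornado_tables = tornado_tables,
         metadata = list(
           config_fingerprint = config_fingerprint(ps),
           package_version = as.character(utils::packageVersion("footcea")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         files = character()),
    class = "report_bundle"
  )
  if (is.null(out_dir)) return(invisible(bundle))

  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  files <- character()
  emit <- function(path, writer) {
    writer(path)
    files <<- c(files, path)
  }
  slug <- function(x) gsub(" ", "_", x)
  if ("csv" %in% formats) {
    emit(file.path(out_dir, "coi.csv"),
         function(p) utils::write.csv(coi, p, row.names = FALSE, na = ""))
    emit(file.path(out_dir, "cea.csv"),
         function(p) utils::write.csv(cea, p, row.names = FALSE, na = ""))
    for (nm in names(tornado_tables)) {
      emit(file.path(out_dir, paste0("tornado_", slug(nm), ".csv")),
           function(p) utils::write.csv(
             as.data.frame(tornado_tables[[nm]]), p, row.names = FALSE, na = ""))
    }
  }
  if ("json" %in% formats) {
    emit(file.path(out_dir, "report.json"), function(p) {
      jsonlite::write_json(
        list(metadata = bundle$metadata, coi = coi, cea = cea,
             tornado = lapply(tornado_tables, as.data.frame)),
        p, auto_unbox = TRUE, digits = NA, na = "null")
    })
  }
  if ("markdown" %in% formats) {
    emit(file.path(out_dir, "report.md"), function(p) {
      writeLines(c(
        "# Diabetic-foot prevention: cost of illness and cost-effectiveness",
        "",
        sprintf("Config fingerprint: `%s` (footcea %s, %s)",
                bundle$metadata$config_fingerprint,
                bundle$metadata$package_version, bundle$metadata$timestamp),
        "",
        "## Cost of illness (direct costs)",
        "",
        coi_markdown(coi),
        "",
        "## Outcomes and cost-effectiveness",
        "",
        cea_markdown(cea)
      ), p)
    })
  }
  bundle$files <- files
  invisible(bundle)
}
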
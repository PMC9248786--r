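## Publication-shaped outputs: treatment-flow (Sankey) edge lists, the
## small-cell disclosure rules, and the end-to-end run with a manifest.
## Suppression is presentation-layer only: every statistic is computed on
## true counts and redacted at rendering.

#' Disclosure suppression rule
#'
#' @param small_cell_max member counts from 1 to this value are rendered
#'   as `<=max` (zero is printed as `0 (0.0%)`, not suppressed).
#' @param sankey_min_share treatment-flow nodes holding less than this
#'   share of their line's members are omitted from the rendered figure
#'   (but kept, flagged, in the machine-readable edge list).
#' @return a `suppression_rule` list.
#' @export
suppression_rule <- function(small_cell_max = 10L, sankey_min_share = 0.01) {
  stopifnot(small_cell_max >= 0, sankey_min_share >= 0, sankey_min_share <= 1)
  structure(list(small_cell_max = as.integer(small_cell_max),
                 sankey_min_share = sankey_min_share),
            class = "suppression_rule")
}

#' Treatment-flow edge list across lines
#'
#' One edge per (line-k regimen state, line-k+1 regimen state) pair, with
#' members who have no further reported line flowing to a terminal node.
#' Outflow of each line equals its initiator count, so members are
#' conserved.
#'
#' @param lines a `pah_lot` from [segment_cohort_lines()].
#' @param max_lines number of lines displayed.
#' @return tibble with `from_line`, `from_state`, `to_line`, `to_state`,
#'   `n_members`.
#' @export
build_sankey <- function(lines, max_lines = 4L) {
  ln <- lines[lines$line_number <= max_lines,
              c("member_id", "line_number", "regimen")]
  nxt <- ln |>
    dplyr::mutate(line_number = .data$line_number - 1L) |>
    dplyr::rename(next_regimen = "regimen")
  ln |>
    dplyr::left_join(nxt, by = c("member_id", "line_number")) |>
    dplyr::mutate(next_regimen = dplyr::coalesce(.data$next_regimen,
                                                 "no further line")) |>
    dplyr::count(from_line = .data$line_number, from_state = .data$regimen,
                 to_state = .data$next_regimen, name = "n_members") |>
    dplyr::mutate(to_line = .data$from_line + 1L) |>
    dplyr::relocate("from_line", "from_state", "to_line", "to_state")
}

#' Apply small-cell disclosure rules to a count table or edge list
#'
#' Adds a `display` column rendering each member count: `0` as
#' `"0 (0.0%)"`, counts from 1 to `small_cell_max` as the suppression
#' string (e.g. `"<=10"`), larger counts verbatim with their percentage
#' when a percentage column is given. For Sankey edge lists, additionally
#' flags edges whose origin-state share of the line is below
#' `sankey_min_share` as `render = FALSE` (retained, never dropped).
#' Idempotent: `display` is always recomputed from the true counts.
#'
#' @param x a tibble with a member-count column.
#' @param rule a [suppression_rule()].
#' @param count_col name of the count column.
#' @param pct_col optional name of a percentage column used in the
#'   display string.
#' @return `x` with `display` (and for edge lists `render`) columns.
#' @export
apply_suppression <- function(x, rule = suppression_rule(),
                              count_col = "n_members", pct_col = NULL) {
  n <- x[[count_col]]
  disp <- ifelse(
    n == 0,
    "0 (0.0%)",
    ifelse(n <= rule$small_cell_max,
           paste0("<=", rule$small_cell_max),
           if (!is.null(pct_col)) {
             sprintf("%d (%.1f%%)", n, x[[pct_col]])
           } else {
             sprintf("%d", n)
           })
  )
  x$display <- disp
  if (all(c("from_line", "from_state") %in% names(x))) {
    line_tot <- stats::ave(n, x$from_line, FUN = sum)
    state_tot <- stats::ave(n, x$from_line, x$from_state, FUN = sum)
    x$render <- state_tot / line_tot >= rule$sankey_min_share &
      n > rule$small_cell_max
  }
  x
}

#' Run the whole pipeline end to end and write its artifact set
#'
#' generate, select, segment, summarize, report: writes the synthetic
#' claims file set, the planted-truth answer key, the attrition report,
#' cohort, line, treatment-pattern, HCRU, and cost tables, the Sankey edge
#' list, and a run manifest. Outputs are deterministic for a fixed
#' (config, seed): rerunning into a fresh directory yields byte-identical
#' files.
#'
#' @param out_dir output directory.
#' @param config a [generator_config()].
#' @param seed optional integer overriding `config$seed`.
#' @param codesets,selection,lot,inflation stage settings.
#' @param rule a [suppression_rule()] for the rendered tables.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(out_dir, config = generator_config(), seed = NULL,
                    codesets = pah_codesets(),
                    selection = selection_config(),
                    lot = lot_config(),
                    inflation = inflation_table(),
                    rule = suppression_rule()) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_population(config, codesets, inflation)
  data_dir <- file.path(out_dir, "data")
  write_claims_dataset(pop$dataset, data_dir, codesets)
  readr::write_csv(pop$truth$members, file.path(data_dir, "truth_members.csv"))
  readr::write_csv(pop$truth$lines, file.path(data_dir, "truth_lines.csv"))
  readr::write_csv(pop$truth$costs, file.path(data_dir, "truth_costs.csv"))

  cohort <- select_cohort(pop$dataset, codesets, selection, lot)
  attr_rep <- attrition_report(cohort)
  readr::write_csv(attr_rep, file.path(out_dir, "attrition.csv"))
  readr::write_csv(tibble::as_tibble(cohort), file.path(out_dir, "cohort.csv"))

  lines <- segment_cohort_lines(cohort, pop$dataset, codesets, lot)
  readr::write_csv(tibble::as_tibble(lines), file.path(out_dir, "lines.csv"))
  pat <- summarize_lines(lines, lot$max_reported_lines, codesets)
  readr::write_csv(pat$overview, file.path(out_dir, "patterns_overview.csv"))
  readr::write_csv(apply_suppression(pat$medications, rule, pct_col = "pct"),
                   file.path(out_dir, "patterns_medications.csv"))
  readr::write_csv(apply_suppression(pat$regimens, rule, pct_col = "pct"),
                   file.path(out_dir, "patterns_regimens.csv"))

  periods <- make_periods(cohort, lines, selection$baseline_days,
                          lot$max_reported_lines)
  hcru <- summarize_period(pop$dataset, periods, codesets)
  costs <- summarize_costs(pop$dataset, periods, codesets, inflation)
  readr::write_csv(hcru, file.path(out_dir, "hcru.csv"))
  readr::write_csv(costs, file.path(out_dir, "costs.csv"))

  edges <- apply_suppression(build_sankey(lines, lot$max_reported_lines), rule)
  jsonlite::write_json(edges, file.path(out_dir, "sankey_edges.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)

  cfg_file <- file.path(out_dir, "effective_config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pahlot")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_members = nrow(pop$dataset$members),
    n_cohort = nrow(cohort),
    n_lines = nrow(lines),
    rows = list(medical_claims = nrow(pop$dataset$medical_claims),
                pharmacy_claims = nrow(pop$dataset$pharmacy_claims)),
    files = sort(c(list.files(out_dir, recursive = TRUE)))
  )
  manifest$files <- setdiff(manifest$files, "manifest.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
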
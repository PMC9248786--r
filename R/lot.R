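## Line-of-therapy engine. A member's post-index PAH medication history is
## segmented into ordered treatment lines. A line is a maximal period on a
## fixed set of medication classes; it ends by
##   - interruption: all-class coverage runs out and no PAH medication claim
##     occurs within the grace window (> gap_days of uncovered time), or
##   - modification: a claim of a class outside the line's class set occurs
##     without an intervening interruption (sequential combination or
##     switch), or
##   - censoring: follow-up ends first.
## Coverage derives from days'-supply run-out of each fill (union, not
## stacked, by default): the run-out of a fill is fill_day + days_supply.

#' Line-of-therapy engine settings
#'
#' @param first_line_window_days length of the class-formation window at the
#'   start of each line: the line's class set is every medication class with
#'   at least one claim in `[start, start + first_line_window_days]`
#'   (boundary inclusive when `window_inclusive`). 30 days by default, the
#'   convention used to distinguish initial combination therapy from
#'   monotherapy in claims studies.
#' @param gap_days grace period after run-out of the last days' supply. A
#'   gap in all-class coverage of **more than** `gap_days` days is a
#'   treatment interruption; a gap of exactly `gap_days` is tolerated.
#' @param max_reported_lines lines beyond this number are still segmented
#'   but marked unreported in summaries (publication tables show four).
#' @param hcpcs_days_supply assumed days' supply for medication
#'   administrations billed on medical claims, which carry no days'-supply
#'   field.
#' @param window_inclusive whether a claim exactly
#'   `first_line_window_days` after the line start falls inside the
#'   formation window.
#' @param stack_supply if `TRUE`, early refills accumulate supply (run-out
#'   extends from the previous run-out instead of the fill day). Off by
#'   default: run-out anchors to the last fill.
#' @param gap_eval_cap_days if finite, interruptions are only recognized
#'   when the run-out day falls within this many days of the index date;
#'   later gaps are treated as continuous. `Inf` (default) evaluates gaps
#'   over the whole follow-up.
#' @return a `lot_config` list.
#' @export
lot_config <- function(first_line_window_days = 30L,
                       gap_days = 60L,
                       max_reported_lines = 4L,
                       hcpcs_days_supply = 30L,
                       window_inclusive = TRUE,
                       stack_supply = FALSE,
                       gap_eval_cap_days = Inf) {
  stopifnot(first_line_window_days > 0, gap_days > 0,
            max_reported_lines > 0, hcpcs_days_supply > 0)
  structure(
    list(first_line_window_days = as.integer(first_line_window_days),
         gap_days = as.integer(gap_days),
         max_reported_lines = as.integer(max_reported_lines),
         hcpcs_days_supply = as.integer(hcpcs_days_supply),
         window_inclusive = isTRUE(window_inclusive),
         stack_supply = isTRUE(stack_supply),
         gap_eval_cap_days = gap_eval_cap_days),
    class = "lot_config"
  )
}

#' Extract PAH medication claims in analysis form
#'
#' Collects pharmacy fills of mapped PAH drugs and medical drug
#' administrations (HCPCS-coded) into one event table: one row per claim
#' with its medication class and days' supply. Pharmacy drug codes absent
#' from the class map are skipped with a warning.
#'
#' @param ds a `claims_dataset`.
#' @param codesets a [pah_codesets()].
#' @param config a [lot_config()] (supplies the assumed medical-claim
#'   supply).
#' @return tibble with `member_id`, `day`, `drug_class`, `drug_code`,
#'   `supply_days`, `source`.
#' @export
pah_med_claims <- function(ds, codesets = pah_codesets(), config = lot_config()) {
  rx_lu <- drug_class_lookup(codesets)
  rx <- ds$pharmacy_claims
  rx_class <- unname(rx_lu[rx$drug_code])
  unmapped <- is.na(rx_class)
  pah_rx <- tibble::tibble(
    member_id = rx$member_id[!unmapped],
    day = rx$fill_day[!unmapped],
    drug_class = rx_class[!unmapped],
    drug_code = rx$drug_code[!unmapped],
    supply_days = rx$days_supply[!unmapped],
    source = "pharmacy"
  )
  hc_lu <- hcpcs_class_lookup(codesets)
  md <- ds$medical_claims
  md_class <- unname(hc_lu[md$hcpcs_drug_code])
  keep <- !is.na(md$hcpcs_drug_code) & !is.na(md_class)
  pah_md <- tibble::tibble(
    member_id = md$member_id[keep],
    day = md$service_day[keep],
    drug_class = md_class[keep],
    drug_code = md$hcpcs_drug_code[keep],
    supply_days = rep(config$hcpcs_days_supply, sum(keep)),
    source = "medical"
  )
  dplyr::arrange(dplyr::bind_rows(pah_rx, pah_md),
                 .data$member_id, .data$day, .data$drug_class, .data$drug_code)
}

#' Build per-class medication coverage intervals
#'
#' Each claim contributes the half-open interval
#' `[day, day + supply_days)`; per (member, class) the intervals are
#' unioned, so overlapping early refills merge rather than stack.
#'
#' @param med_claims output of [pah_med_claims()] (optionally pre-filtered
#'   to one member or to days on/after index).
#' @return tibble of disjoint intervals with `member_id`, `drug_class`,
#'   `start_day`, `end_day`, `source` (`"mixed"` when both claim sources
#'   contribute to a merged interval).
#' @export
build_coverage <- function(med_claims) {
  if (nrow(med_claims) == 0) {
    return(tibble::tibble(member_id = character(), drug_class = character(),
                          start_day = integer(), end_day = integer(),
                          source = character()))
  }
  med_claims |>
    dplyr::mutate(end = .data$day + .data$supply_days) |>
    dplyr::group_by(.data$member_id, .data$drug_class) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      spans <- merge_spans(df$day, df$end, bridge_gap = 0L)
      spans$source <- vapply(seq_len(nrow(spans)), function(i) {
        src <- unique(df$source[df$day < spans$end_day[i] &
                                  df$end > spans$start_day[i]])
        if (length(src) > 1) "mixed" else src
      }, character(1))
      spans
    }) |>
    dplyr::ungroup()
}

#' Medication classes forming a line at its start
#'
#' The class set of a line is every class with at least one claim in the
#' formation window anchored at the line start (the index date for line 1).
#' Two or more classes make the line combination therapy; one makes it
#' monotherapy.
#'
#' @param med_claims member-level claims (as from [pah_med_claims()]).
#' @param start_day line start day.
#' @param config a [lot_config()].
#' @return character vector of class labels (possibly empty).
#' @export
assign_first_line <- function(med_claims, start_day, config = lot_config()) {
  w_end <- start_day + config$first_line_window_days
  inside <- med_claims$day >= start_day &
    (if (config$window_inclusive) med_claims$day <= w_end else med_claims$day < w_end)
  sort(unique(med_claims$drug_class[inside]))
}

## Core single-line scan. `claims` must be sorted by day and restricted to
## day >= start & day < censor. Returns the line's end day, end reason,
## the start day of the next line (NA if none), the class set, and the rows
## consumed by the line.
segment_one_line <- function(claims, start, censor, index_day, config) {
  w_end <- start + config$first_line_window_days
  in_window <- function(d) {
    if (config$window_inclusive) d <= w_end else d < w_end
  }
  gap_ok_day <- if (is.finite(config$gap_eval_cap_days)) {
    index_day + config$gap_eval_cap_days
  } else {
    Inf
  }
  classes <- character(0)
  runout <- start
  consumed <- integer(0)
  n <- nrow(claims)
  i <- 1L
  while (i <= n) {
    d <- claims$day[i]
    cl <- claims$drug_class[i]
    ro_end <- if (config$stack_supply) {
      max(runout, d) + claims$supply_days[i]
    } else {
      d + claims$supply_days[i]
    }
    if (length(classes) > 0 && d > runout + config$gap_days &&
        runout <= gap_ok_day) {
      return(list(end_day = runout, end_reason = "interruption",
                  next_start = d, classes = classes, consumed = consumed))
    }
    if (in_window(d)) {
      classes <- sort(unique(c(classes, cl)))
      runout <- max(runout, ro_end)
      consumed <- c(consumed, i)
    } else if (cl %in% classes) {
      runout <- max(runout, ro_end)
      consumed <- c(consumed, i)
    } else {
      return(list(end_day = d, end_reason = "modification",
                  next_start = d, classes = classes, consumed = consumed))
    }
    i <- i + 1L
  }
  if (censor > runout + config$gap_days && runout <= gap_ok_day) {
    list(end_day = runout, end_reason = "interruption",
         next_start = NA_integer_, classes = classes, consumed = consumed)
  } else {
    list(end_day = censor, end_reason = "censored",
         next_start = NA_integer_, classes = classes, consumed = consumed)
  }
}

#' Detect where a treatment line ends and why
#'
#' Scans forward from the line start through the member's medication
#' claims: a claim of a class outside the line's set without an intervening
#' interruption ends the line by modification on that day; a lapse of more
#' than `gap_days` in all-class coverage after run-out ends it by
#' interruption on the run-out day (a subsequent claim, of any class, opens
#' the next line); otherwise the line is censored at end of follow-up. A
#' terminal gap shorter than the grace period is censored, not interrupted,
#' because the interruption cannot be observed.
#'
#' @param med_claims one member's claims sorted by day.
#' @param line_start_day day the line starts (its formation window anchors
#'   here).
#' @param censor_day end of follow-up (exclusive).
#' @param index_day the member's index day (only used when
#'   `gap_eval_cap_days` is finite).
#' @param config a [lot_config()].
#' @return a list with `end_day`, `end_reason`
#'   (`interruption|modification|censored`), `next_start` (`NA` if no
#'   further line), and `classes`.
#' @export
detect_line_end <- function(med_claims, line_start_day, censor_day,
                            index_day = line_start_day, config = lot_config()) {
  claims <- med_claims[med_claims$day >= line_start_day &
                         med_claims$day < censor_day, , drop = FALSE]
  claims <- claims[order(claims$day, claims$drug_class,
                         claims$drug_code), , drop = FALSE]
  res <- segment_one_line(claims, line_start_day, censor_day, index_day, config)
  res[c("end_day", "end_reason", "next_start", "classes")]
}

#' Classify a line's regimen
#'
#' Mutually exclusive regimen labels: a single class is monotherapy of that
#' class; exactly \{ERA, PDE5I\} is the named ERA + PDE5i combination; any
#' other multi-class set is an "other" combination.
#'
#' @param classes nonempty character vector of medication classes.
#' @return a list with `arm` (`monotherapy|combination`), `detail`, and the
#'   combined `label` (e.g. `"MONO_PDE5I"`, `"COMBO_ERA_PDE5I"`,
#'   `"COMBO_OTHER"`).
#' @export
classify_regimen <- function(classes) {
  classes <- sort(unique(classes))
  if (length(classes) == 0) {
    stop("classify_regimen: empty class set", call. = FALSE)
  }
  bad <- setdiff(classes, pah_drug_classes())
  if (length(bad) > 0) {
    stop("classify_regimen: unknown class ", bad[1], call. = FALSE)
  }
  if (length(classes) == 1) {
    list(arm = "monotherapy", detail = classes,
         label = paste0("MONO_", classes))
  } else if (identical(classes, sort(c("ERA", "PDE5I")))) {
    list(arm = "combination", detail = "ERA_PLUS_PDE5I",
         label = "COMBO_ERA_PDE5I")
  } else {
    list(arm = "combination", detail = "OTHER_COMBINATION",
         label = "COMBO_OTHER")
  }
}

#' Segment one member's follow-up into treatment lines
#'
#' Iteratively applies the class-formation window at each line start and
#' [detect_line_end()] until follow-up is exhausted. Restarting the same
#' medication after an interruption still opens a new line.
#'
#' @param med_claims one member's PAH medication claims (all days).
#' @param index_day the member's index day; line 1 starts here.
#' @param censor_day end of follow-up (exclusive): the earlier of
#'   disenrollment and the day after study end.
#' @param config a [lot_config()].
#' @return tibble with one row per line: `line_number`, `start_day`,
#'   `end_day`, `end_reason`, `classes` (';'-joined), `n_classes`,
#'   `drugs` (';'-joined codes observed in the line), `regimen_arm`,
#'   `regimen_detail`, `regimen`, `months_in_line`, `reported`.
#' @export
segment_lines <- function(med_claims, index_day, censor_day,
                          config = lot_config()) {
  claims <- med_claims[med_claims$day >= index_day &
                         med_claims$day < censor_day, , drop = FALSE]
  claims <- claims[order(claims$day, claims$drug_class,
                         claims$drug_code), , drop = FALSE]
  out <- list()
  start <- index_day
  k <- 0L
  while (!is.na(start)) {
    sub <- claims[claims$day >= start, , drop = FALSE]
    if (nrow(sub) == 0) break
    res <- segment_one_line(sub, start, censor_day, index_day, config)
    k <- k + 1L
    reg <- classify_regimen(res$classes)
    out[[k]] <- tibble::tibble(
      line_number = k,
      start_day = start,
      end_day = res$end_day,
      end_reason = res$end_reason,
      classes = paste(res$classes, collapse = ";"),
      n_classes = length(res$classes),
      drugs = paste(sort(unique(sub$drug_code[res$consumed])), collapse = ";"),
      regimen_arm = reg$arm,
      regimen_detail = reg$detail,
      regimen = reg$label
    )
    start <- res$next_start
  }
  lines <- if (k == 0) {
    tibble::tibble(line_number = integer(), start_day = integer(),
                   end_day = integer(), end_reason = character(),
                   classes = character(), n_classes = integer(),
                   drugs = character(), regimen_arm = character(),
                   regimen_detail = character(), regimen = character())
  } else {
    dplyr::bind_rows(out)
  }
  lines$months_in_line <- days_to_months(lines$end_day - lines$start_day)
  lines$reported <- lines$line_number <= config$max_reported_lines
  lines
}

#' Segment treatment lines for a whole cohort
#'
#' @param cohort an indexed cohort (one row per member with `member_id`,
#'   `index_day`, `censor_day`), as returned by [select_cohort()].
#' @param ds the `claims_dataset`.
#' @param codesets a [pah_codesets()].
#' @param config a [lot_config()].
#' @return a `pah_lot` tibble: one row per (member, line) with the columns
#'   of [segment_lines()] plus `member_id`.
#' @export
segment_cohort_lines <- function(cohort, ds, codesets = pah_codesets(),
                                 config = lot_config()) {
  med <- pah_med_claims(ds, codesets, config)
  med_by <- split(med, med$member_id)
  rows <- purrr::pmap(
    list(cohort$member_id, cohort$index_day, cohort$censor_day),
    function(id, idx, cen) {
      mc <- med_by[[id]]
      if (is.null(mc)) mc <- med[0, ]
      ln <- segment_lines(mc, idx, cen, config)
      if (nrow(ln) > 0) ln$member_id <- id
      ln
    }
  )
  lines <- dplyr::bind_rows(rows)
  lines <- dplyr::relocate(lines, "member_id")
  class(lines) <- c("pah_lot", class(lines))
  lines
}

#' Treatment-pattern summary by line
#'
#' Mirrors the publication treatment-pattern table: per line (up to
#' `max_reported_lines`), the number of initiators, months in line,
#' end-reason breakdown with restart behaviour after interruption,
#' non-exclusive medication class / drug tallies, and mutually exclusive
#' regimen tallies. All statistics are computed on true counts; disclosure
#' suppression is applied only at reporting via [apply_suppression()].
#'
#' @param lines a `pah_lot` tibble from [segment_cohort_lines()].
#' @param max_reported_lines number of lines summarized.
#' @param codesets a [pah_codesets()] used to label drugs.
#' @return a `lot_patterns` list of tibbles: `$overview`, `$medications`,
#'   `$regimens`.
#' @export
summarize_lines <- function(lines, max_reported_lines = 4L,
                            codesets = pah_codesets()) {
  n_cohort <- length(unique(lines$member_id))
  nxt <- lines |>
    dplyr::group_by(.data$member_id) |>
    dplyr::arrange(.data$line_number, .by_group = TRUE) |>
    dplyr::mutate(has_next = .data$line_number < max(.data$line_number)) |>
    dplyr::ungroup()
  overview <- purrr::map_dfr(seq_len(max_reported_lines), function(k) {
    lk <- nxt[nxt$line_number == k, , drop = FALSE]
    n_k <- nrow(lk)
    int <- lk[lk$end_reason == "interruption", , drop = FALSE]
    tibble::tibble(
      line_number = k,
      n_initiators = n_k,
      pct_of_cohort = 100 * n_k / max(n_cohort, 1),
      months_mean = mean(lk$months_in_line),
      months_sd = stats::sd(lk$months_in_line),
      n_remain = sum(lk$end_reason == "censored"),
      n_interruption = nrow(int),
      n_restart = sum(int$has_next),
      n_no_restart = sum(!int$has_next),
      n_modification = sum(lk$end_reason == "modification")
    )
  })
  med_tally <- function(lk, col) {
    ## class/drug strings are unique within a line row, so occurrences
    ## across rows count members
    vals <- unlist(strsplit(lk[[col]], ";", fixed = TRUE))
    dplyr::count(tibble::tibble(item = vals), .data$item, name = "n_members")
  }
  medications <- purrr::map_dfr(seq_len(max_reported_lines), function(k) {
    lk <- lines[lines$line_number == k, , drop = FALSE]
    if (nrow(lk) == 0) return(NULL)
    cls <- med_tally(lk, "classes") |> dplyr::mutate(level = "class")
    drg <- med_tally(lk, "drugs") |> dplyr::mutate(level = "drug")
    dplyr::bind_rows(cls, drg) |>
      dplyr::mutate(line_number = k,
                    n_initiators = nrow(lk),
                    pct = 100 * .data$n_members / nrow(lk)) |>
      dplyr::relocate("line_number", "level", "item")
  })
  drug_names <- c(stats::setNames(codesets$drug_class_map$drug_name,
                                  codesets$drug_class_map$drug_code),
                  stats::setNames(codesets$hcpcs_class_map$drug_name,
                                  codesets$hcpcs_class_map$hcpcs_code))
  if (nrow(medications) > 0) {
    medications$item_name <- ifelse(medications$level == "drug",
                                    unname(drug_names[medications$item]),
                                    medications$item)
  }
  regimens <- purrr::map_dfr(seq_len(max_reported_lines), function(k) {
    lk <- lines[lines$line_number == k, , drop = FALSE]
    if (nrow(lk) == 0) return(NULL)
    lk |>
      dplyr::count(.data$regimen_arm, .data$regimen, name = "n_members") |>
      dplyr::mutate(line_number = k, n_initiators = nrow(lk),
                    pct = 100 * .data$n_members / nrow(lk)) |>
      dplyr::relocate("line_number")
  })
  structure(list(overview = overview, medications = medications,
                 regimens = regimens),
            class = "lot_patterns")
}

#' @export
print.lot_patterns <- function(x, ...) {
  cat("<lot_patterns>\n\nPer-line overview:\n")
  print(x$overview, ...)
  cat("\nRegimens (mutually exclusive):\n")
  print(x$regimens, n = 20, ...)
  invisible(x)
}
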
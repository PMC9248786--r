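## Healthcare resource utilization (HCRU) and cost summaries. All rates and
## costs are per patient per month (PPPM) with the pooled denominator: the
## sum of events (or inflation-adjusted costs) across members in a period
## divided by the sum of patient-months of that period across members --
## not the mean of member-level ratios.

#' Medical-price inflation multipliers to 2020 USD
#'
#' One multiplier per calendar year applied to nominal claim costs
#' (plan + member + coordination-of-benefits) so all costs are expressed in
#' 2020 dollars. Defaults follow the US medical-care consumer price index
#' for 2015-2020, normalized to 2020 = 1; supply your own table for other
#' study frames. No network retrieval is performed.
#'
#' @param years integer calendar years.
#' @param multipliers positive multipliers to 2020 USD (the 2020 entry must
#'   be 1).
#' @return an `inflation_table` tibble with columns `year`, `multiplier`.
#' @export
inflation_table <- function(years = 2015:2020,
                            multipliers = c(1.149, 1.106, 1.078, 1.057,
                                            1.028, 1.000)) {
  stopifnot(length(years) == length(multipliers), all(multipliers > 0))
  if (2020 %in% years && abs(multipliers[years == 2020] - 1) > 1e-12) {
    stop("inflation_table: the 2020 multiplier must be 1", call. = FALSE)
  }
  out <- tibble::tibble(year = as.integer(years),
                        multiplier = as.numeric(multipliers))
  class(out) <- c("inflation_table", class(out))
  out
}

## Multiplier lookup with an informative error for missing years.
inflation_multiplier <- function(day, inflation) {
  yr <- day_to_year(day)
  i <- match(yr, inflation$year)
  if (anyNA(i)) {
    stop("inflation_table has no multiplier for year ",
         yr[which(is.na(i))[1]], call. = FALSE)
  }
  inflation$multiplier[i]
}

#' Identity inflation table
#'
#' All multipliers 1: costs are taken as already expressed in the target
#' dollars.
#' @param years calendar years to cover.
#' @return an `inflation_table`.
#' @export
identity_inflation <- function(years = 2010:2021) {
  inflation_table(years, rep(1, length(years)))
}

#' Analysis periods for a cohort
#'
#' Builds the (member, period) table over which HCRU and costs are pooled:
#' the fixed-length baseline `[index - baseline_days, index)`, the variable
#' post-index period `[index, censor)`, and one period per reported
#' treatment line `[line start, line end)`. Claims in gaps between lines
#' belong to the post-index period but to no line period.
#'
#' @param cohort a `pah_cohort` from [select_cohort()].
#' @param lines optional `pah_lot` from [segment_cohort_lines()]; omit for
#'   baseline/post-index periods only.
#' @param baseline_days baseline length in days.
#' @param max_reported_lines number of line periods to emit.
#' @return tibble with `member_id`, `period`, `start_day`, `end_day`,
#'   `patient_months`.
#' @export
make_periods <- function(cohort, lines = NULL, baseline_days = 183L,
                         max_reported_lines = 4L) {
  base <- tibble::tibble(
    member_id = cohort$member_id,
    period = "baseline",
    start_day = cohort$index_day - as.integer(baseline_days),
    end_day = cohort$index_day
  )
  post <- tibble::tibble(
    member_id = cohort$member_id,
    period = "postindex",
    start_day = cohort$index_day,
    end_day = cohort$censor_day
  )
  out <- dplyr::bind_rows(base, post)
  if (!is.null(lines) && nrow(lines) > 0) {
    ln <- lines[lines$line_number <= max_reported_lines, , drop = FALSE]
    out <- dplyr::bind_rows(out, tibble::tibble(
      member_id = ln$member_id,
      period = paste0("line_", ln$line_number),
      start_day = ln$start_day,
      end_day = ln$end_day
    ))
  }
  out$patient_months <- days_to_months(out$end_day - out$start_day)
  out[out$end_day > out$start_day, , drop = FALSE]
}

#' Is a claim PAH-related?
#'
#' Medical claims are PAH-related when any diagnosis code (any position) is
#' in the PAH set or the claim carries a mapped PAH drug-administration
#' code; pharmacy claims when the drug code maps to a PAH medication class.
#'
#' @param claims a medical- or pharmacy-claims tibble (detected by the
#'   presence of a `drug_code` column).
#' @param codesets a [pah_codesets()].
#' @return logical vector, one element per claim.
#' @export
flag_pah_related <- function(claims, codesets = pah_codesets()) {
  if ("drug_code" %in% names(claims)) {
    claims$drug_code %in% codesets$drug_class_map$drug_code
  } else {
    has_pah_dx(claims$dx_codes, codesets) |
      (!is.na(claims$hcpcs_drug_code) &
         claims$hcpcs_drug_code %in% codesets$hcpcs_class_map$hcpcs_code)
  }
}

## Long event table for HCRU tallies: one row per claim per category it
## counts toward, with all-cause / PAH-related flags.
hcru_events <- function(ds, codesets) {
  md <- ds$medical_claims
  md_pah <- flag_pah_related(md, codesets)
  med_admin <- !is.na(md$hcpcs_drug_code) &
    md$hcpcs_drug_code %in% codesets$hcpcs_class_map$hcpcs_code
  transplant <- has_proc(md$proc_codes, codesets$transplant_proc_codes)
  rx <- ds$pharmacy_claims
  rx_pah <- flag_pah_related(rx, codesets)
  dplyr::bind_rows(
    tibble::tibble(member_id = md$member_id, day = md$service_day,
                   category = dplyr::recode(md$setting,
                                            inpatient = "inpatient",
                                            er = "er",
                                            outpatient = "outpatient"),
                   pah = md_pah),
    tibble::tibble(member_id = md$member_id[med_admin],
                   day = md$service_day[med_admin],
                   category = "pah_med_medical", pah = TRUE),
    tibble::tibble(member_id = md$member_id[transplant],
                   day = md$service_day[transplant],
                   category = "transplant", pah = md_pah[transplant]),
    tibble::tibble(member_id = rx$member_id, day = rx$fill_day,
                   category = "pharmacy_fills", pah = rx_pah),
    tibble::tibble(member_id = rx$member_id[rx_pah], day = rx$fill_day[rx_pah],
                   category = "pah_med_pharmacy", pah = TRUE)
  )
}

hcru_categories <- function(scope) {
  if (scope == "all_cause") {
    c("inpatient", "transplant", "er", "outpatient", "pharmacy_fills")
  } else {
    c("inpatient", "er", "outpatient", "pah_med_medical", "pah_med_pharmacy")
  }
}

#' Summarize utilization per period
#'
#' For each (period, cause scope, category): the number and percentage of
#' members with at least one event, and the PPPM event rate with the
#' pooled patient-month denominator. Events are attributed to a period when
#' their service/fill day falls in `[start_day, end_day)`.
#'
#' Under the PAH-related scope, medical events are restricted to claims
#' with a PAH diagnosis in any position, and the PAH medication categories
#' (medical administrations and pharmacy fills of PAH drugs) are reported.
#'
#' @param ds a `claims_dataset`.
#' @param periods period table from [make_periods()].
#' @param codesets a [pah_codesets()].
#' @param scope cause scopes to compute (default both).
#' @return tibble with one row per (period, scope, category):
#'   `n_members`, `months_mean`, `months_sd`, `patient_months` (pooled),
#'   `n_with_ge1`, `pct_with_ge1`, `n_events`, `pppm`.
#' @export
summarize_period <- function(ds, periods, codesets = pah_codesets(),
                             scope = c("all_cause", "pah_related")) {
  scope <- match.arg(scope, several.ok = TRUE)
  ev <- hcru_events(ds, codesets)
  hits <- ev |>
    dplyr::inner_join(periods, by = "member_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$day >= .data$start_day, .data$day < .data$end_day)
  denom <- periods |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(n_members = dplyr::n(),
                     months_mean = mean(.data$patient_months),
                     months_sd = stats::sd(.data$patient_months),
                     patient_months = sum(.data$patient_months),
                     .groups = "drop")
  purrr::map_dfr(scope, function(sc) {
    h <- if (sc == "pah_related") hits[hits$pah, , drop = FALSE] else hits
    cats <- hcru_categories(sc)
    h <- h[h$category %in% cats, , drop = FALSE]
    counts <- h |>
      dplyr::group_by(.data$period, .data$category) |>
      dplyr::summarise(n_with_ge1 = dplyr::n_distinct(.data$member_id),
                       n_events = dplyr::n(), .groups = "drop")
    tidyr::expand_grid(denom, category = cats) |>
      dplyr::left_join(counts, by = c("period", "category")) |>
      dplyr::mutate(scope = sc,
                    n_with_ge1 = dplyr::coalesce(.data$n_with_ge1, 0L),
                    n_events = dplyr::coalesce(.data$n_events, 0L),
                    pct_with_ge1 = 100 * .data$n_with_ge1 / .data$n_members,
                    pppm = .data$n_events / .data$patient_months) |>
      dplyr::relocate("period", "scope", "category")
  })
}

#' Summarize costs per period
#'
#' Claim cost = (plan paid + member paid + coordination of benefits) times
#' the inflation multiplier of the claim's calendar year. PPPM costs use
#' the pooled patient-month denominator and decompose exactly into medical
#' plus pharmacy components. Under the PAH-related scope, costs are
#' restricted to PAH-flagged claims; the baseline PAH pharmacy cell is
#' structurally missing (`NA`) because cohort members are treatment-naive
#' before index, and the PAH-related total for that period is the medical
#' component alone.
#'
#' @inheritParams summarize_period
#' @param inflation an [inflation_table()].
#' @return tibble with one row per (period, scope): `patient_months`,
#'   `medical_pppm`, `pharmacy_pppm`, `total_pppm`, and the raw adjusted
#'   sums `medical_cost`, `pharmacy_cost`.
#' @export
summarize_costs <- function(ds, periods, codesets = pah_codesets(),
                            inflation = inflation_table(),
                            scope = c("all_cause", "pah_related")) {
  scope <- match.arg(scope, several.ok = TRUE)
  md <- ds$medical_claims
  rx <- ds$pharmacy_claims
  costs <- dplyr::bind_rows(
    tibble::tibble(member_id = md$member_id, day = md$service_day,
                   bucket = "medical",
                   cost = (md$cost_plan + md$cost_member + md$cost_cob) *
                     inflation_multiplier(md$service_day, inflation),
                   pah = flag_pah_related(md, codesets)),
    tibble::tibble(member_id = rx$member_id, day = rx$fill_day,
                   bucket = "pharmacy",
                   cost = (rx$cost_plan + rx$cost_member + rx$cost_cob) *
                     inflation_multiplier(rx$fill_day, inflation),
                   pah = flag_pah_related(rx, codesets))
  )
  hits <- costs |>
    dplyr::inner_join(periods, by = "member_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$day >= .data$start_day, .data$day < .data$end_day)
  denom <- periods |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(n_members = dplyr::n(),
                     patient_months = sum(.data$patient_months),
                     .groups = "drop")
  purrr::map_dfr(scope, function(sc) {
    h <- if (sc == "pah_related") hits[hits$pah, , drop = FALSE] else hits
    sums <- h |>
      dplyr::group_by(.data$period, .data$bucket) |>
      dplyr::summarise(cost = sum(.data$cost), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "bucket", values_from = "cost",
                         values_fill = 0)
    for (b in c("medical", "pharmacy")) {
      if (!b %in% names(sums)) sums[[b]] <- 0
    }
    out <- denom |>
      dplyr::left_join(sums, by = "period") |>
      dplyr::mutate(
        scope = sc,
        medical_cost = dplyr::coalesce(.data$medical, 0),
        pharmacy_cost = dplyr::coalesce(.data$pharmacy, 0),
        medical_pppm = .data$medical_cost / .data$patient_months,
        pharmacy_pppm = .data$pharmacy_cost / .data$patient_months
      )
    if (sc == "pah_related") {
      ## treatment-naive by construction: no PAH pharmacy spend can exist
      ## before index, so the cell is structurally missing, not zero
      base <- out$period == "baseline"
      out$pharmacy_pppm[base] <- NA_real_
      out$pharmacy_cost[base] <- NA_real_
    }
    out |>
      dplyr::mutate(total_pppm = .data$medical_pppm +
                      dplyr::coalesce(.data$pharmacy_pppm, 0)) |>
      dplyr::select("period", "scope", "n_members", "patient_months",
                    "medical_cost", "pharmacy_cost",
                    "medical_pppm", "pharmacy_pppm", "total_pppm")
  })
}

#' Per-line utilization and cost summaries
#'
#' Convenience wrapper restricting [summarize_period()] and
#' [summarize_costs()] to the treatment-line periods; members contribute to
#' line k only if they initiated it.
#'
#' @inheritParams summarize_costs
#' @param lines a `pah_lot` from [segment_cohort_lines()].
#' @param cohort the `pah_cohort` the lines belong to.
#' @param max_reported_lines number of line periods.
#' @return list with `$hcru` and `$costs` tibbles keyed by
#'   `period = "line_k"`.
#' @export
per_line_summaries <- function(cohort, lines, ds, codesets = pah_codesets(),
                               inflation = inflation_table(),
                               max_reported_lines = 4L) {
  periods <- make_periods(cohort, lines,
                          max_reported_lines = max_reported_lines)
  periods <- periods[startsWith(periods$period, "line_"), , drop = FALSE]
  list(hcru = summarize_period(ds, periods, codesets),
       costs = summarize_costs(ds, periods, codesets, inflation))
}
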
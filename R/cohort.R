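## Cohort selection: eight sequential inclusion/exclusion criteria applied
## to a claims dataset, producing the indexed analytic cohort and an
## attrition report. The index date is the member's first PAH medication
## claim (fill or medical administration) in the identification window.

#' Cohort selection settings
#'
#' Defaults encode the study frame: a member-identification window of
#' 2015-10-01 through 2020-11-30, a 6-month (183-day) baseline, at least 30
#' days of post-index enrollment, and a study end of 2020-12-31.
#'
#' @param id_window_start,id_window_end first and last day (inclusive) on
#'   which an index-defining PAH medication claim may fall, as epoch day
#'   offsets.
#' @param baseline_days length of the baseline window preceding the index
#'   date; the diagnosis and RHC criteria look back this far ("6 months" is
#'   implemented as a fixed 183 days for reproducibility).
#' @param min_postindex_days minimum continuous enrollment after index.
#' @param study_end_day last day of the study period (inclusive); follow-up
#'   is censored at the earlier of disenrollment and `study_end_day + 1`.
#' @param adult_age minimum age at index.
#' @param age_strict if `TRUE`, require age strictly greater than
#'   `adult_age`; the default keeps `>=`.
#' @param bridge_gap administrative enrollment gaps up to this many days
#'   are bridged before continuity checks (0 = strictly continuous).
#' @return a `selection_config` list.
#' @export
selection_config <- function(id_window_start = 0L,
                             id_window_end = date_to_day("2020-11-30"),
                             baseline_days = 183L,
                             min_postindex_days = 30L,
                             study_end_day = date_to_day("2020-12-31"),
                             adult_age = 18L,
                             age_strict = FALSE,
                             bridge_gap = 0L) {
  stopifnot(baseline_days > 0, min_postindex_days >= 1,
            id_window_start <= id_window_end,
            id_window_end <= study_end_day)
  structure(
    list(id_window_start = as.integer(id_window_start),
         id_window_end = as.integer(id_window_end),
         baseline_days = as.integer(baseline_days),
         min_postindex_days = as.integer(min_postindex_days),
         study_end_day = as.integer(study_end_day),
         adult_age = as.integer(adult_age),
         age_strict = isTRUE(age_strict),
         bridge_gap = as.integer(bridge_gap)),
    class = "selection_config"
  )
}

#' Find a member's index day
#'
#' The earliest PAH medication claim (pharmacy fill or medical
#' administration) inside the identification window.
#'
#' @param med_claims one member's medication claims (as from
#'   [pah_med_claims()]).
#' @param config a [selection_config()].
#' @return the index day, or `NA` if the member has no in-window claim.
#' @export
find_index <- function(med_claims, config = selection_config()) {
  d <- med_claims$day[med_claims$day >= config$id_window_start &
                        med_claims$day <= config$id_window_end]
  if (length(d) == 0) NA_integer_ else min(d)
}

#' Diagnosis criterion: PH/PAH coded in the baseline window
#'
#' True when, within `[index - baseline_days, index]` (index day
#' inclusive), the member has at least one inpatient claim with a
#' qualifying diagnosis in any position, or qualifying outpatient/ER
#' claims on at least two distinct service days.
#'
#' @param medical_claims one member's medical claims.
#' @param index_day the member's index day.
#' @param codesets a [pah_codesets()].
#' @param config a [selection_config()].
#' @return logical.
#' @export
check_dx_criterion <- function(medical_claims, index_day,
                               codesets = pah_codesets(),
                               config = selection_config()) {
  lo <- index_day - config$baseline_days
  mc <- medical_claims[medical_claims$service_day >= lo &
                         medical_claims$service_day <= index_day, , drop = FALSE]
  if (nrow(mc) == 0) return(FALSE)
  pah <- has_pah_dx(mc$dx_codes, codesets)
  if (any(pah & mc$setting == "inpatient")) return(TRUE)
  out_days <- unique(mc$service_day[pah & mc$setting %in% c("outpatient", "er")])
  length(out_days) >= 2
}

#' RHC criterion: right heart catheterization in the baseline window
#'
#' True when any claim in `[index - baseline_days, index]` carries a
#' configured RHC procedure code.
#'
#' @inheritParams check_dx_criterion
#' @return logical.
#' @export
check_rhc <- function(medical_claims, index_day,
                      codesets = pah_codesets(),
                      config = selection_config()) {
  lo <- index_day - config$baseline_days
  mc <- medical_claims[medical_claims$service_day >= lo &
                         medical_claims$service_day <= index_day, , drop = FALSE]
  if (nrow(mc) == 0) return(FALSE)
  any(has_proc(mc$proc_codes, codesets$rhc_proc_codes))
}

#' Treatment-naive criterion
#'
#' True when the member has no PAH medication claim on any day from the
#' start of their continuous enrollment up to the day before index.
#'
#' @param med_claims one member's medication claims (all days).
#' @param enroll_start_day start of the continuous enrollment span
#'   containing the index day.
#' @param index_day the member's index day.
#' @return logical.
#' @export
check_treatment_naive <- function(med_claims, enroll_start_day, index_day) {
  !any(med_claims$day >= enroll_start_day & med_claims$day <= index_day - 1L)
}

#' Apply the eight sequential selection criteria
#'
#' Steps: (1) in-database membership, (2) at least one PAH medication claim
#' in the identification window (the earliest sets the index date),
#' (3) adult age at index, (4) baseline PH/PAH diagnosis criterion,
#' (5) baseline RHC claim, (6) treatment-naive before index, (7) at least
#' `baseline_days` of continuous enrollment before index, (8) at least
#' `min_postindex_days` of continuous enrollment after index. Counts after
#' each step form the attrition report.
#'
#' @param ds a `claims_dataset`.
#' @param codesets a [pah_codesets()].
#' @param config a [selection_config()].
#' @param lot a [lot_config()] (supplies the assumed days' supply for
#'   HCPCS-coded medication administrations when finding the index).
#' @return a `pah_cohort` tibble: one row per selected member with
#'   `member_id`, `index_day`, `age_at_index`, `baseline_start`,
#'   `censor_day`, `enroll_start`, `enroll_end`, `followup_days`,
#'   `followup_months`; the attrition report is attached as
#'   `attr(, "attrition")` and retrievable with [attrition_report()].
#' @export
select_cohort <- function(ds, codesets = pah_codesets(),
                          config = selection_config(),
                          lot = lot_config()) {
  med <- pah_med_claims(ds, codesets, lot)
  enr <- normalize_enrollment(ds$enrollment, bridge_gap = config$bridge_gap)

  steps <- c("Members in the database during the identification window",
             ">=1 PAH medication claim in the window; first claim sets the index date",
             paste0("Age ", if (config$age_strict) ">" else ">=", " ",
                    config$adult_age, " years on the index date"),
             ">=1 inpatient or >=2 outpatient claims on distinct dates with a PH/PAH diagnosis in the baseline window",
             ">=1 right heart catheterization claim in the baseline window",
             "No PAH medication claim from start of continuous enrollment to the day before index",
             paste0(">=", config$baseline_days, " days continuous enrollment before index"),
             paste0(">=", config$min_postindex_days, " days continuous enrollment after index"))
  n_steps <- integer(8)

  ## step 1: in database
  cur <- tibble::tibble(member_id = ds$members$member_id)
  n_steps[1] <- nrow(cur)

  ## step 2: index assignment
  in_win <- med[!is.na(med$day) & med$day >= config$id_window_start &
                  med$day <= config$id_window_end, , drop = FALSE]
  idx <- if (nrow(in_win) == 0) {
    tibble::tibble(member_id = character(), index_day = integer())
  } else {
    in_win |>
      dplyr::group_by(.data$member_id) |>
      dplyr::summarise(index_day = min(.data$day), .groups = "drop")
  }
  cur <- dplyr::inner_join(cur, idx, by = "member_id")
  n_steps[2] <- nrow(cur)

  ## step 3: adult at index (year precision: claims carry birth year only)
  cur <- cur |>
    dplyr::left_join(ds$members[, c("member_id", "birth_year")], by = "member_id") |>
    dplyr::mutate(age_at_index = day_to_year(.data$index_day) - .data$birth_year)
  cur <- if (config$age_strict) {
    dplyr::filter(cur, .data$age_at_index > config$adult_age)
  } else {
    dplyr::filter(cur, .data$age_at_index >= config$adult_age)
  }
  n_steps[3] <- nrow(cur)

  ## step 4: diagnosis criterion
  md <- ds$medical_claims
  md_pah <- md[has_pah_dx(md$dx_codes, codesets), c("member_id", "service_day", "setting")]
  dx_ok <- md_pah |>
    dplyr::inner_join(cur[, c("member_id", "index_day")], by = "member_id") |>
    dplyr::filter(.data$service_day >= .data$index_day - config$baseline_days,
                  .data$service_day <= .data$index_day) |>
    dplyr::group_by(.data$member_id) |>
    dplyr::summarise(
      ok = any(.data$setting == "inpatient") ||
        dplyr::n_distinct(.data$service_day[.data$setting %in% c("outpatient", "er")]) >= 2,
      .groups = "drop") |>
    dplyr::filter(.data$ok)
  cur <- dplyr::semi_join(cur, dx_ok, by = "member_id")
  n_steps[4] <- nrow(cur)

  ## step 5: RHC criterion
  md_rhc <- md[has_proc(md$proc_codes, codesets$rhc_proc_codes),
               c("member_id", "service_day")]
  rhc_ok <- md_rhc |>
    dplyr::inner_join(cur[, c("member_id", "index_day")], by = "member_id") |>
    dplyr::filter(.data$service_day >= .data$index_day - config$baseline_days,
                  .data$service_day <= .data$index_day) |>
    dplyr::distinct(.data$member_id)
  cur <- dplyr::semi_join(cur, rhc_ok, by = "member_id")
  n_steps[5] <- nrow(cur)

  ## enrollment span containing the index day (used by steps 6-8)
  span <- enr |>
    dplyr::inner_join(cur[, c("member_id", "index_day")], by = "member_id") |>
    dplyr::filter(.data$start_day <= .data$index_day,
                  .data$index_day < .data$end_day) |>
    dplyr::select("member_id", enroll_start = "start_day", enroll_end = "end_day")
  cur <- dplyr::left_join(cur, span, by = "member_id")

  ## step 6: treatment-naive (scan from start of continuous enrollment;
  ## members not enrolled at index scan their whole history)
  prior <- med |>
    dplyr::inner_join(cur[, c("member_id", "index_day", "enroll_start")],
                      by = "member_id") |>
    dplyr::filter(.data$day <= .data$index_day - 1L,
                  is.na(.data$enroll_start) | .data$day >= .data$enroll_start) |>
    dplyr::distinct(.data$member_id)
  cur <- dplyr::anti_join(cur, prior, by = "member_id")
  n_steps[6] <- nrow(cur)

  ## step 7: baseline continuous enrollment
  cur <- dplyr::filter(cur, !is.na(.data$enroll_start),
                       .data$enroll_start <= .data$index_day - config$baseline_days)
  n_steps[7] <- nrow(cur)

  ## step 8: post-index continuous enrollment
  cur <- dplyr::filter(cur, .data$enroll_end >= .data$index_day + config$min_postindex_days)
  n_steps[8] <- nrow(cur)

  cohort <- cur |>
    dplyr::mutate(
      baseline_start = .data$index_day - config$baseline_days,
      censor_day = pmin(.data$enroll_end, config$study_end_day + 1L),
      followup_days = .data$censor_day - .data$index_day,
      followup_months = days_to_months(.data$followup_days)
    ) |>
    dplyr::select("member_id", "index_day", "age_at_index", "baseline_start",
                  "censor_day", "enroll_start", "enroll_end",
                  "followup_days", "followup_months") |>
    dplyr::arrange(.data$member_id)

  report <- tibble::tibble(
    step = 1:8,
    criteria = steps,
    n_remaining = n_steps,
    pct_of_previous = c(NA, 100 * n_steps[-1] / pmax(n_steps[-8], 1))
  )
  class(report) <- c("attrition_report", class(report))
  attr(cohort, "attrition") <- report
  class(cohort) <- c("pah_cohort", class(cohort))
  cohort
}

#' Retrieve the attrition report attached to a cohort
#'
#' @param cohort a `pah_cohort` from [select_cohort()].
#' @return the `attrition_report` tibble (step, criteria, n_remaining,
#'   pct_of_previous).
#' @export
attrition_report <- function(cohort) {
  attr(cohort, "attrition")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Attrition (", x$n_remaining[1], " -> ", x$n_remaining[8],
      " members)\n", sep = "")
  NextMethod()
}
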
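## Claims data model: an in-memory dataset is a list of four tibbles
## (members, enrollment, medical_claims, pharmacy_claims) with integer day
## offsets, validated against the schema invariants below. Multi-valued
## code fields (dx_codes, proc_codes) are ';'-separated strings so the
## on-disk format stays plain RFC-4180 CSV.

members_cols <- function() {
  c(member_id = "character", birth_year = "integer", sex = "character",
    insurance = "character", region = "character", qci = "double")
}

enrollment_cols <- function() {
  c(member_id = "character", start_day = "integer", end_day = "integer",
    benefit = "character")
}

medical_cols <- function() {
  c(member_id = "character", service_day = "integer", setting = "character",
    dx_codes = "character", proc_codes = "character",
    hcpcs_drug_code = "character",
    cost_plan = "double", cost_member = "double", cost_cob = "double")
}

pharmacy_cols <- function() {
  c(member_id = "character", fill_day = "integer", drug_code = "character",
    days_supply = "integer",
    cost_plan = "double", cost_member = "double", cost_cob = "double")
}

#' Construct a validated claims dataset
#'
#' Bundles the four claims tables into a `claims_dataset` object and checks
#' the schema invariants: unique member ids, positive days' supply,
#' non-negative finite costs, half-open enrollment spans with
#' `start_day < end_day`, and referential integrity of every claim's
#' `member_id` against the member table.
#'
#' @param members,enrollment,medical_claims,pharmacy_claims data frames
#'   following the documented schema (see `write_claims_dataset()` for the
#'   data dictionary).
#' @param codesets a [pah_codesets()] object; drug codes absent from its
#'   class map are retained but flagged in the `unknown_drug_codes`
#'   attribute.
#' @param validate set `FALSE` to skip invariant checks (internal use).
#' @return a `claims_dataset`: a named list of four tibbles.
#' @export
claims_dataset <- function(members, enrollment, medical_claims,
                           pharmacy_claims, codesets = pah_codesets(),
                           validate = TRUE) {
  ds <- structure(
    list(members = coerce_table(members, members_cols(), "members"),
         enrollment = coerce_table(enrollment, enrollment_cols(), "enrollment"),
         medical_claims = coerce_table(medical_claims, medical_cols(), "medical_claims"),
         pharmacy_claims = coerce_table(pharmacy_claims, pharmacy_cols(), "pharmacy_claims")),
    class = "claims_dataset"
  )
  if (validate) {
    validate_claims_dataset(ds)
    unknown <- setdiff(unique(ds$pharmacy_claims$drug_code),
                       codesets$drug_class_map$drug_code)
    ## retained in the tables, surfaced via the attribute (non-PAH
    ## background fills are expected to be unmapped)
    attr(ds, "unknown_drug_codes") <- unknown
  }
  ds
}

## Coerce a raw table to the declared column types; ISO dates in *_day
## columns are converted to epoch day offsets. Errors name the offending
## column or row.
coerce_table <- function(df, cols, table_name, epoch = PAHLOT_EPOCH) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(names(cols), names(df))
  if (length(missing) > 0) {
    stop("table '", table_name, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[names(cols)]
  for (nm in names(cols)) {
    v <- df[[nm]]
    if (cols[[nm]] == "integer") {
      if (grepl("_day$", nm) && (inherits(v, "Date") ||
          (is.character(v) && any(grepl("^\\d{4}-\\d{2}-\\d{2}$", v))))) {
        v <- date_to_day(v, epoch)
      }
      iv <- suppressWarnings(as.integer(v))
      bad <- which(is.na(iv) & !is.na(v) | (!is.na(v) & as.numeric(v) != iv))
      if (length(bad) > 0) {
        stop("table '", table_name, "', column '", nm, "': non-integer value at row ",
             bad[1], call. = FALSE)
      }
      df[[nm]] <- iv
    } else if (cols[[nm]] == "double") {
      df[[nm]] <- as.numeric(v)
    } else {
      df[[nm]] <- as.character(v)
    }
  }
  df
}

#' Check claims-dataset invariants
#'
#' @param ds a `claims_dataset`.
#' @return `ds`, invisibly; stops with an informative error on the first
#'   violated invariant (naming the table, column, and row).
#' @export
validate_claims_dataset <- function(ds) {
  stopifnot(inherits(ds, "claims_dataset"))
  m <- ds$members
  if (anyDuplicated(m$member_id)) {
    stop("members: duplicated member_id ",
         m$member_id[duplicated(m$member_id)][1], call. = FALSE)
  }
  if (any(!is.na(m$qci) & m$qci < 0)) {
    stop("members: negative qci at row ", which(m$qci < 0)[1], call. = FALSE)
  }
  e <- ds$enrollment
  if (any(e$start_day >= e$end_day)) {
    stop("enrollment: start_day >= end_day at row ",
         which(e$start_day >= e$end_day)[1], call. = FALSE)
  }
  p <- ds$pharmacy_claims
  if (any(is.na(p$days_supply) | p$days_supply < 1)) {
    stop("pharmacy_claims: days_supply < 1 at row ",
         which(is.na(p$days_supply) | p$days_supply < 1)[1], call. = FALSE)
  }
  for (tb in c("medical_claims", "pharmacy_claims")) {
    for (cc in c("cost_plan", "cost_member", "cost_cob")) {
      v <- ds[[tb]][[cc]]
      bad <- which(is.na(v) | !is.finite(v) | v < 0)
      if (length(bad) > 0) {
        stop(tb, ": invalid ", cc, " at row ", bad[1], call. = FALSE)
      }
    }
  }
  md <- ds$medical_claims
  bad_setting <- which(!md$setting %in% c("inpatient", "er", "outpatient"))
  if (length(bad_setting) > 0) {
    stop("medical_claims: unknown setting '", md$setting[bad_setting[1]],
         "' at row ", bad_setting[1], call. = FALSE)
  }
  for (tb in c("enrollment", "medical_claims", "pharmacy_claims")) {
    orphan <- setdiff(unique(ds[[tb]]$member_id), m$member_id)
    if (length(orphan) > 0) {
      stop(tb, ": member_id ", orphan[1], " not present in members table",
           call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat("  members:         ", nrow(x$members), "\n")
  cat("  enrollment spans:", nrow(x$enrollment), "\n")
  cat("  medical claims:  ", nrow(x$medical_claims), "\n")
  cat("  pharmacy claims: ", nrow(x$pharmacy_claims), "\n")
  invisible(x)
}

#' Write a claims dataset to a directory of CSV files
#'
#' Emits `members.csv`, `enrollment.csv`, `medical_claims.csv`,
#' `pharmacy_claims.csv`, and `drug_class_map.csv` (UTF-8, RFC-4180), plus a
#' `data_dictionary.csv` sidecar describing every column. Row order is
#' deterministic: member_id, then event day.
#'
#' @param ds a validated `claims_dataset`.
#' @param out_dir output directory (created if absent).
#' @param codesets the [pah_codesets()] whose drug class map is written
#'   alongside the tables.
#' @return `out_dir`, invisibly.
#' @export
write_claims_dataset <- function(ds, out_dir, codesets = pah_codesets()) {
  validate_claims_dataset(ds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ord <- list(
    members = dplyr::arrange(ds$members, .data$member_id),
    enrollment = dplyr::arrange(ds$enrollment, .data$member_id, .data$start_day),
    medical_claims = dplyr::arrange(ds$medical_claims, .data$member_id,
                                    .data$service_day, .data$setting),
    pharmacy_claims = dplyr::arrange(ds$pharmacy_claims, .data$member_id,
                                     .data$fill_day, .data$drug_code)
  )
  for (nm in names(ord)) {
    readr::write_csv(ord[[nm]], file.path(out_dir, paste0(nm, ".csv")), na = "")
  }
  readr::write_csv(codesets$drug_class_map,
                   file.path(out_dir, "drug_class_map.csv"), na = "")
  readr::write_csv(data_dictionary(), file.path(out_dir, "data_dictionary.csv"),
                   na = "")
  invisible(out_dir)
}

#' Read a claims dataset from a directory of CSV files
#'
#' Inverse of [write_claims_dataset()]. ISO dates in day columns are
#' accepted and converted to epoch day offsets; all invariants are enforced
#' on load.
#'
#' @param in_dir directory containing the CSV file set.
#' @param codesets a [pah_codesets()]; if `in_dir` contains a
#'   `drug_class_map.csv` it replaces the map inside `codesets`.
#' @return a validated `claims_dataset`.
#' @export
read_claims_dataset <- function(in_dir, codesets = pah_codesets()) {
  path <- function(nm) file.path(in_dir, paste0(nm, ".csv"))
  for (nm in c("members", "enrollment", "medical_claims", "pharmacy_claims")) {
    if (!file.exists(path(nm))) {
      stop("missing file: ", path(nm), call. = FALSE)
    }
  }
  rd <- function(nm) readr::read_csv(path(nm), show_col_types = FALSE,
                                     col_types = readr::cols(.default = "c"),
                                     na = character())
  map_file <- path("drug_class_map")
  if (file.exists(map_file)) {
    codesets$drug_class_map <- readr::read_csv(map_file, show_col_types = FALSE)
  }
  md <- rd("medical_claims")
  md$hcpcs_drug_code[md$hcpcs_drug_code == ""] <- NA_character_
  claims_dataset(rd("members"), rd("enrollment"), md, rd("pharmacy_claims"),
                 codesets = codesets)
}

data_dictionary <- function() {
  dict <- function(table, cols) {
    tibble::tibble(table = table, column = names(cols), type = unname(cols))
  }
  out <- dplyr::bind_rows(
    dict("members", members_cols()),
    dict("enrollment", enrollment_cols()),
    dict("medical_claims", medical_cols()),
    dict("pharmacy_claims", pharmacy_cols())
  )
  notes <- c(
    member_id = "opaque member identifier, unique in members",
    birth_year = "4-digit birth year; age at day d = year(d) - birth_year",
    sex = "F | M | U",
    insurance = "commercial | medicare_advantage | medicare_other",
    region = "midwest | northeast | south | west",
    qci = "pre-assigned Quan-Charlson comorbidity score",
    start_day = "integer day offset from the epoch; span is [start_day, end_day)",
    end_day = "integer day offset; exclusive",
    benefit = "medical_and_pharmacy",
    service_day = "integer day offset of service (admission day for stays)",
    setting = "inpatient | er | outpatient",
    dx_codes = "';'-separated diagnosis codes; position 1 = primary",
    proc_codes = "';'-separated procedure codes",
    hcpcs_drug_code = "drug-administration code, empty if none",
    cost_plan = "health-plan paid amount, nominal USD of service year",
    cost_member = "member paid amount",
    cost_cob = "coordination-of-benefits (third-party payer) amount",
    fill_day = "integer day offset of the pharmacy fill",
    drug_code = "pharmacy drug token; see drug_class_map.csv",
    days_supply = "days' supply dispensed, >= 1"
  )
  out$note <- unname(notes[out$column])
  out
}

#' Normalize enrollment spans
#'
#' Merges overlapping or abutting half-open spans and bridges
#' administrative gaps of at most `bridge_gap` days, returning sorted,
#' disjoint spans per member. With the default `bridge_gap = 0` the output
#' covers exactly the same days as the input ("continuous" means strictly
#' continuous).
#'
#' @param spans a data frame with `member_id`, `start_day`, `end_day`.
#' @param bridge_gap maximum gap (days) between consecutive spans that is
#'   still treated as continuous coverage.
#' @return a tibble of disjoint spans sorted by member and start day.
#' @export
#' @examples
#' normalize_enrollment(
#'   tibble::tibble(member_id = "a", start_day = c(0L, 100L), end_day = c(100L, 200L))
#' )
normalize_enrollment <- function(spans, bridge_gap = 0L) {
  spans <- tibble::as_tibble(spans)
  if (nrow(spans) == 0) {
    return(tibble::tibble(member_id = character(), start_day = integer(),
                          end_day = integer()))
  }
  spans |>
    dplyr::arrange(.data$member_id, .data$start_day, .data$end_day) |>
    dplyr::group_by(.data$member_id) |>
    dplyr::group_modify(function(df, key) {
      merge_spans(df$start_day, df$end_day, bridge_gap)
    }) |>
    dplyr::ungroup()
}

## Merge sorted half-open spans, bridging gaps <= bridge_gap days.
merge_spans <- function(start, end, bridge_gap) {
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] - me <= bridge_gap) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  tibble::tibble(start_day = c(out_s, ms), end_day = c(out_e, me))
}

## Continuous-enrollment span containing a given day (or NULL).
## Spans must already be normalized for the member.
span_containing <- function(spans, day) {
  hit <- spans$start_day <= day & day < spans$end_day
  if (!any(hit)) return(NULL)
  spans[which(hit)[1], ]
}
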
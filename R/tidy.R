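## broom-style verbs for the pipeline's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname pah_tidiers
#' @param x a result object.
#' @param ... unused.
#' @method tidy attrition_report
tidy.attrition_report <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' Tidiers for cohort, line, and pattern objects
#'
#' `tidy()` returns the underlying per-row tibble; `glance()` returns a
#' one-row summary.
#' @name pah_tidiers
NULL

#' @export
#' @rdname pah_tidiers
#' @method tidy pah_cohort
tidy.pah_cohort <- function(x, ...) {
  out <- x
  attr(out, "attrition") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @export
#' @rdname pah_tidiers
#' @method glance pah_cohort
glance.pah_cohort <- function(x, ...) {
  rep <- attrition_report(x)
  tibble::tibble(
    n_screened = rep$n_remaining[1],
    n_cohort = nrow(x),
    retention = nrow(x) / max(rep$n_remaining[1], 1),
    followup_months_mean = mean(x$followup_months),
    followup_months_sd = stats::sd(x$followup_months),
    age_mean = mean(x$age_at_index)
  )
}

#' @export
#' @rdname pah_tidiers
#' @method tidy pah_lot
tidy.pah_lot <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @export
#' @rdname pah_tidiers
#' @method glance pah_lot
glance.pah_lot <- function(x, ...) {
  per_member <- dplyr::count(x, .data$member_id)
  first <- x[x$line_number == 1, , drop = FALSE]
  tibble::tibble(
    n_members = nrow(per_member),
    n_lines = nrow(x),
    mean_lines = mean(per_member$n),
    pct_combination_first_line =
      100 * mean(first$regimen_arm == "combination"),
    months_first_line_mean = mean(first$months_in_line)
  )
}
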
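## Synthetic-population generator. Generation is trajectory-first: the
## answer key (attrition fate, index day, line sequence with end reasons,
## period costs) is sampled first, then claims are emitted that realize it
## exactly under the default engine rules, so every downstream stage can be
## tested against planted truth. Categorical mixes that the study reports
## (regimen mixes, restart shares, attrition fates) are planted exactly by
## largest-remainder allocation; event times and follow-up are drawn from
## calibrated right-skewed distributions.

## epoch day ranges of index calendar years 2015..2020
index_year_bounds <- function() {
  list(lo = c(`2015` = 0L, `2016` = 92L, `2017` = 458L, `2018` = 823L,
              `2019` = 1188L, `2020` = 1553L),
       hi = c(`2015` = 91L, `2016` = 457L, `2017` = 822L, `2018` = 1187L,
              `2019` = 1552L, `2020` = 1887L))
}

## class-prevalence weights used when composing "other" combinations
combo_class_weights <- c(ERA = 0.28, PDE5I = 0.45, SGC = 0.11,
                         PROSTA_ORAL = 0.10, PROSTA_INHALED = 0.07,
                         PROSTA_PARENTERAL = 0.09)

## length-safe single draw
pick1 <- function(x, prob = NULL) {
  if (length(x) == 1) return(x)
  sample(x, 1, prob = prob)
}

## Can a member whose previous line used `prev_classes` modify into a line
## with this regimen label? (A modification line must contain at least one
## class absent from the previous line: the triggering claim.)
label_feasible <- function(label, prev_classes) {
  if (is.null(prev_classes)) return(TRUE)
  if (startsWith(label, "MONO_")) {
    return(!(sub("^MONO_", "", label) %in% prev_classes))
  }
  if (label == "COMBO_ERA_PDE5I") {
    return(length(setdiff(c("ERA", "PDE5I"), prev_classes)) >= 1)
  }
  length(prev_classes) < length(pah_drug_classes())
}

## Materialize the class set for a regimen label. For modification
## entrants (prev_classes non-NULL) the set always contains a new class
## and preferentially keeps previous classes (sequential combination).
realize_classes <- function(label, prev_classes = NULL) {
  all_cl <- pah_drug_classes()
  if (startsWith(label, "MONO_")) {
    return(sub("^MONO_", "", label))
  }
  if (label == "COMBO_ERA_PDE5I") {
    return(c("ERA", "PDE5I"))
  }
  size <- pick1(2:3, prob = c(0.8, 0.2))
  if (!is.null(prev_classes) && length(prev_classes) > 0) {
    new_pool <- setdiff(all_cl, prev_classes)
    new1 <- pick1(new_pool, prob = combo_class_weights[new_pool])
    pool <- c(prev_classes, setdiff(all_cl, c(prev_classes, new1)))
    wts <- c(rep(3, length(prev_classes)),
             rep(1, length(pool) - length(prev_classes)))
    rest <- sample(pool, min(size - 1, length(pool)), prob = wts)
    cl <- sort(unique(c(new1, rest)))
  } else {
    cl <- sort(c("ERA", "PDE5I"))
    for (try in 1:100) {
      cl <- sort(sample(all_cl, size, prob = combo_class_weights[all_cl]))
      if (!identical(cl, sort(c("ERA", "PDE5I")))) break
    }
  }
  if (identical(cl, sort(c("ERA", "PDE5I")))) {
    cl <- sort(c(cl, pick1(setdiff(all_cl, cl))))
  }
  cl
}

## Exact largest-remainder label allocation over entrants, honoring
## modification feasibility; prev_list[[i]] is NULL for unconstrained
## entrants (line 1 and restart entrants).
alloc_labels <- function(prev_list, mix) {
  n <- length(prev_list)
  if (n == 0) return(character(0))
  remaining <- alloc_counts(n, mix)
  feas_mat <- vapply(names(remaining), function(lab) {
    vapply(prev_list, function(pc) label_feasible(lab, pc), logical(1))
  }, logical(n))
  feas_mat <- matrix(feas_mat, nrow = n,
                     dimnames = list(NULL, names(remaining)))
  ## most-constrained entrants pick first so feasible labels are not
  ## exhausted by unconstrained ones
  ord <- sample.int(n)
  ord <- ord[order(rowSums(feas_mat)[ord])]
  labels <- character(n)
  for (i in ord) {
    feas <- names(remaining)[remaining > 0 & feas_mat[i, ]]
    if (length(feas) == 0) {
      ## pool exhausted for this entrant: draw any feasible label from the
      ## original mix so the realized shares stay close to it
      feas_all <- names(mix)[feas_mat[i, ]]
      labels[i] <- if (length(feas_all) > 0) {
        pick1(feas_all, prob = mix[feas_all])
      } else {
        paste0("MONO_", setdiff(pah_drug_classes(), prev_list[[i]])[1])
      }
    } else {
      lab <- pick1(feas, prob = remaining[feas])
      remaining[lab] <- remaining[lab] - 1L
      labels[i] <- lab
    }
  }
  labels
}

## Draw one batch of candidate event times (months) from the per-line
## mixture model.
r_event_time <- function(m, p) {
  fast <- stats::runif(m) < p$w
  t <- numeric(m)
  if (any(fast)) t[fast] <- stats::runif(sum(fast), 1.05, p$fast_hi)
  if (any(!fast)) t[!fast] <- rlnorm_trunc(sum(!fast), p$meanlog, p$sdlog, 1.05)
  t
}

## Sample the full line structure (starts, ends, reasons; days relative to
## index) for nc cohort members. Line-1 restarts are planted exactly.
sample_trajectories <- function(nc, config) {
  fpars <- lnorm_pars(config$followup_months[["mean"]],
                      config$followup_months[["sd"]])
  F_days <- pmax(32L, as.integer(round(
    rlnorm_trunc(nc, fpars[["meanlog"]], fpars[["sdlog"]], 1.05, 63) *
      DAYS_PER_MONTH)))
  start <- rep(0L, nc)
  alive <- rep(TRUE, nc)
  rows <- list()
  k <- 1L
  while (any(alive)) {
    if (k > 80L) stop("trajectory recursion did not terminate", call. = FALSE)
    p <- config$line_event_model[[min(k, length(config$line_event_model))]]
    idx <- which(alive)
    m <- length(idx)
    R <- F_days[idx] - start[idx]
    is_int <- stats::runif(m) < p$q
    T_days <- pmax(32L, as.integer(round(r_event_time(m, p) * DAYS_PER_MONTH)))
    obs_int <- is_int & (T_days + 61L <= R)
    obs_mod <- !is_int & (T_days <= R - 2L)
    remain <- !(obs_int | obs_mod)
    reason <- ifelse(remain, "censored",
                     ifelse(obs_int, "interruption", "modification"))
    end_rel <- ifelse(remain, F_days[idx], start[idx] + T_days)
    eligible <- obs_int & (R - T_days >= 90L)
    p_restart <- config$restart_prob[min(k, length(config$restart_prob))]
    if (k == 1L) {
      ## plant the restart share exactly among first-line interrupters
      n_int <- sum(obs_int)
      n_restart <- alloc_counts(n_int, c(r = p_restart, n = 1 - p_restart))[["r"]]
      restart <- logical(m)
      eli <- which(eligible)
      if (length(eli) > 0 && n_restart > 0) {
        restart[eli[sample.int(length(eli), min(n_restart, length(eli)))]] <- TRUE
      }
    } else {
      restart <- eligible & (stats::runif(m) < p_restart)
    }
    gap <- pmin(sample(75:180, m, replace = TRUE), R - T_days - 14L)
    rows[[k]] <- tibble::tibble(
      i = idx, line_number = k, start = start[idx],
      end = as.integer(end_rel), end_reason = reason
    )
    alive[idx] <- obs_mod | restart
    start[idx] <- as.integer(ifelse(obs_mod, start[idx] + T_days,
                                    ifelse(restart, start[idx] + T_days + gap,
                                           start[idx])))
    k <- k + 1L
  }
  list(F_days = F_days, lines = dplyr::bind_rows(rows))
}

## Assign regimen labels and class sets to every planted line. Mixes for
## lines 1-4 are planted exactly; lines beyond 4 draw from the line-4 mix.
assign_regimens <- function(lines, config) {
  lines <- dplyr::arrange(lines, .data$line_number, .data$i)
  lines$regimen <- NA_character_
  lines$classes <- NA_character_
  prev_classes <- list()  # by member i: classes of their previous line
  prev_reason <- list()
  mixes <- config$later_line_regimen_mixes
  for (k in sort(unique(lines$line_number))) {
    rows_k <- which(lines$line_number == k)
    ids <- lines$i[rows_k]
    prevs <- lapply(seq_along(ids), function(j) {
      if (k == 1L) return(NULL)
      if (identical(prev_reason[[ids[j]]], "modification")) {
        prev_classes[[ids[j]]]
      } else {
        NULL  # restart entrants are unconstrained
      }
    })
    mix <- if (k == 1L) {
      config$first_line_regimen_mix
    } else if (k == 2L) {
      mixes$line2
    } else if (k == 3L) {
      mixes$line3
    } else {
      mixes$line4plus
    }
    labels <- if (k <= 4L) {
      alloc_labels(prevs, mix)
    } else {
      vapply(prevs, function(pc) {
        for (try in 1:50) {
          lab <- pick1(names(mix), prob = mix)
          if (label_feasible(lab, pc)) return(lab)
        }
        "COMBO_OTHER"
      }, character(1))
    }
    for (j in seq_along(rows_k)) {
      cl <- realize_classes(labels[j], prevs[[j]])
      lines$regimen[rows_k[j]] <- labels[j]
      lines$classes[rows_k[j]] <- paste(sort(cl), collapse = ";")
      prev_classes[[ids[j]]] <- sort(cl)
      prev_reason[[ids[j]]] <- lines$end_reason[rows_k[j]]
    }
  }
  lines
}

## Sample an index day consistent with the member's follow-up: the
## configured year mix restricted to years in which index + follow-up
## still fits inside the study period.
sample_index_day <- function(F_days, config, study_cap = 1919L) {
  yb <- index_year_bounds()
  latest <- study_cap - F_days
  feasible <- yb$lo <= latest
  w <- config$index_year_mix[feasible]
  yr <- pick1(names(w), prob = w)
  hi <- min(yb$hi[[yr]], latest)
  pick1(seq.int(yb$lo[[yr]], hi))
}

## Attrition fates: 0 = cohort, 2..8 = first failing step; planted exactly.
sample_attrition_fates <- function(n, pass) {
  p_fail <- numeric(7)
  carry <- 1
  for (j in seq_along(pass)) {
    p_fail[j] <- carry * (1 - pass[[j]])
    carry <- carry * pass[[j]]
  }
  probs <- c(stats::setNames(p_fail, paste0("fail", 2:8)), cohort = carry)
  counts <- alloc_counts(n, probs)
  fates <- rep(c(2:8, 0L), counts)
  fates[sample.int(length(fates))]
}

#' Generate a synthetic claims population with planted ground truth
#'
#' Draws attrition fates, trajectories (follow-up, line sequence with end
#' reasons, regimens), demographics, and costs per member, then emits the
#' claims that realize them exactly under the default engine rules. The
#' returned answer key records, per member, the planted index day,
#' attrition fate, line sequence, and period costs, so pipeline output can
#' be compared with zero tolerance. Deterministic for a fixed
#' (config, seed).
#'
#' @param config a [generator_config()].
#' @param codesets a [pah_codesets()].
#' @param inflation an [inflation_table()]; planted 2020-USD costs are
#'   deflated to nominal claim dollars with it, so re-adjusting during
#'   analysis recovers them exactly.
#' @return a `pah_population` list with `$dataset` (a `claims_dataset`),
#'   `$truth` (a `planted_truth` list of `members`, `lines`, `costs`
#'   tibbles), and `$config`.
#' @export
generate_population <- function(config = generator_config(),
                                codesets = pah_codesets(),
                                inflation = inflation_table()) {
  set.seed(config$seed)
  n <- config$n_members
  ids <- sprintf("M%05d", seq_len(n))
  fates <- sample_attrition_fates(n, config$attrition_pass)
  cohort_pos <- which(fates == 0L)
  nc <- length(cohort_pos)

  traj <- if (nc > 0) sample_trajectories(nc, config) else
    list(F_days = integer(0), lines = tibble::tibble())
  lines <- if (nc > 0) assign_regimens(traj$lines, config) else traj$lines

  dem <- config$demographics
  specs <- vector("list", n)
  ci <- 0L
  for (j in seq_len(n)) {
    if (fates[j] == 0L) {
      ci <- ci + 1L
      F_days <- traj$F_days[ci]
      idx <- sample_index_day(F_days, config)
      age <- round(rnorm_trunc(1, dem$age[["mean"]], dem$age[["sd"]],
                               dem$age[["lo"]], dem$age[["hi"]]))
      ml <- lines[lines$i == ci, c("line_number", "start", "end",
                                   "end_reason", "classes", "regimen")]
      fpars <- lnorm_pars(config$preindex_months[["mean"]],
                          config$preindex_months[["sd"]])
      pre_days <- as.integer(round(
        rlnorm_trunc(1, fpars[["meanlog"]], fpars[["sdlog"]], 6.3, 240) *
          DAYS_PER_MONTH))
      specs[[j]] <- list(
        member_id = ids[j], fail_step = NA_integer_, index_day = idx,
        followup_days = F_days, pre_days = pre_days,
        birth_year = day_to_year(idx) - age,
        sex = pick1(c("F", "M"), prob = c(dem$female, 1 - dem$female)),
        insurance = pick1(names(dem$insurance), prob = dem$insurance),
        region = pick1(names(dem$region), prob = dem$region),
        qci = round(rnorm_trunc(1, dem$qci[["mean"]], dem$qci[["sd"]],
                                dem$qci[["lo"]], dem$qci[["hi"]]), 1),
        lines = ml
      )
    } else {
      idx <- if (fates[j] == 2L) NA_integer_ else
        pick1(seq.int(300L, if (fates[j] == 6L) 850L else 1500L))
      age <- if (fates[j] == 3L) 16L else
        round(rnorm_trunc(1, dem$age[["mean"]], dem$age[["sd"]],
                          dem$age[["lo"]], dem$age[["hi"]]))
      specs[[j]] <- list(
        member_id = ids[j], fail_step = fates[j], index_day = idx,
        followup_days = NA_integer_, pre_days = NA_integer_,
        birth_year = if (is.na(idx)) 1960L else day_to_year(idx) - age,
        sex = pick1(c("F", "M"), prob = c(dem$female, 1 - dem$female)),
        insurance = pick1(names(dem$insurance), prob = dem$insurance),
        region = pick1(names(dem$region), prob = dem$region),
        qci = round(rnorm_trunc(1, dem$qci[["mean"]], dem$qci[["sd"]],
                                dem$qci[["lo"]], dem$qci[["hi"]]), 1),
        lines = NULL
      )
    }
  }

  parts <- lapply(specs, plant_member, config = config,
                  codesets = codesets, inflation = inflation)
  members <- dplyr::bind_rows(lapply(parts, `[[`, "member"))
  enrollment <- dplyr::bind_rows(lapply(parts, `[[`, "enrollment"))
  medical <- dplyr::bind_rows(lapply(parts, `[[`, "medical"))
  pharmacy <- dplyr::bind_rows(lapply(parts, `[[`, "pharmacy"))
  ds <- claims_dataset(members, enrollment, medical, pharmacy,
                       codesets = codesets)

  truth_members <- dplyr::bind_rows(lapply(parts, `[[`, "truth_member"))
  truth_lines <- dplyr::bind_rows(lapply(parts, `[[`, "truth_lines"))
  truth_costs <- dplyr::bind_rows(lapply(parts, `[[`, "truth_costs"))
  truth <- structure(list(members = truth_members, lines = truth_lines,
                          costs = truth_costs),
                     class = "planted_truth")
  structure(list(dataset = ds, truth = truth, config = config),
            class = "pah_population")
}

#' @export
print.pah_population <- function(x, ...) {
  cat("<pah_population> n =", nrow(x$dataset$members),
      "| planted cohort =", sum(x$truth$members$fate == "cohort"), "\n")
  invisible(x)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>", nrow(x$members), "members,",
      nrow(x$lines), "planted lines\n")
  invisible(x)
}
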
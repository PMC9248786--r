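## Claim emission: turn one member's planted specification (attrition
## fate, index day, line sequence) into claims that the default engine
## recovers exactly. Fill timing deliberately avoids every tie-break band:
## within-line refills are contiguous, modification and censoring leave at
## most a 15-day tail of uncovered time (well under the 60-day grace), and
## restart gaps are at least 75 days (well over it). Class-formation
## offsets stay at most 27 days after a line start, inside the 30-day
## window regardless of its boundary convention.

dx_pool_other <- c("I50.9", "J44.9", "E11.9", "I10", "N18.3", "F41.1",
                   "F32.9", "I73.9")

rand_dx <- function(codesets, pah = FALSE) {
  oth <- pick1(dx_pool_other)
  if (!pah) return(oth)
  pah_code <- pick1(codesets$pah_dx_codes)
  ## any-position rule: the PAH code is sometimes secondary
  if (stats::runif(1) < 0.5) paste(pah_code, oth, sep = ";") else
    paste(oth, pah_code, sep = ";")
}

## Emit fills (pharmacy rows and medication-administration medical rows)
## realizing a member's planted line table (days relative to index).
emit_line_fills <- function(lines, config) {
  hc_map <- hcpcs_for_drug()
  rx_day <- integer(0); rx_drug <- character(0); rx_supply <- integer(0)
  ad_day <- integer(0); ad_code <- character(0)
  prev_classes <- NULL
  for (r in seq_len(nrow(lines))) {
    cl <- strsplit(lines$classes[r], ";", fixed = TRUE)[[1]]
    reason <- lines$end_reason[r]
    s <- lines$start[r]
    dur <- lines$end[r] - s
    anchor_pool <- if (r > 1 && lines$end_reason[r - 1] == "modification") {
      setdiff(cl, prev_classes)
    } else {
      cl
    }
    anchor <- pick1(anchor_pool)
    others <- setdiff(cl, anchor)
    off_max <- min(27L, dur - 1L)
    cand <- if (off_max >= 3L) seq.int(3L, off_max) else seq.int(1L, max(1L, off_max))
    offs <- stats::setNames(c(0L, if (length(others))
      cand[sample.int(length(cand), length(others),
                      replace = length(cand) < length(others))]),
      c(anchor, others))
    e_anchor <- if (reason == "interruption") dur else
      max(1L, dur - pick1(0:min(15L, dur - 1L)))
    for (c2 in c(anchor, others)) {
      o <- offs[[c2]]
      e_target <- if (c2 == anchor) e_anchor else
        max(o + 1L, e_anchor - pick1(0:10))
      supply <- as.integer(pick1(names(config$days_supply_choices),
                                 prob = config$days_supply_choices))
      mix <- config$drug_mixes[[c2]]
      drug <- pick1(names(mix), prob = mix)
      fd <- seq.int(o, e_target - 1L, by = supply)
      sup <- rep(supply, length(fd))
      sup[length(fd)] <- e_target - fd[length(fd)]
      ## some 30-day fills of inhaled/parenteral prostacyclins are billed
      ## as medical administrations (same coverage contribution)
      can_admin <- !is.na(hc_map[drug]) & sup == 30L
      as_admin <- can_admin & stats::runif(length(fd)) < 0.5
      rx_day <- c(rx_day, s + fd[!as_admin])
      rx_drug <- c(rx_drug, rep(drug, sum(!as_admin)))
      rx_supply <- c(rx_supply, sup[!as_admin])
      ad_day <- c(ad_day, s + fd[as_admin])
      ad_code <- c(ad_code, rep(unname(hc_map[drug]), sum(as_admin)))
    }
    prev_classes <- cl
  }
  list(rx = tibble::tibble(day = rx_day, drug_code = rx_drug,
                           days_supply = rx_supply),
       admin = tibble::tibble(day = ad_day, hcpcs = ad_code))
}

## Distribute the member's planted period cost budgets (2020 USD PPPM
## targets x months x a lognormal member factor) over their claims, then
## deflate to nominal dollars by service year. Returns per-claim nominal
## cost components plus the realized adjusted sums per period (the answer
## key for cost recovery).
assign_member_costs <- function(md, rx, index_day, followup_days,
                                config, inflation) {
  cm <- config$cost_model
  f <- stats::rlnorm(1, -cm$member_sigma^2 / 2, cm$member_sigma)
  per_start <- c(baseline = index_day - 183L, postindex = index_day)
  per_end <- c(baseline = index_day, postindex = index_day + followup_days)
  months <- days_to_months(per_end - per_start)
  md$cost2020 <- 0
  rx$cost2020 <- 0
  noise <- function(k) stats::rlnorm(k, -cm$claim_sigma^2 / 2, cm$claim_sigma)
  for (per in c("baseline", "postindex")) {
    tgt <- cm[[per]]
    in_md <- md$day >= per_start[[per]] & md$day < per_end[[per]]
    in_rx <- rx$day >= per_start[[per]] & rx$day < per_end[[per]]
    ## medical: PAH-related and other buckets, reallocated if one is empty
    med_b <- c(pah = tgt[["medical_pah"]], other = tgt[["medical_other"]]) *
      months[[per]] * f
    sel <- list(pah = in_md & md$pah, other = in_md & !md$pah)
    for (b in c("pah", "other")) {
      if (!any(sel[[b]])) {
        med_b[setdiff(c("pah", "other"), b)] <-
          med_b[setdiff(c("pah", "other"), b)] + med_b[[b]]
        med_b[[b]] <- 0
      }
    }
    for (b in c("pah", "other")) {
      if (any(sel[[b]]) && med_b[[b]] > 0) {
        w <- cm$setting_weights[md$setting[sel[[b]]]] * noise(sum(sel[[b]]))
        md$cost2020[sel[[b]]] <- med_b[[b]] * w / sum(w)
      }
    }
    rx_b <- c(pah = tgt[["pharmacy_pah"]], other = tgt[["pharmacy_other"]]) *
      months[[per]] * f
    rsel <- list(pah = in_rx & rx$pah, other = in_rx & !rx$pah)
    for (b in c("pah", "other")) {
      if (!any(rsel[[b]])) {
        rx_b[setdiff(c("pah", "other"), b)] <-
          rx_b[setdiff(c("pah", "other"), b)] + rx_b[[b]]
        rx_b[[b]] <- 0
      }
    }
    cw <- cm$class_weights
    for (b in c("pah", "other")) {
      if (any(rsel[[b]]) && rx_b[[b]] > 0) {
        wkey <- if (b == "pah") rx$drug_class[rsel[[b]]] else
          rep("other", sum(rsel[[b]]))
        w <- cw[wkey] * noise(sum(rsel[[b]]))
        rx$cost2020[rsel[[b]]] <- rx_b[[b]] * w / sum(w)
      }
    }
  }
  md <- split_cost(md, inflation)
  rx <- split_cost(rx, inflation)
  truth <- purrr::map_dfr(c("baseline", "postindex"), function(per) {
    in_md <- md$day >= per_start[[per]] & md$day < per_end[[per]]
    in_rx <- rx$day >= per_start[[per]] & rx$day < per_end[[per]]
    tibble::tibble(
      period = per,
      patient_months = months[[per]],
      medical_cost = sum(md$adj[in_md]),
      medical_pah_cost = sum(md$adj[in_md & md$pah]),
      pharmacy_cost = sum(rx$adj[in_rx]),
      pharmacy_pah_cost = sum(rx$adj[in_rx & rx$pah])
    )
  })
  list(md = md, rx = rx, truth = truth)
}

## nominal components (rounded to cents) and the adjusted total the
## analysis pipeline will recompute
split_cost <- function(df, inflation) {
  if (nrow(df) == 0) {
    df$cost_plan <- df$cost_member <- df$cost_cob <- df$adj <- numeric(0)
    return(df)
  }
  mult <- inflation_multiplier(df$day, inflation)
  nominal <- round(df$cost2020 / mult, 2)
  df$cost_plan <- round(0.8 * nominal, 2)
  df$cost_member <- round(0.15 * nominal, 2)
  df$cost_cob <- pmax(0, round(nominal - df$cost_plan - df$cost_member, 2))
  df$adj <- (df$cost_plan + df$cost_member + df$cost_cob) * mult
  df
}

#' Emit the claims realizing one planted member specification
#'
#' The workhorse behind [generate_population()], exported so tests can
#' plant hand-built trajectories. Cohort members (`fail_step = NA`) get
#' enrollment, baseline diagnosis and RHC evidence, medication fills
#' realizing each planted line, utilization events, and costs; members
#' planted to fail selection step k get exactly the claims that pass steps
#' 2..k-1 and fail step k.
#'
#' @param spec a list with `member_id`, `fail_step` (`NA` or 2-8),
#'   `index_day`, `followup_days`, `pre_days`, `birth_year`, `sex`,
#'   `insurance`, `region`, `qci`, and for cohort members `lines` (a data
#'   frame with `line_number`, `start`, `end` in days relative to index,
#'   `end_reason`, `classes` as a ';'-joined string, `regimen`).
#' @param config a [generator_config()].
#' @param codesets a [pah_codesets()].
#' @param inflation an [inflation_table()].
#' @return list of one-member table rows (`member`, `enrollment`,
#'   `medical`, `pharmacy`) plus answer-key rows (`truth_member`,
#'   `truth_lines`, `truth_costs`).
#' @export
plant_member <- function(spec, config = generator_config(),
                         codesets = pah_codesets(),
                         inflation = inflation_table()) {
  member <- tibble::tibble(
    member_id = spec$member_id, birth_year = spec$birth_year, sex = spec$sex,
    insurance = spec$insurance, region = spec$region, qci = spec$qci
  )
  if (!is.na(spec$fail_step)) {
    return(plant_fail_member(spec, member, config, codesets, inflation))
  }
  idx <- spec$index_day
  F_days <- spec$followup_days
  enrollment <- tibble::tibble(
    member_id = spec$member_id, start_day = idx - spec$pre_days,
    end_day = idx + F_days, benefit = "medical_and_pharmacy"
  )

  fills <- emit_line_fills(spec$lines, config)
  rx <- tibble::tibble(
    day = idx + fills$rx$day, drug_code = fills$rx$drug_code,
    days_supply = fills$rx$days_supply, pah = TRUE
  )
  rx$drug_class <- unname(drug_class_lookup(codesets)[rx$drug_code])

  rates <- config$hcru_rates
  mb <- days_to_months(183)
  mp <- days_to_months(F_days)
  ev <- function(setting, count, days, pah_frac) {
    if (count == 0) return(NULL)
    tibble::tibble(day = days, setting = setting,
                   pah_dx = stats::runif(count) < pah_frac,
                   proc = NA_character_, hcpcs = NA_character_)
  }
  n_of <- function(rate, months) stats::rpois(1, rate * months)
  base_days <- function(k) idx - sample.int(183, k, replace = TRUE)
  post_days <- function(k) idx + sample(0:(F_days - 1), k, replace = TRUE)
  events <- dplyr::bind_rows(
    ev("inpatient", k1 <- n_of(rates$baseline[["inpatient"]], mb),
       base_days(k1), rates$pah_dx_frac_baseline[["inpatient"]]),
    ev("er", k2 <- n_of(rates$baseline[["er"]], mb), base_days(k2),
       rates$pah_dx_frac_baseline[["er"]]),
    ev("outpatient", k3 <- n_of(rates$baseline[["outpatient"]], mb),
       base_days(k3), rates$pah_dx_frac_baseline[["outpatient"]]),
    ev("inpatient", k4 <- n_of(rates$postindex[["inpatient"]], mp),
       post_days(k4), rates$pah_dx_frac_postindex[["inpatient"]]),
    ev("er", k5 <- n_of(rates$postindex[["er"]], mp), post_days(k5),
       rates$pah_dx_frac_postindex[["er"]]),
    ev("outpatient", k6 <- n_of(rates$postindex[["outpatient"]], mp),
       post_days(k6), rates$pah_dx_frac_postindex[["outpatient"]])
  )
  ## planted baseline evidence: two outpatient PAH-diagnosis claims on
  ## distinct days and one RHC claim at or before index
  ev_days <- sample(5:180, 2)
  evidence <- tibble::tibble(
    day = c(idx - ev_days, idx - pick1(0:180)),
    setting = "outpatient",
    pah_dx = c(TRUE, TRUE, stats::runif(1) < 0.8),
    proc = c(NA_character_, NA_character_, pick1(codesets$rhc_proc_codes)),
    hcpcs = NA_character_
  )
  admin <- if (nrow(fills$admin) > 0) {
    tibble::tibble(day = idx + fills$admin$day, setting = "outpatient",
                   pah_dx = stats::runif(nrow(fills$admin)) < 0.8,
                   proc = NA_character_, hcpcs = fills$admin$hcpcs)
  } else {
    NULL
  }
  transplant <- if (stats::runif(1) < rates$transplant_prob) {
    tibble::tibble(day = idx + pick1(0:(F_days - 1)), setting = "inpatient",
                   pah_dx = stats::runif(1) < 0.5,
                   proc = pick1(codesets$transplant_proc_codes),
                   hcpcs = NA_character_)
  } else {
    NULL
  }
  md <- dplyr::bind_rows(events, evidence, admin, transplant)
  md$dx_codes <- vapply(md$pah_dx, function(p) rand_dx(codesets, p),
                        character(1))
  md$pah <- md$pah_dx | !is.na(md$hcpcs)

  ## non-PAH background pharmacy fills
  nb <- stats::rpois(1, rates$baseline[["pharmacy_other"]] * mb)
  np <- stats::rpois(1, rates$postindex[["pharmacy_other"]] * mp)
  rx_other <- tibble::tibble(
    day = c(base_days(nb), post_days(np)),
    drug_code = sprintf("RX_OTHER_%02d", sample.int(20, nb + np, replace = TRUE)),
    days_supply = sample(c(30L, 90L), nb + np, replace = TRUE,
                         prob = c(0.8, 0.2)),
    pah = FALSE, drug_class = "other"
  )
  rx <- dplyr::bind_rows(rx, rx_other)

  cost <- assign_member_costs(md, rx, idx, F_days, config, inflation)
  md <- cost$md
  rx <- cost$rx

  medical <- tibble::tibble(
    member_id = spec$member_id, service_day = md$day, setting = md$setting,
    dx_codes = md$dx_codes,
    proc_codes = ifelse(is.na(md$proc), "", md$proc),
    hcpcs_drug_code = md$hcpcs,
    cost_plan = md$cost_plan, cost_member = md$cost_member,
    cost_cob = md$cost_cob
  )
  pharmacy <- tibble::tibble(
    member_id = spec$member_id, fill_day = rx$day, drug_code = rx$drug_code,
    days_supply = rx$days_supply,
    cost_plan = rx$cost_plan, cost_member = rx$cost_member,
    cost_cob = rx$cost_cob
  )
  truth_lines <- tibble::tibble(
    member_id = spec$member_id,
    line_number = spec$lines$line_number,
    start_day = idx + spec$lines$start,
    end_day = idx + spec$lines$end,
    end_reason = spec$lines$end_reason,
    classes = spec$lines$classes,
    regimen = spec$lines$regimen
  )
  truth_member <- tibble::tibble(
    member_id = spec$member_id, fate = "cohort", fail_step = NA_integer_,
    index_day = idx, censor_day = idx + F_days, followup_days = F_days,
    n_lines = nrow(spec$lines), unambiguous = TRUE
  )
  truth_costs <- dplyr::mutate(cost$truth, member_id = spec$member_id,
                               .before = 1)
  list(member = member, enrollment = enrollment, medical = medical,
       pharmacy = pharmacy, truth_member = truth_member,
       truth_lines = truth_lines, truth_costs = truth_costs)
}

## Members planted to exit selection at a given step: minimal claims that
## pass every earlier step and fail exactly the planted one.
plant_fail_member <- function(spec, member, config, codesets, inflation) {
  step <- spec$fail_step
  idx <- spec$index_day
  mk_md <- function(day, setting = "outpatient", pah = FALSE,
                    proc = NA_character_) {
    tibble::tibble(day = day, setting = setting, pah_dx = pah, proc = proc,
                   hcpcs = NA_character_)
  }
  if (step == 2L) {
    enrollment <- tibble::tibble(member_id = spec$member_id,
                                 start_day = -300L, end_day = 800L,
                                 benefit = "medical_and_pharmacy")
    md <- dplyr::bind_rows(mk_md(pick1(0:700)), mk_md(pick1(0:700)))
    rx <- tibble::tibble(day = pick1(0:700),
                         drug_code = "RX_OTHER_01", days_supply = 30L,
                         pah = FALSE, drug_class = "other")
  } else {
    enr <- switch(as.character(step),
                  `7` = c(idx - 100L, idx + 200L),
                  `8` = c(idx - 400L, idx + 15L),
                  `6` = c(idx - 900L, idx + 200L),
                  c(idx - 400L, idx + 200L))
    enrollment <- tibble::tibble(member_id = spec$member_id,
                                 start_day = enr[1], end_day = enr[2],
                                 benefit = "medical_and_pharmacy")
    dx_md <- if (step == 4L) {
      ## insufficient evidence: two qualifying claims on the same day
      dplyr::bind_rows(mk_md(idx - 40L, pah = TRUE), mk_md(idx - 40L, pah = TRUE))
    } else {
      dplyr::bind_rows(mk_md(idx - 30L, pah = TRUE), mk_md(idx - 60L, pah = TRUE))
    }
    rhc_md <- if (step == 5L) NULL else
      mk_md(idx - 50L, proc = pick1(codesets$rhc_proc_codes))
    md <- dplyr::bind_rows(dx_md, rhc_md, mk_md(idx - 90L))
    rx <- tibble::tibble(day = idx, drug_code = "RX_SILDENAFIL",
                         days_supply = 30L, pah = TRUE, drug_class = "PDE5I")
    if (step == 6L) {
      ## prior PAH fill inside enrollment but before the identification
      ## window, so it cannot itself become the index
      rx <- dplyr::bind_rows(
        tibble::tibble(day = -20L, drug_code = "RX_SILDENAFIL",
                       days_supply = 30L, pah = TRUE, drug_class = "PDE5I"),
        rx)
    }
  }
  md$dx_codes <- vapply(md$pah_dx, function(p) rand_dx(codesets, p),
                        character(1))
  md$pah <- md$pah_dx
  md$cost2020 <- 150 * stats::rlnorm(nrow(md), -0.125, 0.5)
  rx$cost2020 <- 60 * stats::rlnorm(nrow(rx), -0.125, 0.5)
  md <- split_cost(md, inflation)
  rx <- split_cost(rx, inflation)
  medical <- tibble::tibble(
    member_id = spec$member_id, service_day = md$day, setting = md$setting,
    dx_codes = md$dx_codes,
    proc_codes = ifelse(is.na(md$proc), "", md$proc),
    hcpcs_drug_code = md$hcpcs,
    cost_plan = md$cost_plan, cost_member = md$cost_member,
    cost_cob = md$cost_cob
  )
  pharmacy <- tibble::tibble(
    member_id = spec$member_id, fill_day = rx$day, drug_code = rx$drug_code,
    days_supply = rx$days_supply,
    cost_plan = rx$cost_plan, cost_member = rx$cost_member,
    cost_cob = rx$cost_cob
  )
  truth_member <- tibble::tibble(
    member_id = spec$member_id, fate = paste0("fail_step_", step),
    fail_step = step,
    index_day = if (step == 2L) NA_integer_ else idx,
    censor_day = NA_integer_, followup_days = NA_integer_,
    n_lines = 0L, unambiguous = NA
  )
  list(member = member, enrollment = enrollment, medical = medical,
       pharmacy = pharmacy, truth_member = truth_member,
       truth_lines = NULL, truth_costs = NULL)
}
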
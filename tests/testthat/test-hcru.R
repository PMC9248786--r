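six_month_member <- function(claims_md = NULL, claims_rx = NULL) {
  md <- if (is.null(claims_md)) med_row("m1", -300)[0, ] else claims_md
  rx <- if (is.null(claims_rx)) rx_row("m1", -300)[0, ] else claims_rx
  claims_dataset(blank_member("m1"), enr_row("m1", -200, 400), md, rx,
                 validate = TRUE)
}

one_period <- function(start = 0L, end = 183L, label = "baseline") {
  tibble::tibble(member_id = "m1", period = label, start_day = start,
                 end_day = end,
                 patient_months = days_to_months(end - start))
}

test_that("pooled PPPM: one hospitalization in six months is about 0.17", {
  ds <- six_month_member(med_row("m1", 50, setting = "inpatient",
                                 dx = "I27.0"))
  out <- summarize_period(ds, one_period(), scope = "all_cause")
  inp <- out[out$category == "inpatient", ]
  expect_identical(inp$n_with_ge1, 1L)
  expect_equal(inp$pct_with_ge1, 100)
  expect_equal(inp$pppm, 1 / days_to_months(183))
  expect_equal(round(inp$pppm, 2), 0.17)
})

test_that("a period without claims reports zero everywhere", {
  ds <- six_month_member(med_row("m1", 300, dx = "I27.0"))
  out <- summarize_period(ds, one_period())
  expect_true(all(out$n_with_ge1 == 0))
  expect_true(all(out$pppm == 0))
})

test_that("HCRU counts match a brute-force tally on random populations", {
  pop <- generate_population(generator_config(n_members = 60, seed = 515))
  ds <- pop$dataset
  cohort <- select_cohort(ds)
  periods <- make_periods(cohort)
  out <- summarize_period(ds, periods, scope = "all_cause")
  md <- ds$medical_claims
  for (per in c("baseline", "postindex")) {
    pp <- periods[periods$period == per, ]
    for (cat in c("inpatient", "er", "outpatient")) {
      hand <- sum(vapply(seq_len(nrow(pp)), function(i) {
        sum(md$member_id == pp$member_id[i] & md$setting == cat &
              md$service_day >= pp$start_day[i] &
              md$service_day < pp$end_day[i])
      }, numeric(1)))
      got <- out[out$period == per & out$category == cat, ]
      expect_equal(got$n_events, hand)
      expect_equal(got$pppm, hand / sum(pp$patient_months))
    }
  }
})

test_that("claim costs adjust by year multiplier and pool per month", {
  ds <- six_month_member(med_row("m1", 50, cost = 600))
  # identity inflation: $600 over six 30.4375-day months
  out <- summarize_costs(ds, one_period(), inflation = identity_inflation(),
                         scope = "all_cause")
  expect_equal(out$total_pppm, 600 / days_to_months(183))
  # day 50 falls in 2015; a 1.05 multiplier scales the claim
  infl <- inflation_table(2015:2020, c(1.05, 1, 1, 1, 1, 1))
  out2 <- summarize_costs(ds, one_period(), inflation = infl,
                          scope = "all_cause")
  expect_equal(out2$total_pppm, 630 / days_to_months(183))
  expect_error(
    summarize_costs(ds, one_period(), inflation = inflation_table(2016:2020,
                                                                  rep(1, 5))),
    "2015")
})

test_that("PAH-related flags follow diagnosis, HCPCS, and drug-code rules", {
  cs <- pah_codesets()
  md <- dplyr::bind_rows(
    med_row("m1", 10, dx = "J44.9;I27.20"),
    med_row("m1", 11, dx = "J44.9"),
    med_row("m1", 12, hcpcs = "J_TREPROSTINIL_PAR"),
    med_row("m1", 13, hcpcs = "J_UNKNOWN")
  )
  expect_identical(flag_pah_related(md, cs), c(TRUE, FALSE, TRUE, FALSE))
  rx <- dplyr::bind_rows(rx_row("m1", 10), rx_row("m1", 11, drug = "RX_OTHER_01"))
  expect_identical(flag_pah_related(rx, cs), c(TRUE, FALSE))
})

test_that("cost and scope identities hold on a generated population", {
  pop <- generate_population(generator_config(n_members = 80, seed = 616))
  ds <- pop$dataset
  cohort <- select_cohort(ds)
  lines <- segment_cohort_lines(cohort, ds)
  periods <- make_periods(cohort, lines)
  hcru <- summarize_period(ds, periods)
  costs <- summarize_costs(ds, periods)

  # decomposition: total = medical + pharmacy (NA pharmacy = medical only)
  expect_equal(costs$total_pppm,
               costs$medical_pppm + dplyr::coalesce(costs$pharmacy_pppm, 0))
  # denominator identity: PPPM x pooled months = raw sums
  expect_equal(costs$medical_pppm * costs$patient_months, costs$medical_cost)
  ok <- !is.na(costs$pharmacy_cost)
  expect_equal((costs$pharmacy_pppm * costs$patient_months)[ok],
               costs$pharmacy_cost[ok])
  # scope monotonicity for costs and utilization
  wide <- tidyr::pivot_wider(
    costs[, c("period", "scope", "medical_pppm")],
    names_from = "scope", values_from = "medical_pppm")
  expect_true(all(wide$pah_related <= wide$all_cause + 1e-9))
  hw <- tidyr::pivot_wider(
    hcru[hcru$category %in% c("inpatient", "er", "outpatient"),
         c("period", "scope", "category", "n_events")],
    names_from = "scope", values_from = "n_events")
  expect_true(all(hw$pah_related <= hw$all_cause))
})

test_that("post-index claims partition across line periods and gaps", {
  pop <- generate_population(generator_config(n_members = 80, seed = 717))
  ds <- pop$dataset
  cohort <- select_cohort(ds)
  lines <- segment_cohort_lines(cohort, ds)
  periods <- make_periods(cohort, lines)
  line_p <- periods[startsWith(periods$period, "line_"), ]
  # line periods never overlap within a member
  for (id in unique(line_p$member_id)) {
    lp <- line_p[line_p$member_id == id, ]
    lp <- lp[order(lp$start_day), ]
    if (nrow(lp) > 1) {
      expect_true(all(lp$start_day[-1] >= lp$end_day[-nrow(lp)]))
    }
  }
  # every line period lies inside the member's post-index period
  post <- periods[periods$period == "postindex", ]
  j <- match(line_p$member_id, post$member_id)
  expect_true(all(line_p$start_day >= post$start_day[j]))
  expect_true(all(line_p$end_day <= post$end_day[j]))
  # pooled post-index events >= sum of line-period events (gap claims)
  hcru <- summarize_period(ds, periods, scope = "all_cause")
  for (cat in c("inpatient", "outpatient", "pharmacy_fills")) {
    post_n <- hcru$n_events[hcru$period == "postindex" & hcru$category == cat]
    line_n <- sum(hcru$n_events[startsWith(hcru$period, "line_") &
                                  hcru$category == cat])
    expect_gte(post_n, line_n)
  }
})

test_that("per-line summaries cover exactly the line periods", {
  pop <- generate_population(generator_config(n_members = 60, seed = 919))
  cohort <- select_cohort(pop$dataset)
  lines <- segment_cohort_lines(cohort, pop$dataset)
  out <- per_line_summaries(cohort, lines, pop$dataset)
  got_periods <- sort(unique(out$hcru$period))
  want <- paste0("line_", sort(unique(pmin(lines$line_number, 4))))
  expect_setequal(got_periods, want)
  # denominators equal line initiator counts
  n1 <- out$costs$n_members[out$costs$period == "line_1" &
                              out$costs$scope == "all_cause"]
  expect_identical(n1, nrow(cohort))
})

test_that("baseline PAH pharmacy cost is structurally missing, not zero", {
  pop <- generate_population(generator_config(n_members = 40, seed = 818))
  cohort <- select_cohort(pop$dataset)
  costs <- summarize_costs(pop$dataset, make_periods(cohort))
  cell <- costs[costs$period == "baseline" & costs$scope == "pah_related", ]
  expect_true(is.na(cell$pharmacy_pppm))
  expect_equal(cell$total_pppm, cell$medical_pppm)
})
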
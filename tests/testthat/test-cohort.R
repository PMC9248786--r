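test_that("each selection step removes exactly the member violating it", {
  ds <- attrition_fixture()
  cohort <- select_cohort(ds)
  rep <- attrition_report(cohort)
  expect_identical(rep$n_remaining, c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L))
  expect_identical(cohort$member_id, "ok")
  expect_identical(cohort$index_day, 400L)
  expect_equal(rep$pct_of_previous[-1],
               100 * rep$n_remaining[-1] / rep$n_remaining[-8])
})

test_that("an empty dataset yields an all-zero attrition report", {
  ds <- claims_dataset(blank_member("z")[0, ], enr_row("z", 0, 1)[0, ],
                       med_row("z", 0)[0, ], rx_row("z", 0)[0, ])
  rep <- attrition_report(select_cohort(ds))
  expect_identical(rep$n_remaining, rep(0L, 8))
})

test_that("find_index matches a brute-force scan on random fill sets", {
  cfg <- selection_config()
  set.seed(101)
  for (rep in 1:100) {
    n <- sample.int(8, 1)
    med <- tibble::tibble(day = sample(-200:2100, n), drug_class = "PDE5I",
                          drug_code = "RX_SILDENAFIL", supply_days = 30L,
                          source = "pharmacy")
    in_win <- med$day[med$day >= cfg$id_window_start &
                        med$day <= cfg$id_window_end]
    want <- if (length(in_win)) min(in_win) else NA_integer_
    expect_identical(find_index(med, cfg), want)
  }
})

test_that("diagnosis criterion enforces settings and distinct dates", {
  cs <- pah_codesets()
  # two qualifying outpatient claims on the same day do not qualify
  same_day <- dplyr::bind_rows(med_row("a", 90, dx = "I27.0"),
                               med_row("a", 90, dx = "I27.9"))
  expect_false(check_dx_criterion(same_day, 100, cs))
  # one inpatient claim with the code in a non-primary position qualifies
  inp <- med_row("a", 90, setting = "inpatient", dx = "J44.9;E11.9;I27.0")
  expect_true(check_dx_criterion(inp, 100, cs))
  # a claim on the index day itself counts; one 184+ days before does not
  edge <- dplyr::bind_rows(med_row("a", 100, dx = "I27.0"),
                           med_row("a", 100 - 183, dx = "I27.0"))
  expect_true(check_dx_criterion(edge, 100, cs))
  late <- dplyr::bind_rows(med_row("a", 100 - 184, dx = "I27.0"),
                           med_row("a", 100 - 190, dx = "I27.0"))
  expect_false(check_dx_criterion(late, 100, cs))
})

test_that("diagnosis criterion matches a day-set enumeration oracle", {
  cs <- pah_codesets()
  cfg <- selection_config()
  set.seed(202)
  for (rep in 1:100) {
    n <- sample.int(6, 1)
    md <- tibble::tibble(
      member_id = "a",
      service_day = sample(-100:150, n, replace = TRUE),
      setting = sample(c("inpatient", "outpatient", "er"), n, replace = TRUE),
      dx_codes = sample(c("I27.0", "416.9", "J44.9"), n, replace = TRUE),
      proc_codes = "", hcpcs_drug_code = NA_character_,
      cost_plan = 0, cost_member = 0, cost_cob = 0
    )
    idx <- 100L
    win <- md[md$service_day >= idx - 183L & md$service_day <= idx, ]
    qual <- win[win$dx_codes %in% cs$pah_dx_codes, ]
    want <- any(qual$setting == "inpatient") ||
      length(unique(qual$service_day[qual$setting != "inpatient"])) >= 2
    expect_identical(check_dx_criterion(md, idx, cs, cfg), want)
  }
})

test_that("RHC criterion covers the index day and not earlier than baseline", {
  cs <- pah_codesets()
  on_index <- med_row("a", 100, proc = "93451")
  expect_true(check_rhc(on_index, 100, cs))
  seven_months <- med_row("a", 100 - 213, proc = "93451")
  expect_false(check_rhc(seven_months, 100, cs))
})

test_that("treatment-naive scan stops at the day before index", {
  med <- tibble::tibble(day = c(-250L, 90L, 100L), drug_class = "PDE5I",
                        drug_code = "RX_SILDENAFIL", supply_days = 30L,
                        source = "pharmacy")
  expect_false(check_treatment_naive(med, -300L, 100L))
  expect_true(check_treatment_naive(med[med$day >= 100, ], -300L, 100L))
  # a fill before the continuous-enrollment start does not count
  expect_true(check_treatment_naive(med[med$day != 90, ], -200L, 100L))
})

test_that("attrition counts are invariant to input row order", {
  ds <- attrition_fixture()
  set.seed(5)
  shuf <- claims_dataset(
    ds$members[sample.int(nrow(ds$members)), ],
    ds$enrollment[sample.int(nrow(ds$enrollment)), ],
    ds$medical_claims[sample.int(nrow(ds$medical_claims)), ],
    ds$pharmacy_claims[sample.int(nrow(ds$pharmacy_claims)), ]
  )
  expect_identical(attrition_report(select_cohort(shuf))$n_remaining,
                   attrition_report(select_cohort(ds))$n_remaining)
})

test_that("every survivor independently satisfies all eight predicates", {
  pop <- generate_population(generator_config(n_members = 120, seed = 404))
  ds <- pop$dataset
  cs <- pah_codesets()
  cfg <- selection_config()
  cohort <- select_cohort(ds, cs, cfg)
  expect_gt(nrow(cohort), 50)
  med <- pah_med_claims(ds, cs)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$member_id[i]
    mc <- med[med$member_id == id, ]
    mdc <- ds$medical_claims[ds$medical_claims$member_id == id, ]
    idx <- find_index(mc, cfg)
    expect_identical(idx, cohort$index_day[i])
    expect_gte(day_to_year(idx) -
                 ds$members$birth_year[ds$members$member_id == id], 18)
    expect_true(check_dx_criterion(mdc, idx, cs, cfg))
    expect_true(check_rhc(mdc, idx, cs, cfg))
    expect_true(check_treatment_naive(mc, cohort$enroll_start[i], idx))
    expect_lte(cohort$enroll_start[i], idx - cfg$baseline_days)
    expect_gte(cohort$enroll_end[i], idx + cfg$min_postindex_days)
  }
})

test_that("monotonicity: counts never increase across steps", {
  pop <- generate_population(generator_config(n_members = 150, seed = 505))
  rep <- attrition_report(select_cohort(pop$dataset))
  expect_true(all(diff(rep$n_remaining) <= 0))
})
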
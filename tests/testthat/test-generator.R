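test_that("largest-remainder allocation is exact and sums to n", {
  probs <- c(a = 0.117, b = 0.517, c = 0.085, d = 0.281)
  for (n in c(1L, 7L, 843L, 2000L)) {
    counts <- alloc_counts(n, probs)
    expect_identical(sum(counts), n)
    expect_true(all(abs(counts - n * probs / sum(probs)) <= 1))
  }
})

test_that("identical config and seed give byte-identical file sets", {
  cfg <- generator_config(n_members = 40, seed = 88)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_claims_dataset(generate_population(cfg)$dataset, d1)
  write_claims_dataset(generate_population(cfg)$dataset, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("a forced single-member trajectory flows through the pipeline", {
  spec <- list(
    member_id = "solo", fail_step = NA_integer_, index_day = 200L,
    followup_days = 120L, pre_days = 250L, birth_year = 1950L, sex = "F",
    insurance = "commercial", region = "west", qci = 2,
    lines = tibble::tibble(line_number = 1L, start = 0L, end = 120L,
                           end_reason = "censored", classes = "PDE5I",
                           regimen = "MONO_PDE5I")
  )
  set.seed(1)
  parts <- plant_member(spec, generator_config())
  ds <- claims_dataset(parts$member, parts$enrollment, parts$medical,
                       parts$pharmacy)
  cohort <- select_cohort(ds)
  expect_identical(nrow(cohort), 1L)
  expect_identical(cohort$index_day, 200L)
  expect_identical(cohort$censor_day, 320L)
  lines <- segment_cohort_lines(cohort, ds)
  expect_identical(nrow(lines), 1L)
  expect_identical(lines$regimen, "MONO_PDE5I")
  expect_identical(lines$end_reason, "censored")
})

test_that("planted truth is recovered exactly on a generated population", {
  pop <- generate_population(generator_config(n_members = 200, seed = 909))
  ds <- pop$dataset
  truth <- pop$truth

  cohort <- select_cohort(ds)
  tm <- truth$members
  expect_setequal(cohort$member_id, tm$member_id[tm$fate == "cohort"])
  got <- cohort[match(tm$member_id[tm$fate == "cohort"], cohort$member_id), ]
  expect_identical(got$index_day, tm$index_day[tm$fate == "cohort"])
  expect_identical(got$censor_day, tm$censor_day[tm$fate == "cohort"])

  lines <- segment_cohort_lines(cohort, ds)
  key <- c("member_id", "line_number")
  tl <- dplyr::arrange(truth$lines, .data$member_id, .data$line_number)
  el <- dplyr::arrange(tibble::as_tibble(lines), .data$member_id,
                       .data$line_number)
  expect_identical(nrow(el), nrow(tl))
  expect_identical(el$start_day, tl$start_day)
  expect_identical(el$end_day, tl$end_day)
  expect_identical(el$end_reason, tl$end_reason)
  expect_identical(el$classes, tl$classes)
  expect_identical(el$regimen, tl$regimen)
})

test_that("members planted to fail step k fail exactly step k", {
  pop <- generate_population(generator_config(n_members = 250, seed = 117))
  ds <- pop$dataset
  cs <- pah_codesets()
  cfg <- selection_config()
  med <- pah_med_claims(ds, cs)
  enr <- normalize_enrollment(ds$enrollment)
  truth <- pop$truth$members
  fails <- truth[!is.na(truth$fail_step), ]
  expect_gt(nrow(fails), 20)
  expect_setequal(unique(fails$fail_step), 2:8)
  first_fail <- function(id) {
    mc <- med[med$member_id == id, ]
    mdc <- ds$medical_claims[ds$medical_claims$member_id == id, ]
    idx <- find_index(mc, cfg)
    if (is.na(idx)) return(2L)
    by <- ds$members$birth_year[ds$members$member_id == id]
    if (day_to_year(idx) - by < cfg$adult_age) return(3L)
    if (!check_dx_criterion(mdc, idx, cs, cfg)) return(4L)
    if (!check_rhc(mdc, idx, cs, cfg)) return(5L)
    sp <- enr[enr$member_id == id & enr$start_day <= idx & idx < enr$end_day, ]
    es <- if (nrow(sp)) sp$start_day[1] else -Inf
    if (!check_treatment_naive(mc, es, idx)) return(6L)
    if (nrow(sp) == 0 || sp$start_day[1] > idx - cfg$baseline_days) return(7L)
    if (sp$end_day[1] < idx + cfg$min_postindex_days) return(8L)
    0L
  }
  got <- vapply(fails$member_id, first_fail, integer(1))
  expect_identical(unname(got), fails$fail_step)
  # and the attrition report loses exactly the planted counts
  rep <- attrition_report(select_cohort(ds, cs, cfg))
  planted_n <- nrow(truth) - cumsum(table(factor(fails$fail_step, levels = 2:8)))
  expect_identical(rep$n_remaining[-1], unname(as.integer(planted_n)))
})

test_that("planted period costs are recovered to floating tolerance", {
  pop <- generate_population(generator_config(n_members = 120, seed = 212))
  cohort <- select_cohort(pop$dataset)
  periods <- make_periods(cohort)
  costs <- summarize_costs(pop$dataset, periods)
  tc <- pop$truth$costs
  for (per in c("baseline", "postindex")) {
    planted <- tc[tc$period == per, ]
    all_cause <- costs[costs$period == per & costs$scope == "all_cause", ]
    expect_equal(all_cause$medical_cost, sum(planted$medical_cost),
                 tolerance = 1e-9)
    expect_equal(all_cause$pharmacy_cost, sum(planted$pharmacy_cost),
                 tolerance = 1e-9)
    pah <- costs[costs$period == per & costs$scope == "pah_related", ]
    expect_equal(pah$medical_cost, sum(planted$medical_pah_cost),
                 tolerance = 1e-9)
    if (per == "postindex") {
      expect_equal(pah$pharmacy_cost, sum(planted$pharmacy_pah_cost),
                   tolerance = 1e-9)
    } else {
      expect_true(is.na(pah$pharmacy_cost))
    }
  }
})

test_that("degenerate cost settings are honoured", {
  cfg <- generator_config(n_members = 30, seed = 33,
                          attrition_pass = c(step2 = 1, step3 = 1, step4 = 1,
                                             step5 = 1, step6 = 1, step7 = 1,
                                             step8 = 1))
  # all-zero cost targets -> all planted claim costs zero
  cfg$cost_model$baseline[] <- 0
  cfg$cost_model$postindex[] <- 0
  pop <- generate_population(cfg)
  cm <- pop$dataset$medical_claims
  pc <- pop$dataset$pharmacy_claims
  expect_true(all(cm$cost_plan + cm$cost_member + cm$cost_cob == 0))
  expect_true(all(pc$cost_plan + pc$cost_member + pc$cost_cob == 0))

  # zero-variance draws -> pooled PPPM equals the configured target
  # almost exactly (cent rounding aside)
  cfg2 <- generator_config(n_members = 60, seed = 34)
  cfg2$cost_model$member_sigma <- 0
  cfg2$cost_model$claim_sigma <- 0
  pop2 <- generate_population(cfg2)
  cohort <- select_cohort(pop2$dataset)
  costs <- summarize_costs(pop2$dataset, make_periods(cohort))
  base_total <- costs$total_pppm[costs$period == "baseline" &
                                   costs$scope == "all_cause"]
  expect_equal(base_total, 14208 + 909, tolerance = 1e-4)
})

test_that("config validation rejects malformed distributions", {
  expect_error(generator_config(n_members = 0), "n_members")
  expect_error(generator_config(index_year_mix = c(`2016` = 0.5, `2017` = 0.4)),
               "sum to 1")
  expect_error(
    generator_config(line_continuation = list(c(remain = 0.5, interrupt = 0.2,
                                                modify = 0.2))),
    "sum to 1")
  expect_error(generator_config(restart_prob = c(1.2, 0.3, 0.3, 0.3)),
               "\\[0, 1\\]")
})
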
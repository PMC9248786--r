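med_claims <- function(days, classes, supplies = 30L,
                       drugs = NULL) {
  n <- length(days)
  tibble::tibble(
    day = as.integer(days),
    drug_class = rep_len(classes, n),
    drug_code = if (is.null(drugs)) paste0("RX_", rep_len(classes, n)) else drugs,
    supply_days = as.integer(rep_len(supplies, n)),
    source = "pharmacy"
  )
}

test_that("coverage intervals union without stacking", {
  abut <- build_coverage(dplyr::mutate(med_claims(c(0, 30), "PDE5I"),
                                       member_id = "m"))
  expect_identical(nrow(abut), 1L)
  expect_identical(abut$start_day, 0L)
  expect_identical(abut$end_day, 60L)
  overlap <- build_coverage(dplyr::mutate(med_claims(c(0, 20), "PDE5I"),
                                          member_id = "m"))
  expect_identical(overlap$end_day, 50L)  # overlap merged, not stacked
})

test_that("coverage matches a per-day set-union oracle on random fills", {
  set.seed(303)
  for (rep in 1:50) {
    h <- random_history()
    h$member_id <- "m"
    cov <- build_coverage(h)
    for (cl in unique(h$drug_class)) {
      want <- sort(unique(unlist(Map(
        function(d, s) seq.int(d, d + s - 1L),
        h$day[h$drug_class == cl], h$supply_days[h$drug_class == cl]))))
      got <- unlist(Map(seq.int, cov$start_day[cov$drug_class == cl],
                        cov$end_day[cov$drug_class == cl] - 1L))
      expect_identical(sort(got), want)
    }
  }
})

test_that("first-line window boundary is inclusive by default, exclusive on request", {
  h <- med_claims(c(0, 30), c("ERA", "PDE5I"))
  expect_setequal(assign_first_line(h, 0L), c("ERA", "PDE5I"))
  h31 <- med_claims(c(0, 31), c("ERA", "PDE5I"))
  expect_identical(assign_first_line(h31, 0L), "ERA")
  excl <- lot_config(window_inclusive = FALSE)
  expect_identical(assign_first_line(h, 0L, excl), "ERA")
})

test_that("line ends are detected with the documented reasons", {
  # sequential combination: new class claim during continuous coverage
  h <- med_claims(c(0, 30, 60, 90, 120, 150, 180), "PDE5I")
  h$drug_class[5] <- "ERA"; h$drug_code[5] <- "RX_ERA"
  res <- detect_line_end(h, 0L, 400L)
  expect_identical(res$end_reason, "modification")
  expect_identical(res$end_day, 120L)
  expect_identical(res$next_start, 120L)

  # gap beyond the grace period: interruption at run-out, restart later
  h2 <- med_claims(c(0, 30, 250), "PDE5I")
  res2 <- detect_line_end(h2, 0L, 400L)
  expect_identical(res2$end_reason, "interruption")
  expect_identical(res2$end_day, 60L)
  expect_identical(res2$next_start, 250L)

  # a gap of exactly gap_days is tolerated (interruption needs > 60)
  h3 <- med_claims(c(0, 91), "PDE5I")  # run-out 30, refill 61 days later
  res3 <- detect_line_end(h3, 0L, 400L)
  expect_identical(res3$end_reason, "interruption")
  expect_identical(res3$next_start, 91L)
  h4 <- med_claims(c(0, 90), "PDE5I")  # refill exactly 60 days after run-out
  res4 <- detect_line_end(h4, 0L, 150L)
  expect_identical(res4$end_reason, "censored")

  # terminal gap: censoring within the grace period, interruption beyond
  one <- med_claims(0, "PDE5I")
  expect_identical(detect_line_end(one, 0L, 85L)$end_reason, "censored")
  expect_identical(detect_line_end(one, 0L, 91L)$end_reason, "interruption")
  expect_identical(detect_line_end(one, 0L, 91L)$end_day, 30L)
})

test_that("regimen classification matches hand enumeration on all 63 subsets", {
  classes <- pah_drug_classes()
  for (mask in 1:63) {
    set <- classes[as.logical(bitwAnd(mask, 2^(0:5)))]
    got <- classify_regimen(set)
    if (length(set) == 1) {
      expect_identical(got$arm, "monotherapy")
      expect_identical(got$detail, set)
      expect_identical(got$label, paste0("MONO_", set))
    } else if (setequal(set, c("ERA", "PDE5I"))) {
      expect_identical(got$label, "COMBO_ERA_PDE5I")
      expect_identical(got$arm, "combination")
    } else {
      expect_identical(got$label, "COMBO_OTHER")
      expect_identical(got$arm, "combination")
    }
  }
  expect_error(classify_regimen(character(0)), "empty")
  expect_error(classify_regimen("NOT_A_CLASS"), "unknown")
})

test_that("a planted three-line trajectory is segmented exactly", {
  # line 1: PDE5I mono, modification at day 90 adding ERA while PDE5I
  # coverage continues; line 2: ERA+PDE5I, interruption at run-out 210;
  # line 3: restart SGC at day 300, censored at day 380
  h <- dplyr::bind_rows(
    med_claims(c(0, 30, 60), "PDE5I"),
    med_claims(c(90, 120, 150, 180), c("ERA", "PDE5I", "ERA", "PDE5I")),
    med_claims(300, "SGC")
  )
  lines <- segment_lines(h, 0L, 380L)
  expect_identical(nrow(lines), 3L)
  expect_identical(lines$end_reason,
                   c("modification", "interruption", "censored"))
  expect_identical(lines$start_day, c(0L, 90L, 300L))
  expect_identical(lines$end_day, c(90L, 210L, 380L))
  expect_identical(lines$classes, c("PDE5I", "ERA;PDE5I", "SGC"))
  expect_identical(lines$regimen,
                   c("MONO_PDE5I", "COMBO_ERA_PDE5I", "MONO_SGC"))
  expect_equal(lines$months_in_line, c(90, 120, 80) / 30.4375)
})

test_that("a single fill censored shortly after start yields one censored line", {
  lines <- segment_lines(med_claims(0, "SGC"), 0L, 40L)
  expect_identical(nrow(lines), 1L)
  expect_identical(lines$end_reason, "censored")
  expect_identical(lines$end_day, 40L)
})

test_that("restart rule: inserting a long gap adds exactly one line", {
  set.seed(99)
  for (rep in 1:20) {
    # continuous mono trajectory of contiguous fills
    n <- sample(3:6, 1)
    h <- med_claims(seq(0, by = 30, length.out = n), "ERA")
    base <- segment_lines(h, 0L, max(h$day) + 100L)
    # push the last fill far beyond the grace period
    h2 <- h
    shift <- 100L + sample(0:50, 1)
    h2$day[n] <- h2$day[n] + shift
    split <- segment_lines(h2, 0L, max(h2$day) + 100L)
    expect_identical(nrow(split), nrow(base) + 1L)
    expect_identical(split$end_reason[nrow(base)], "interruption")
  }
})

test_that("widening the formation window never lowers the combination share", {
  set.seed(111)
  shares <- sapply(c(15L, 30L, 60L, 90L), function(w) {
    combo <- 0L
    for (rep in 1:60) {
      set.seed(1000 + rep)
      h <- random_history()
      ln <- segment_lines(h, min(h$day), 400L,
                          lot_config(first_line_window_days = w))
      combo <- combo + (ln$n_classes[1] >= 2)
    }
    combo
  })
  expect_true(all(diff(shares) >= 0))
})

test_that("engine agrees with the day-stepping oracle on random histories", {
  set.seed(424)
  for (rep in 1:120) {
    h <- random_history()
    censor <- max(h$day) + sample(20:300, 1)
    idx <- min(h$day)
    eng <- segment_lines(h, idx, censor)
    ora <- oracle_segment(h, idx, censor)
    expect_identical(nrow(eng), nrow(ora))
    expect_identical(eng$start_day, ora$start_day)
    expect_identical(eng$end_day, ora$end_day)
    expect_identical(eng$end_reason, ora$end_reason)
    expect_identical(eng$classes, ora$classes)
  }
})

test_that("lines partition time in order and map to one regimen each", {
  pop <- generate_population(generator_config(n_members = 120, seed = 606))
  cohort <- select_cohort(pop$dataset)
  lines <- segment_cohort_lines(cohort, pop$dataset)
  by_member <- split(lines, lines$member_id)
  for (ml in by_member) {
    expect_identical(ml$line_number, seq_len(nrow(ml)))
    if (nrow(ml) > 1) {
      expect_true(all(diff(ml$start_day) > 0))
      expect_true(all(ml$start_day[-1] >= ml$end_day[-nrow(ml)]))
    }
  }
  expect_true(all((lines$regimen_arm == "monotherapy") ==
                    (lines$n_classes == 1)))
  pat <- summarize_lines(lines)
  reg_tot <- pat$regimens |>
    dplyr::group_by(.data$line_number) |>
    dplyr::summarise(n = sum(.data$n_members))
  expect_identical(reg_tot$n, pat$overview$n_initiators[reg_tot$line_number])
})
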
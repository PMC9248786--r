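## Generator configuration: the default values ARE the study conditions --
## demographic mixes, regimen mixes, fate shares, follow-up moments, HCRU
## rates, and PPPM cost targets of the published cohort. The per-line
## event-time model is calibrated once (see the methods vignette) so that
## the emergent fate shares and months-in-line reproduce those targets
## under realistic follow-up censoring; its parameters ship frozen here.

## truncated samplers (inverse-CDF, exactly vectorized and deterministic)
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## lognormal meanlog/sdlog moment-matched to a target mean and SD
lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Largest-remainder integer allocation
#'
#' Splits `n` units across categories proportionally to `probs`, rounding
#' by largest fractional remainder so the counts sum exactly to `n`. Used
#' wherever the generator plants a categorical mix exactly rather than by
#' independent draws.
#'
#' @param n total count.
#' @param probs named nonnegative weights (normalized internally).
#' @return named integer vector summing to `n`.
#' @export
alloc_counts <- function(n, probs) {
  p <- probs / sum(probs)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

default_first_line_mix <- function() {
  c(MONO_ERA = 99, MONO_PDE5I = 436, MONO_PROSTA_ORAL = 5,
    MONO_PROSTA_INHALED = 22, MONO_PROSTA_PARENTERAL = 30, MONO_SGC = 72,
    COMBO_ERA_PDE5I = 103, COMBO_OTHER = 76) / 843
}

default_later_line_mixes <- function() {
  list(
    line2 = c(MONO_ERA = 27, MONO_PDE5I = 89, MONO_PROSTA_ORAL = 6,
              MONO_PROSTA_INHALED = 5, MONO_PROSTA_PARENTERAL = 8,
              MONO_SGC = 13, COMBO_ERA_PDE5I = 72, COMBO_OTHER = 106) / 326,
    line3 = c(MONO_ERA = 21, MONO_PDE5I = 35, MONO_PROSTA_ORAL = 2,
              MONO_PROSTA_INHALED = 2, MONO_PROSTA_PARENTERAL = 2,
              MONO_SGC = 5, COMBO_ERA_PDE5I = 24, COMBO_OTHER = 57) / 148,
    line4plus = c(MONO_ERA = 8, MONO_PDE5I = 13, MONO_PROSTA_ORAL = 2,
                  MONO_PROSTA_INHALED = 2, MONO_PROSTA_PARENTERAL = 2,
                  MONO_SGC = 3, COMBO_ERA_PDE5I = 10, COMBO_OTHER = 41) / 81
  )
}

## Per-line competing-risk event-time model (frozen calibration output).
## At a line start with residual follow-up R: the candidate event is an
## interruption w.p. q, else a modification; its time T (months) is a
## mixture of an early-event uniform on [1.05, fast_hi] (w.p. w) and a
## truncated lognormal tail. The event is observed only if it fits inside
## R (interruptions additionally need the 61-day gap to be observable);
## otherwise the line is censored at end of follow-up.
default_line_event_model <- function() {
  list(
    list(q = 0.5053, w = 0.5706, meanlog = 4.5076, sdlog = 1.4, fast_hi = 2.5),
    list(q = 0.3262, w = 0.0421, meanlog = 1.9730, sdlog = 1.2, fast_hi = 4.0),
    list(q = 0.2983, w = 0.0000, meanlog = 1.3939, sdlog = 0.8, fast_hi = 4.0),
    list(q = 0.2467, w = 0.0000, meanlog = 1.7231, sdlog = 0.8, fast_hi = 4.0)
  )
}

default_drug_mixes <- function() {
  list(
    ERA = c(RX_AMBRISENTAN = 0.51, RX_MACITENTAN = 0.47, RX_BOSENTAN = 0.02),
    PDE5I = c(RX_SILDENAFIL = 0.67, RX_TADALAFIL = 0.33),
    SGC = c(RX_RIOCIGUAT = 1),
    PROSTA_ORAL = c(RX_SELEXIPAG = 0.75, RX_TREPROSTINIL_OR = 0.25),
    PROSTA_INHALED = c(RX_TREPROSTINIL_INH = 0.97, RX_ILOPROST = 0.03),
    PROSTA_PARENTERAL = c(RX_TREPROSTINIL_PAR = 0.48, RX_EPOPROSTENOL = 0.52)
  )
}

## pharmacy drug token -> HCPCS administration token (classes that can be
## billed as medical administrations)
hcpcs_for_drug <- function() {
  c(RX_TREPROSTINIL_PAR = "J_TREPROSTINIL_PAR",
    RX_EPOPROSTENOL = "J_EPOPROSTENOL",
    RX_ILOPROST = "J_ILOPROST",
    RX_TREPROSTINIL_INH = "J_TREPROSTINIL_INH")
}

#' Synthetic-population generator settings
#'
#' The defaults encode the published study conditions: attrition pass
#' rates by step (compressed to desk scale; the source database's step-2
#' retention of 0.02% is not meaningful at thousands of members), index-year
#' and demographic mixes, regimen mixes per line, per-line continuation
#' targets with the frozen event-time model that realizes them, follow-up
#' moments (mean 18.5 / SD 15.4 months, truncated to [1.05, 63]), HCRU
#' PPPM rates, and PPPM cost targets in 2020 USD.
#'
#' @param n_members population size (cohort plus planted attrition
#'   failures).
#' @param seed integer seed; identical (config, seed) pairs generate
#'   byte-identical datasets.
#' @param attrition_pass named pass probabilities for selection steps 2-8
#'   (step 1 is membership itself).
#' @param index_year_mix distribution of index calendar year.
#' @param first_line_regimen_mix,later_line_regimen_mixes categorical
#'   regimen distributions planted exactly by largest-remainder
#'   allocation.
#' @param line_continuation per-line target shares of
#'   \{remain, interrupt, modify\} (must each sum to 1). These are the
#'   calibration targets realized by `line_event_model`.
#' @param line_event_model frozen per-line event-time parameters (see
#'   source); recalibrate if you change `line_continuation` or
#'   `followup_months`.
#' @param restart_prob per-line probability that an interrupted member
#'   later restarts therapy (line 1 is planted exactly).
#' @param followup_months `c(mean, sd)` of post-index follow-up months.
#' @param preindex_months `c(mean, sd)` of pre-index enrollment months.
#' @param hcru_rates PPPM event rates and PAH-diagnosis fractions per
#'   period (see source for fields).
#' @param cost_model PPPM cost targets (2020 USD) per period and component,
#'   plus dispersion and cost-split parameters.
#' @param days_supply_choices fill lengths and their probabilities.
#' @param demographics age/sex/insurance/region/comorbidity mixes.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    n_members = 2000L,
    seed = 1L,
    attrition_pass = c(step2 = 0.95, step3 = 0.97, step4 = 0.94,
                       step5 = 0.95, step6 = 0.97, step7 = 0.96,
                       step8 = 0.985),
    index_year_mix = c(`2015` = 42, `2016` = 179, `2017` = 173,
                       `2018` = 158, `2019` = 158, `2020` = 133) / 843,
    first_line_regimen_mix = default_first_line_mix(),
    later_line_regimen_mixes = default_later_line_mixes(),
    line_continuation = list(c(remain = 0.397, interrupt = 0.297, modify = 0.306),
                             c(remain = 0.426, interrupt = 0.172, modify = 0.402),
                             c(remain = 0.338, interrupt = 0.176, modify = 0.486),
                             c(remain = 0.432, interrupt = 0.123, modify = 0.445)),
    line_event_model = default_line_event_model(),
    restart_prob = c(0.272, 0.304, 0.346, 0.30),
    followup_months = c(mean = 18.5, sd = 15.4),
    preindex_months = c(mean = 68.4, sd = 52.7),
    hcru_rates = list(
      baseline = c(inpatient = 0.17, er = 0.07, outpatient = 5.34,
                   pharmacy_other = 2.95),
      postindex = c(inpatient = 0.09, er = 0.05, outpatient = 5.60,
                    pharmacy_other = 3.01),
      pah_dx_frac_baseline = c(inpatient = 0.647, er = 0.143, outpatient = 0.17),
      pah_dx_frac_postindex = c(inpatient = 0.667, er = 0.20, outpatient = 0.239),
      transplant_prob = 0.053
    ),
    cost_model = list(
      baseline = c(medical_pah = 10868, medical_other = 3340,
                   pharmacy_pah = 0, pharmacy_other = 909),
      postindex = c(medical_pah = 3617, medical_other = 2732,
                    pharmacy_pah = 6889, pharmacy_other = 963),
      member_sigma = 0.5,
      claim_sigma = 0.6,
      setting_weights = c(inpatient = 30, er = 3, outpatient = 1),
      class_weights = c(ERA = 8, PDE5I = 1, SGC = 8, PROSTA_ORAL = 12,
                        PROSTA_INHALED = 15, PROSTA_PARENTERAL = 18,
                        other = 1),
      split = c(plan = 0.8, member = 0.15, cob = 0.05)
    ),
    days_supply_choices = c(`30` = 0.85, `90` = 0.15),
    demographics = list(
      age = c(mean = 62.3, sd = 14.1, lo = 19, hi = 95),
      female = 0.642,
      insurance = c(commercial = 0.59, medicare_advantage = 0.237,
                    medicare_other = 0.173),
      region = c(midwest = 0.325, northeast = 0.146, south = 0.311,
                 west = 0.218),
      qci = c(mean = 4.6, sd = 2.7, lo = 0, hi = 15)
    )) {
  stopifnot(n_members >= 1)
  check_probs <- function(x, nm) {
    if (any(x < 0 | x > 1)) {
      stop("generator_config: ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  check_mix <- function(x, nm) {
    check_probs(x, nm)
    if (abs(sum(x) - 1) > 1e-9) {
      stop("generator_config: ", nm, " must sum to 1 (got ", sum(x), ")",
           call. = FALSE)
    }
  }
  check_probs(attrition_pass, "attrition_pass")
  check_mix(index_year_mix, "index_year_mix")
  check_mix(first_line_regimen_mix, "first_line_regimen_mix")
  for (nm in names(later_line_regimen_mixes)) {
    check_mix(later_line_regimen_mixes[[nm]], paste0("regimen mix ", nm))
  }
  for (k in seq_along(line_continuation)) {
    check_mix(line_continuation[[k]], paste0("line_continuation[[", k, "]]"))
  }
  check_probs(restart_prob, "restart_prob")
  check_mix(days_supply_choices, "days_supply_choices")
  stopifnot(followup_months[["mean"]] > 0, followup_months[["sd"]] > 0)
  structure(
    list(n_members = as.integer(n_members), seed = as.integer(seed),
         attrition_pass = attrition_pass, index_year_mix = index_year_mix,
         first_line_regimen_mix = first_line_regimen_mix,
         later_line_regimen_mixes = later_line_regimen_mixes,
         line_continuation = line_continuation,
         line_event_model = line_event_model,
         restart_prob = restart_prob,
         followup_months = followup_months,
         preindex_months = preindex_months,
         hcru_rates = hcru_rates, cost_model = cost_model,
         days_supply_choices = days_supply_choices,
         demographics = demographics,
         drug_mixes = default_drug_mixes()),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> n_members =", x$n_members, " seed =", x$seed, "\n")
  cat("  cohort fraction ~", round(prod(x$attrition_pass), 3), "\n")
  invisible(x)
}
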
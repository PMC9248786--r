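# Hand-built fixture builders, independent of the synthetic generator.

blank_member <- function(id, birth_year = 1955L) {
  tibble::tibble(member_id = id, birth_year = birth_year, sex = "F",
                 insurance = "commercial", region = "south", qci = 3)
}

med_row <- function(id, day, setting = "outpatient", dx = "",
                    proc = "", hcpcs = NA_character_, cost = 100) {
  tibble::tibble(member_id = id, service_day = as.integer(day),
                 setting = setting, dx_codes = dx, proc_codes = proc,
                 hcpcs_drug_code = hcpcs, cost_plan = cost,
                 cost_member = 0, cost_cob = 0)
}

rx_row <- function(id, day, drug = "RX_SILDENAFIL", supply = 30L,
                   cost = 50) {
  tibble::tibble(member_id = id, fill_day = as.integer(day),
                 drug_code = drug, days_supply = as.integer(supply),
                 cost_plan = cost, cost_member = 0, cost_cob = 0)
}

enr_row <- function(id, start, end) {
  tibble::tibble(member_id = id, start_day = as.integer(start),
                 end_day = as.integer(end), benefit = "medical_and_pharmacy")
}

# Nine members: "ok" passes every step; "f2".."f8" each fail exactly the
# named selection step and pass all earlier ones. Index day 400 throughout.
attrition_fixture <- function() {
  idx <- 400L
  evidence <- function(id) dplyr::bind_rows(
    med_row(id, idx - 30, dx = "I27.0;J44.9"),
    med_row(id, idx - 60, dx = "416.0"),
    med_row(id, idx - 50, proc = "93451")
  )
  members <- dplyr::bind_rows(
    blank_member("ok"),
    blank_member("f2"),
    blank_member("f3", birth_year = day_to_year(idx) - 16L),
    blank_member("f4"), blank_member("f5"), blank_member("f6"),
    blank_member("f7"), blank_member("f8")
  )
  enrollment <- dplyr::bind_rows(
    enr_row("ok", idx - 400, idx + 300),
    enr_row("f2", idx - 400, idx + 300),
    enr_row("f3", idx - 400, idx + 300),
    enr_row("f4", idx - 400, idx + 300),
    enr_row("f5", idx - 400, idx + 300),
    enr_row("f6", idx - 900, idx + 300),
    enr_row("f7", idx - 100, idx + 300),
    enr_row("f8", idx - 400, idx + 15)
  )
  medical <- dplyr::bind_rows(
    evidence("ok"), evidence("f3"), evidence("f6"), evidence("f7"),
    evidence("f8"),
    # f4: two qualifying outpatient claims on the SAME day, RHC present
    med_row("f4", idx - 40, dx = "I27.20"),
    med_row("f4", idx - 40, dx = "I27.20"),
    med_row("f4", idx - 50, proc = "93451"),
    # f5: diagnosis evidence fine, no RHC anywhere
    med_row("f5", idx - 30, dx = "I27.0"),
    med_row("f5", idx - 60, dx = "I27.9")
  )
  pharmacy <- dplyr::bind_rows(
    rx_row("ok", idx),
    # f2: no PAH medication claim at all
    rx_row("f2", idx, drug = "RX_UNMAPPED_DRUG"),
    rx_row("f3", idx), rx_row("f4", idx), rx_row("f5", idx),
    # f6: prior fill before the identification window, inside enrollment
    rx_row("f6", -20L), rx_row("f6", idx),
    rx_row("f7", idx), rx_row("f8", idx)
  )
  claims_dataset(members, enrollment, medical, pharmacy)
}

# minimal single-member dataset with a given set of pharmacy fills
one_member_ds <- function(fills, enroll_start = -400L, enroll_end = 1200L,
                          extra_medical = NULL) {
  idx <- min(fills$fill_day)
  medical <- dplyr::bind_rows(
    med_row("m1", idx - 30, dx = "I27.0"),
    med_row("m1", idx - 60, dx = "I27.9"),
    med_row("m1", idx - 10, proc = "93451"),
    extra_medical
  )
  claims_dataset(blank_member("m1"), enr_row("m1", enroll_start, enroll_end),
                 medical, fills)
}
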
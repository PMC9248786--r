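## Code sets: PAH diagnosis codes, RHC procedure codes, and the synthetic
## drug-code -> medication-class dictionaries used throughout the pipeline.

#' The six PAH medication classes
#'
#' Endothelin receptor antagonists (ERA), phosphodiesterase-5 inhibitors
#' (PDE5I), soluble guanylate cyclase stimulators (SGC), and the three
#' prostacyclin / IP-receptor-agonist routes, which are distinguished as
#' separate classes: oral, inhaled, and parenteral.
#'
#' @return character vector of the six class labels.
#' @export
pah_drug_classes <- function() {
  c("ERA", "PDE5I", "SGC", "PROSTA_ORAL", "PROSTA_INHALED", "PROSTA_PARENTERAL")
}

#' Default PAH/PH diagnosis code set
#'
#' ICD-9-CM 416.0 / 416.8 / 416.9 and ICD-10-CM I27.0 / I27.2 / I27.20 /
#' I27.21 / I27.29 / I27.89 / I27.9. Codes are matched as exact strings
#' against the diagnosis codes on medical claims (any position).
#'
#' @return character vector of diagnosis codes.
#' @export
default_pah_dx_codes <- function() {
  c("416.0", "416.8", "416.9",
    "I27.0", "I27.2", "I27.20", "I27.21", "I27.29", "I27.89", "I27.9")
}

#' Default drug-code to medication-class map
#'
#' Synthetic pharmacy drug tokens (one per PAH drug named in the protocol)
#' mapped to the six medication classes. Real GPI/NDC dictionaries are out of
#' scope; any claims extract can be used by supplying its own map with the
#' same three columns.
#'
#' @return a tibble with columns `drug_code`, `drug_name`, `drug_class`.
#' @export
default_drug_class_map <- function() {
  tibble::tribble(
    ~drug_code,            ~drug_name,             ~drug_class,
    "RX_AMBRISENTAN",      "ambrisentan",          "ERA",
    "RX_BOSENTAN",         "bosentan",             "ERA",
    "RX_MACITENTAN",       "macitentan",           "ERA",
    "RX_SILDENAFIL",       "sildenafil",           "PDE5I",
    "RX_TADALAFIL",        "tadalafil",            "PDE5I",
    "RX_RIOCIGUAT",        "riociguat",            "SGC",
    "RX_SELEXIPAG",        "selexipag",            "PROSTA_ORAL",
    "RX_TREPROSTINIL_OR",  "treprostinil oral",    "PROSTA_ORAL",
    "RX_ILOPROST",         "iloprost",             "PROSTA_INHALED",
    "RX_TREPROSTINIL_INH", "treprostinil inhaled", "PROSTA_INHALED",
    "RX_TREPROSTINIL_PAR", "treprostinil parenteral", "PROSTA_PARENTERAL",
    "RX_EPOPROSTENOL",     "epoprostenol",         "PROSTA_PARENTERAL"
  )
}

#' Default HCPCS drug-administration code to medication-class map
#'
#' Medication classes that can be administered in a medical setting
#' (inhaled and parenteral prostacyclins) carry HCPCS-like tokens on medical
#' claims; these map to the same class space as pharmacy fills.
#'
#' @return a tibble with columns `hcpcs_code`, `drug_name`, `drug_class`.
#' @export
default_hcpcs_class_map <- function() {
  tibble::tribble(
    ~hcpcs_code,          ~drug_name,                ~drug_class,
    "J_TREPROSTINIL_PAR", "treprostinil parenteral", "PROSTA_PARENTERAL",
    "J_EPOPROSTENOL",     "epoprostenol",            "PROSTA_PARENTERAL",
    "J_ILOPROST",         "iloprost",                "PROSTA_INHALED",
    "J_TREPROSTINIL_INH", "treprostinil inhaled",    "PROSTA_INHALED"
  )
}

#' Assemble the code sets used by every pipeline stage
#'
#' @param pah_dx_codes diagnosis codes identifying PH/PAH.
#' @param rhc_proc_codes procedure codes identifying right heart
#'   catheterization (RHC), the confirmatory procedure required for cohort
#'   entry.
#' @param drug_class_map tibble mapping pharmacy `drug_code` to
#'   `drug_class`.
#' @param hcpcs_class_map tibble mapping medical `hcpcs_code` to
#'   `drug_class`.
#' @param transplant_proc_codes procedure codes identifying lung or
#'   heart-lung transplant.
#' @return an object of class `pah_codesets` (a named list).
#' @export
pah_codesets <- function(pah_dx_codes = default_pah_dx_codes(),
                         rhc_proc_codes = c("93451", "93453", "93456",
                                            "93457", "93458", "93460", "93461"),
                         drug_class_map = default_drug_class_map(),
                         hcpcs_class_map = default_hcpcs_class_map(),
                         transplant_proc_codes = c("TXP_LUNG", "TXP_HEART_LUNG")) {
  stopifnot(is.character(pah_dx_codes), length(pah_dx_codes) > 0,
            is.character(rhc_proc_codes))
  drug_class_map <- tibble::as_tibble(drug_class_map)
  hcpcs_class_map <- tibble::as_tibble(hcpcs_class_map)
  need <- c("drug_code", "drug_class")
  if (!all(need %in% names(drug_class_map))) {
    stop("drug_class_map must have columns drug_code and drug_class", call. = FALSE)
  }
  if (!all(c("hcpcs_code", "drug_class") %in% names(hcpcs_class_map))) {
    stop("hcpcs_class_map must have columns hcpcs_code and drug_class", call. = FALSE)
  }
  bad <- setdiff(unique(c(drug_class_map$drug_class, hcpcs_class_map$drug_class)),
                 pah_drug_classes())
  if (length(bad) > 0) {
    stop("unknown drug class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(drug_class_map$drug_code)) {
    stop("drug_class_map maps some drug_code to more than one row", call. = FALSE)
  }
  structure(
    list(pah_dx_codes = pah_dx_codes,
         rhc_proc_codes = rhc_proc_codes,
         drug_class_map = drug_class_map,
         hcpcs_class_map = hcpcs_class_map,
         transplant_proc_codes = transplant_proc_codes),
    class = "pah_codesets"
  )
}

#' @export
print.pah_codesets <- function(x, ...) {
  cat("<pah_codesets>\n")
  cat("  dx codes:   ", length(x$pah_dx_codes), "\n")
  cat("  RHC codes:  ", length(x$rhc_proc_codes), "\n")
  cat("  drug codes: ", nrow(x$drug_class_map), "->",
      length(unique(x$drug_class_map$drug_class)), "classes\n")
  cat("  HCPCS codes:", nrow(x$hcpcs_class_map), "\n")
  invisible(x)
}

## Internal lookups: named vectors drug_code -> class
drug_class_lookup <- function(codesets) {
  stats::setNames(codesets$drug_class_map$drug_class, codesets$drug_class_map$drug_code)
}

hcpcs_class_lookup <- function(codesets) {
  stats::setNames(codesets$hcpcs_class_map$drug_class, codesets$hcpcs_class_map$hcpcs_code)
}

## Does any diagnosis code in a ';'-separated string belong to the PAH set?
has_pah_dx <- function(dx_codes, codesets) {
  if (length(dx_codes) == 0) return(logical(0))
  dx_codes <- as.character(dx_codes)
  vapply(strsplit(ifelse(is.na(dx_codes), "", dx_codes), ";", fixed = TRUE),
         function(codes) any(codes %in% codesets$pah_dx_codes),
         logical(1))
}

## Does any procedure code match a configured set?
has_proc <- function(proc_codes, set) {
  if (length(proc_codes) == 0) return(logical(0))
  proc_codes <- as.character(proc_codes)
  vapply(strsplit(ifelse(is.na(proc_codes), "", proc_codes), ";", fixed = TRUE),
         function(codes) any(codes %in% set),
         logical(1))
}
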
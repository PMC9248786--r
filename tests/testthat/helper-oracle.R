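# Independent day-by-day line-segmentation simulator: walks calendar days
# one at a time, tracking the class set formed in the line-start window and
# the running all-class run-out, and applies the interruption /
# modification / censoring rules literally. Used as the oracle against the
# event-driven engine.

oracle_segment <- function(claims, index_day, censor_day,
                           window = 30L, gap = 60L) {
  claims <- claims[claims$day >= index_day & claims$day < censor_day, ,
                   drop = FALSE]
  claims <- claims[order(claims$day, claims$drug_class, claims$drug_code), ,
                   drop = FALSE]
  out <- list()
  s <- index_day
  repeat {
    cs <- claims[claims$day >= s, , drop = FALSE]
    if (nrow(cs) == 0) break
    C <- character(0)
    runout <- s
    end <- NA_integer_; reason <- NA_character_; nxt <- NA_integer_
    d <- s
    while (d < censor_day) {
      todays <- cs[cs$day == d, , drop = FALSE]
      if (nrow(todays) > 0) {
        if (length(C) > 0 && d > runout + gap) {
          end <- runout; reason <- "interruption"; nxt <- d
          break
        }
        for (r in seq_len(nrow(todays))) {
          cl <- todays$drug_class[r]
          if (d <= s + window) {
            C <- union(C, cl)
            runout <- max(runout, d + todays$supply_days[r])
          } else if (cl %in% C) {
            runout <- max(runout, d + todays$supply_days[r])
          } else {
            end <- d; reason <- "modification"; nxt <- d
            break
          }
        }
        if (!is.na(end)) break
      }
      d <- d + 1L
    }
    if (is.na(end)) {
      if (censor_day > runout + gap) {
        end <- runout; reason <- "interruption"
      } else {
        end <- censor_day; reason <- "censored"
      }
    }
    out[[length(out) + 1]] <- tibble::tibble(
      line_number = length(out) + 1L, start_day = s, end_day = end,
      end_reason = reason, classes = paste(sort(C), collapse = ";")
    )
    if (is.na(nxt)) break
    s <- nxt
  }
  dplyr::bind_rows(out)
}

# random small medication history for engine-vs-oracle comparison
random_history <- function(max_fills = 6L) {
  n <- sample.int(max_fills, 1)
  tibble::tibble(
    day = sort(sample(0:250, n, replace = TRUE)),
    drug_class = sample(pah_drug_classes(), n, replace = TRUE),
    drug_code = paste0("RX_", seq_len(n)),
    supply_days = sample(c(5L, 15L, 30L, 45L, 90L), n, replace = TRUE),
    source = "pharmacy"
  )
}
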
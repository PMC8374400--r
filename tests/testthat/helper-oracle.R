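# Brute-force oracle for the percentage aggregation: explicit loops,
# integer (rational) arithmetic on abundances known to be exact multiples
# of 1/scale.  Deliberately shares no code with the package internals.
oracle_percent <- function(sample, genus, abundance, mode,
                           taxonomy, ecogroup, scale = 1L) {
  units <- round(abundance * scale)
  cat_of <- character(length(genus))
  for (i in seq_along(genus)) {
    g <- tolower(trimws(genus[i]))
    val <- NA_character_
    if (mode %in% c("phylum", "order", "family")) {
      for (j in seq_len(nrow(taxonomy)))
        if (tolower(trimws(taxonomy$genus[j])) == g) {
          val <- taxonomy[[mode]][j]
          break
        }
    } else {
      for (j in seq_len(nrow(ecogroup)))
        if (tolower(trimws(ecogroup$genus[j])) == g) {
          val <- ecogroup[[mode]][j]
          break
        }
    }
    cat_of[i] <- if (is.na(val) || !nzchar(val)) "Uncertain" else val
  }
  out <- list()
  for (s in unique(sample)) {
    idx <- which(sample == s)
    tot <- 0
    for (i in idx) tot <- tot + units[i]
    row <- numeric(0)
    for (cc in unique(cat_of)) {
      gsum <- 0
      for (i in idx) if (cat_of[i] == cc) gsum <- gsum + units[i]
      row[[cc]] <- 100 * gsum / tot
    }
    out[[s]] <- row
  }
  out
}

# Write a small CSV from lines, returning its path (auto-deleted by caller's
# tempdir lifetime; tests run in a per-session temp directory).
tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# The worked result table for order mode of the bundled two-sample
# assemblage: 14 categories, values as printed at one decimal.
ORDER_EXPECTED <- local({
  cats <- c("Bennettitales", "Corystospermales", "Cyatheales", "Equisetales",
            "Ginkgoales", "Gleicheniales", "Isoetales", "Lycopodiales",
            "Marattiales", "Notothyladales", "Osmundales", "Peltaspermales",
            "Pinales", "Uncertain")
  m <- matrix(c(33.8, 8.9,
                25,   33.9,
                6.6,  4.7,
                0,    2,
                4.4,  7.5,
                13.2, 7.7,
                7.4,  2.4,
                0,    8.4,
                0,    11.3,
                5.9,  0.7,
                0.7,  0,
                0,    1.3,
                1.5,  9.8,
                1.5,  1.5),
              nrow = 2, dimnames = list(c("HJG 01", "HJG 02"), cats))
  m
})

# Hand-derived EPH shares for sample HJG 01 (summed from the bundled
# ecogroup excerpt over the assemblage; verified to total 100).
EPH_HJG01_EXPECTED <- c(hydrophytes = 7.4, hygrophytes = 16.1,
                        mesophytes = 42.6, xerophytes = 1.5,
                        Uncertain = 32.4)
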
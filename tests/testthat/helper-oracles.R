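# Independent oracles used across the test files.

# Brute-force digestion oracle: examine every substring of the parent
# and keep those whose boundaries are valid tryptic termini and whose
# internal uncleaved-site count is within the missed-cleavage budget.
# Deliberately a different route than the boundary walk in digest().
brute_force_digest <- function(sequence, max_missed) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(letters)
  is_cut_after <- function(i) {
    i >= 1 && i < n && letters[i] %in% c("K", "R") && letters[i + 1] != "P"
  }
  out <- list()
  for (start in 1:n) {
    for (end in start:n) {
      left_ok <- start == 1 || is_cut_after(start - 1)
      right_ok <- end == n || is_cut_after(end)
      if (!left_ok || !right_ok) next
      internal <- if (end > start)
        sum(vapply(start:(end - 1), is_cut_after, TRUE)) else 0L
      if (internal <= max_missed)
        out[[length(out) + 1L]] <- data.frame(
          sequence = paste(letters[start:end], collapse = ""),
          start = start, end = end, missed_cleavages = internal)
    }
  }
  d <- do.call(rbind, out)
  d[order(d$start, d$missed_cleavages), , drop = FALSE]
}

random_protein <- function(len) {
  paste(sample(rownames(qconquant:::.RESIDUE_COMPOSITION), len,
               replace = TRUE), collapse = "")
}

# Residue-table sum oracle for peptide masses, independent of
# peptide_mass()'s lookup caching.
mass_by_table <- function(sequence, kind = "monoisotopic") {
  tab <- residue_table()
  col <- if (kind == "monoisotopic") "mono" else "average"
  water <- if (kind == "monoisotopic") WATER_MONO else WATER_AVG
  sum(tab[strsplit(sequence, "", fixed = TRUE)[[1]], col]) + water
}
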
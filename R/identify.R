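# Peptide-mass-fingerprint identification: match an observed list of
# singly-protonated monoisotopic masses against the theoretical tryptic
# digest of a protein, within a mass tolerance, and report sequence
# coverage. This is deliberately tolerance matching plus coverage, not a
# probabilistic search-engine score: coverage percent and match counts
# are the quantities the workflow reports.

#' Read an observed mass list
#'
#' Accepts one-mass-per-line text or CSV with columns `mass` and
#' optionally `intensity`. Masses are sorted ascending.
#'
#' @param path Input path.
#' @param source Label recorded with the list.
#' @return A data frame with columns `mass`, `intensity`, `source`.
#' @export
read_mass_list <- function(path, source = basename(path)) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    tab <- utils::read.csv(path)
    if (!"mass" %in% names(tab))
      names(tab)[1] <- "mass"
    if (!"intensity" %in% names(tab)) tab$intensity <- NA_real_
  } else {
    tab <- data.frame(mass = as.numeric(readLines(path)),
                      intensity = NA_real_)
  }
  tab <- tab[!is.na(tab$mass), c("mass", "intensity")]
  if (any(tab$mass <= 0)) stop("masses must be positive", call. = FALSE)
  tab <- tab[order(tab$mass), , drop = FALSE]
  tab$source <- source
  tab
}

# Enumerate theoretical peptides x variable-modification combinations.
# Each M can be oxidized, each Y nitrated; combinations are capped at
# max_mods simultaneous modifications to keep the candidate list sparse.
.theoretical_candidates <- function(protein, max_missed, variable_mods,
                                    max_mods = 2L) {
  peps <- digest(protein, max_missed = max_missed)
  modtab <- modification_table()
  modtab <- modtab[modtab$name %in% variable_mods, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(peps))) {
    seq <- peps$sequence[i]
    base_mass <- peptide_mass(seq)
    # modifiable sites in this peptide
    sites <- list()
    for (j in seq_len(nrow(modtab))) {
      at <- which(strsplit(seq, "", fixed = TRUE)[[1]] == modtab$target[j])
      for (s in at) sites[[length(sites) + 1L]] <-
        list(name = modtab$name[j], site = s, delta = modtab$delta[j])
    }
    nmax <- min(length(sites), max_mods)
    combos <- list(integer(0))
    if (nmax >= 1) for (k in seq_len(nmax))
      combos <- c(combos, utils::combn(seq_along(sites), k, simplify = FALSE))
    for (cmb in combos) {
      delta <- sum(vapply(sites[cmb], `[[`, 0, "delta"))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq, start = peps$start[i], end = peps$end[i],
        missed_cleavages = peps$missed_cleavages[i],
        n_mods = length(cmb),
        modifications = paste(vapply(sites[cmb], function(s)
          paste0(s$name, "@", s$site), ""), collapse = ";"),
        theoretical_mh = base_mass + delta + PROTON_MASS
      )
    }
  }
  do.call(rbind, rows)
}

#' Match an observed mass list to a protein's theoretical digest
#'
#' Theoretical `[M+H]+` monoisotopic masses are enumerated over the
#' tryptic digest (up to `max_missed` missed cleavages) and variable
#' modification combinations. Each observed mass is assigned to the
#' nearest theoretical peptide within `tolerance`; ties are broken by
#' fewer modifications, then fewer missed cleavages, then the most
#' N-terminal peptide. Each observed mass matches at most one peptide
#' (greedy closest-match assignment).
#'
#' @param mass_list Numeric vector of observed `[M+H]+` masses, or a
#'   data frame from [read_mass_list()].
#' @param protein Protein sequence.
#' @param tolerance Peptide mass tolerance in Da (default 0.3).
#' @param max_missed Maximum missed cleavages (default 1).
#' @param variable_mods Character vector of variable modification names
#'   (default oxidation of M and nitration of Y).
#' @param protein_id Identifier reported in the result.
#' @return A `pmf_result` list: `protein_id`, `matches` (data frame of
#'   observed mass, theoretical mass, delta, peptide, span, missed
#'   cleavages, modifications), `n_matched`, `coverage` (percent).
#' @export
match_masses <- function(mass_list, protein, tolerance = 0.3,
                         max_missed = 1L,
                         variable_mods = c("oxidation", "nitro"),
                         protein_id = NA_character_) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (is.data.frame(mass_list)) mass_list <- mass_list$mass
  empty <- data.frame(observed = numeric(0), theoretical = numeric(0),
                      delta = numeric(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0),
                      modifications = character(0))
  res <- structure(list(protein_id = protein_id, matches = empty,
                        n_matched = 0L, coverage = 0),
                   class = "pmf_result")
  if (length(mass_list) == 0L) return(res)
  cand <- .theoretical_candidates(protein, max_missed, variable_mods)
  rows <- list()
  for (obs in sort(mass_list)) {
    d <- abs(cand$theoretical_mh - obs)
    ok <- which(d <= tolerance)
    if (!length(ok)) next
    ok <- ok[order(d[ok], cand$n_mods[ok], cand$missed_cleavages[ok],
                   cand$start[ok])]
    best <- ok[1]
    rows[[length(rows) + 1L]] <- data.frame(
      observed = obs, theoretical = cand$theoretical_mh[best],
      delta = obs - cand$theoretical_mh[best],
      sequence = cand$sequence[best], start = cand$start[best],
      end = cand$end[best],
      missed_cleavages = cand$missed_cleavages[best],
      modifications = cand$modifications[best]
    )
  }
  if (length(rows)) res$matches <- do.call(rbind, rows)
  res$n_matched <- nrow(res$matches)
  res$coverage <- coverage(res, protein)
  res
}

#' Sequence coverage of a PMF result
#'
#' Percentage of the protein's residues covered by the union of matched
#' peptide spans (overlaps counted once).
#'
#' @param pmf_result A `pmf_result` from [match_masses()].
#' @param protein The protein sequence the result refers to.
#' @return Coverage percent in `[0, 100]`.
#' @export
coverage <- function(pmf_result, protein) {
  m <- pmf_result$matches
  if (nrow(m) == 0L) return(0)
  covered <- logical(nchar(protein))
  for (i in seq_len(nrow(m))) covered[m$start[i]:m$end[i]] <- TRUE
  100 * sum(covered) / nchar(protein)
}

#' @export
print.pmf_result <- function(x, ...) {
  cat(sprintf("<pmf_result> %s: %d matched peptides, %.1f%% coverage\n",
              x$protein_id, x$n_matched, x$coverage))
  invisible(x)
}

#' Write a PMF report and matched-span map
#'
#' @param result A `pmf_result`.
#' @param report_path CSV path for the match table.
#' @param span_path Optional path for a BED-like span table
#'   (protein, start, end, peptide).
#' @return The match table, invisibly.
#' @export
write_pmf_report <- function(result, report_path, span_path = NULL) {
  utils::write.csv(result$matches, report_path, row.names = FALSE)
  if (!is.null(span_path)) {
    spans <- data.frame(protein = result$protein_id,
                        start = result$matches$start,
                        end = result$matches$end,
                        peptide = result$matches$sequence)
    utils::write.table(spans, span_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result$matches)
}
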
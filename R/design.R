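# Fingerprint-peptide design: candidate evaluation against empirical
# detectability rules, uniqueness screening against a background proteome
# with the trypsin cleavage-context argument, QconCAT assembly, and the
# molar bookkeeping that links a weighed standard to released peptide
# amounts.

#' Design rules for fingerprint peptides
#'
#' The rules are scored preferences, not hard filters: a peptide may
#' fail a rule and still be usable (a 6-residue peptide was successfully
#' used for DcR3 quantification). Candidates are ranked by the number of
#' rules they satisfy.
#'
#' @param min_length,max_length Preferred peptide length range in
#'   residues (default 8-15, which limits charge-state spread).
#' @param forbid_proline_context Penalize peptides that start with
#'   proline or contain an internal K/R followed by P (both impair clean
#'   tryptic release).
#' @param forbid_adjacent_basics Penalize adjacent basic residues
#'   (KK/KR/RK/RR) inside the peptide or spanning its boundaries, which
#'   reduce digestion efficiency.
#' @param require_unique Whether the uniqueness screen verdict enters
#'   the score (only meaningful when a background proteome is supplied).
#' @return A `design_rules` list.
#' @export
design_rules <- function(min_length = 8L, max_length = 15L,
                         forbid_proline_context = TRUE,
                         forbid_adjacent_basics = TRUE,
                         require_unique = FALSE) {
  stopifnot(min_length > 0, max_length >= min_length)
  structure(list(min_length = min_length, max_length = max_length,
                 forbid_proline_context = forbid_proline_context,
                 forbid_adjacent_basics = forbid_adjacent_basics,
                 require_unique = require_unique),
            class = "design_rules")
}

.has_adjacent_basics <- function(sequence, before = "", after = "") {
  ext <- paste0(before, sequence, after)
  grepl("[KR][KR]", ext)
}

.has_proline_block <- function(sequence, after = "") {
  if (startsWith(sequence, "P")) return(TRUE)
  # internal K/R immediately followed by P (a blocked cleavage inside),
  # or the residue after the peptide in its parent being P
  grepl("[KR]P", paste0(sequence, after))
}

#' Evaluate tryptic peptides of a protein as fingerprint candidates
#'
#' Digests the protein (0 missed cleavages) and scores every peptide
#' against the design rules; optionally screens each against a
#' background proteome for uniqueness. All peptides are reported with
#' per-rule pass/fail flags, ranked by number of satisfied rules with
#' ties broken by parent position.
#'
#' @param sequence Protein sequence.
#' @param rules A [design_rules()] object.
#' @param background Optional named character vector of background
#'   proteome sequences for the uniqueness screen.
#' @param parent Identifier for the protein.
#' @return A data frame with one row per tryptic peptide: coordinates,
#'   `length_ok`, `no_proline_block`, `no_adjacent_basics`, `verdict`,
#'   `conflicts` (semicolon-separated identifiers), `score`, `rank`.
#' @export
evaluate_candidates <- function(sequence, rules = design_rules(),
                                background = NULL,
                                parent = NA_character_) {
  peps <- digest(sequence, max_missed = 0L, parent = parent)
  if (nrow(peps) == 0L) return(peps)
  n <- nchar(sequence)
  before <- ifelse(peps$start > 1L,
                   substring(sequence, peps$start - 1L, peps$start - 1L), "")
  after <- ifelse(peps$end < n,
                  substring(sequence, peps$end + 1L, peps$end + 1L), "")
  len <- nchar(peps$sequence)
  peps$length_ok <- len >= rules$min_length & len <= rules$max_length
  peps$no_proline_block <- !mapply(.has_proline_block, peps$sequence, after)
  peps$no_adjacent_basics <- !mapply(.has_adjacent_basics, peps$sequence,
                                     before, after)
  if (!is.null(background)) {
    screens <- lapply(peps$sequence, uniqueness_screen, background = background)
    peps$verdict <- vapply(screens, `[[`, "", "verdict")
    peps$conflicts <- vapply(screens, function(s)
      paste(s$conflicts, collapse = ";"), "")
  } else {
    peps$verdict <- NA_character_
    peps$conflicts <- ""
  }
  score <- as.integer(peps$length_ok)
  if (rules$forbid_proline_context) score <- score + peps$no_proline_block
  if (rules$forbid_adjacent_basics) score <- score + peps$no_adjacent_basics
  if (rules$require_unique && !is.null(background))
    score <- score + (peps$verdict != "shared")
  peps$score <- score
  ord <- order(-peps$score, peps$start)
  peps$rank <- match(seq_len(nrow(peps)), ord)
  peps[ord, , drop = FALSE]
}

#' Screen a peptide for uniqueness against a background proteome
#'
#' Finds every exact occurrence of the peptide sequence in the
#' background. An occurrence only threatens quantification if trypsin
#' could actually liberate that peptide from the background protein,
#' i.e. if the residue immediately N-terminal to the hit is K or R, or
#' the hit starts at the protein's first residue (a mature N-terminus).
#' Occurrences without such a cleavage context share the sequence but
#' can never appear as the free peptide.
#'
#' @param pep Peptide sequence (or `peptide` object).
#' @param background Named character vector of background protein
#'   sequences.
#' @return A list with `verdict` (`"unique"`,
#'   `"shared-context-unique"` or `"shared"`), `conflicts` (identifiers
#'   of proteins from which the peptide is liberable) and `occurrences`
#'   (identifiers of all proteins containing the sequence).
#' @export
uniqueness_screen <- function(pep, background) {
  seq <- .peptide_sequence(pep)
  validate_sequence(seq)
  if (length(background) == 0L)
    stop("background proteome is empty", call. = FALSE)
  occ_ids <- character(0)
  conflict_ids <- character(0)
  for (id in names(background)) {
    prot <- background[[id]]
    hits <- gregexpr(seq, prot, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    occ_ids <- c(occ_ids, id)
    prev <- ifelse(hits == 1L, "", substring(prot, hits - 1L, hits - 1L))
    if (any(hits == 1L | prev %in% c("K", "R")))
      conflict_ids <- c(conflict_ids, id)
  }
  verdict <- if (length(conflict_ids)) "shared"
    else if (length(occ_ids)) "shared-context-unique"
    else "unique"
  list(verdict = verdict, conflicts = conflict_ids, occurrences = occ_ids)
}

#' Assemble a QconCAT concatamer from fingerprint peptides
#'
#' Concatenates the peptides in order, appends an optional affinity-tag
#' sequence at the C-terminus, and verifies by in-silico digestion that
#' every design peptide is released intact (each peptide must end in
#' K/R and none may begin with P, otherwise tryptic release is not
#' guaranteed). Each concatamer molecule releases exactly one copy of
#' each peptide, which is what makes the construct a stoichiometric
#' internal standard.
#'
#' @param peptides Character vector of fingerprint peptide sequences.
#' @param tag Optional C-terminal tag sequence (e.g. `"HHHHHH"`).
#' @return A `qconcat_design` list: `peptides`, `tag`, `sequence`,
#'   `molar_mass` (average-mass Da of the full construct),
#'   `nitrogen` (per-peptide nitrogen counts), `release` (1 per
#'   peptide per molecule).
#' @export
assemble_qconcat <- function(peptides, tag = "") {
  stopifnot(length(peptides) >= 1L)
  for (p in peptides) validate_sequence(p)
  validate_sequence(tag, allow_empty = TRUE)
  last <- substring(peptides, nchar(peptides), nchar(peptides))
  if (any(!last %in% c("K", "R")))
    stop("every QconCAT peptide must end in K or R for tryptic release",
         call. = FALSE)
  nxt <- c(substring(peptides[-1], 1L, 1L),
           if (nzchar(tag)) substring(tag, 1L, 1L) else "")
  if (any(nxt == "P"))
    stop("a peptide or the tag begins with P: the preceding cleavage is blocked",
         call. = FALSE)
  sequence <- paste0(paste(peptides, collapse = ""), tag)
  released <- digest(sequence, max_missed = 0L)$sequence
  missing <- setdiff(peptides, released)
  if (length(missing))
    stop(sprintf("assembly failed to release: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(
    peptides = peptides, tag = tag, sequence = sequence,
    molar_mass = peptide_mass(sequence, kind = "average"),
    nitrogen = vapply(peptides, nitrogen_count, 0L),
    release = rep(1L, length(peptides))
  ), class = "qconcat_design")
}

#' @export
print.qconcat_design <- function(x, ...) {
  cat(sprintf("<qconcat_design> %d peptides + tag '%s', %d aa, %.1f Da\n",
              length(x$peptides), x$tag, nchar(x$sequence), x$molar_mass))
  invisible(x)
}

#' Convert between mass and molar amounts of a protein
#'
#' `ug_to_pmol()` converts micrograms of a protein of known molar mass
#' to picomoles; `pmol_to_ug()` is the exact inverse. 5.8 ug of a
#' 58.5 kDa concatamer is 99.15 pmol.
#'
#' @param ug Mass amount in micrograms.
#' @param pmol Molar amount in picomoles.
#' @param molar_mass Molar mass in Da (g/mol), positive.
#' @return Numeric amount in the target unit.
#' @export
ug_to_pmol <- function(ug, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  ug / molar_mass * 1e6
}

#' @rdname ug_to_pmol
#' @export
pmol_to_ug <- function(pmol, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  pmol * molar_mass / 1e6
}

#' Correct a light/heavy ratio for incomplete metabolic labelling
#'
#' If a fraction `f` of the heavy standard molecules is actually
#' unlabelled, the observed light signal contains a leakage term `f * S`
#' from the spike and the heavy signal is attenuated to `(1 - f) * S`.
#' On the ratio scale the exact correction is
#' `corrected = (1 - f) * observed - f`, which recovers the true
#' analyte/spike ratio and reduces to the identity at `f = 0` (the
#' default: labelling efficiencies above 99% need no correction).
#'
#' @param measured_ratio Observed light/heavy area ratio.
#' @param unlabeled_fraction Fraction of the heavy standard that is
#'   unlabelled, in `[0, 1)`.
#' @return Corrected ratio. A negative corrected ratio (over-correction
#'   of a weak light signal) is returned as `NA` with a warning, so the
#'   measurement is flagged rather than silently negative.
#' @export
labelling_efficiency_correction <- function(measured_ratio,
                                            unlabeled_fraction = 0) {
  if (unlabeled_fraction < 0 || unlabeled_fraction >= 1)
    stop("unlabeled_fraction must be in [0, 1)", call. = FALSE)
  corrected <- (1 - unlabeled_fraction) * measured_ratio - unlabeled_fraction
  bad <- !is.na(corrected) & corrected < 0
  if (any(bad)) {
    warning("labelling correction drove ", sum(bad),
            " ratio(s) negative; flagged as NA", call. = FALSE)
    corrected[bad] <- NA_real_
  }
  corrected
}

#' Save a QconCAT design as FASTA plus a sidecar peptide table
#'
#' @param design A `qconcat_design`.
#' @param fasta_path Output FASTA path for the full construct sequence.
#' @param table_path Output CSV path for the peptide table (order,
#'   sequence, nitrogen count, light/heavy monoisotopic masses).
#' @param id Record identifier for the FASTA entry.
#' @return The table, invisibly.
#' @export
write_design <- function(design, fasta_path, table_path, id = "QconCAT") {
  write_fasta(stats::setNames(design$sequence, id), fasta_path)
  tab <- data.frame(
    order = seq_along(design$peptides),
    sequence = design$peptides,
    nitrogen = design$nitrogen,
    light_mono = vapply(design$peptides, peptide_mass, 0),
    heavy_mono = vapply(design$peptides, heavy_mass, 0),
    row.names = NULL
  )
  utils::write.csv(tab, table_path, row.names = FALSE)
  invisible(tab)
}
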
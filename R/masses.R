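# Peptide mass bookkeeping: neutral masses for light (14N) and heavy
# (15N metabolically labelled) species, variable modifications, charge
# states, and natural-abundance isotope envelopes.

# Variable modifications used for database searching: oxidation of
# methionine and nitration of tyrosine.
.MODIFICATIONS <- list(
  oxidation = list(target = "M", delta = 15.994915),
  nitro     = list(target = "Y", delta = 44.985078)
)

#' Known variable modifications
#'
#' @return Data frame with columns `name`, `target` (residue letter) and
#'   `delta` (monoisotopic mass shift, Da).
#' @export
modification_table <- function() {
  data.frame(
    name = names(.MODIFICATIONS),
    target = vapply(.MODIFICATIONS, `[[`, "", "target"),
    delta = vapply(.MODIFICATIONS, `[[`, 0, "delta"),
    row.names = NULL
  )
}

.peptide_sequence <- function(peptide) {
  if (inherits(peptide, "peptide")) peptide$sequence else peptide
}

.peptide_mods <- function(peptide) {
  if (inherits(peptide, "peptide")) peptide$modifications else list()
}

#' Construct a peptide object
#'
#' A peptide is a tryptic fragment with optional parent coordinates and
#' a list of site-specific modifications. Most mass functions also accept
#' a bare character sequence.
#'
#' @param sequence Amino-acid sequence.
#' @param parent Parent protein identifier.
#' @param start,end 1-based inclusive coordinates in the parent.
#' @param missed_cleavages Number of internal uncleaved K/R sites.
#' @param modifications List of `list(name =, site =, delta =)` entries.
#' @return An object of class `peptide`.
#' @export
peptide <- function(sequence, parent = NA_character_, start = NA_integer_,
                    end = NA_integer_, missed_cleavages = 0L,
                    modifications = list()) {
  validate_sequence(sequence)
  if (!is.na(start) && !is.na(end) &&
      end - start + 1L != nchar(sequence))
    stop("start/end span does not match sequence length", call. = FALSE)
  structure(list(sequence = sequence, parent = parent, start = start,
                 end = end, missed_cleavages = missed_cleavages,
                 modifications = modifications),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  mods <- if (length(x$modifications))
    paste0(" +", vapply(x$modifications, function(m)
      paste0(m$name, "@", m$site), "")) else ""
  cat(sprintf("<peptide> %s%s (parent %s, %s-%s, %d missed)\n",
              x$sequence, paste(mods, collapse = ""), x$parent,
              x$start, x$end, x$missed_cleavages))
  invisible(x)
}

#' Apply a variable modification to a peptide
#'
#' @param pep A `peptide` object or character sequence.
#' @param mod_name One of the names in [modification_table()].
#' @param site 1-based position within the peptide; must carry the
#'   modification's target residue.
#' @return A `peptide` with the modification recorded; its mass as
#'   computed by [peptide_mass()] includes the delta.
#' @export
apply_modification <- function(pep, mod_name, site) {
  if (!mod_name %in% names(.MODIFICATIONS))
    stop(sprintf("unknown modification '%s'", mod_name), call. = FALSE)
  if (is.character(pep)) pep <- peptide(pep)
  mod <- .MODIFICATIONS[[mod_name]]
  seq <- pep$sequence
  if (site < 1 || site > nchar(seq))
    stop("modification site outside peptide", call. = FALSE)
  res <- substring(seq, site, site)
  if (res != mod$target)
    stop(sprintf("modification '%s' targets %s but position %d is %s",
                 mod_name, mod$target, site, res), call. = FALSE)
  pep$modifications <- c(pep$modifications,
                         list(list(name = mod_name, site = site,
                                   delta = mod$delta)))
  pep
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, plus any modification deltas.
#' The empty sequence gives the mass of water.
#'
#' @param pep A `peptide` object or character sequence (may be `""`).
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("LLQALR")  # 712.4595
#' @export
peptide_mass <- function(pep, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  seq <- .peptide_sequence(pep)
  validate_sequence(seq, allow_empty = TRUE)
  water <- if (kind == "monoisotopic") WATER_MONO else WATER_AVG
  m <- water
  if (nzchar(seq)) {
    tab <- .residue_masses(kind)
    m <- m + sum(tab[strsplit(seq, "", fixed = TRUE)[[1]]])
  }
  m + sum(vapply(.peptide_mods(pep), `[[`, 0, "delta"))
}

#' Nitrogen atoms in a peptide
#'
#' Backbone plus side-chain nitrogens, summed over residues. This is the
#' number of mass units of [N15_SHIFT] a fully 15N-labelled peptide
#' gains over its light form.
#'
#' @inheritParams peptide_mass
#' @return Integer nitrogen count.
#' @examples
#' nitrogen_count("LLQALR")  # 10
#' @export
nitrogen_count <- function(pep) {
  seq <- .peptide_sequence(pep)
  validate_sequence(seq, allow_empty = TRUE)
  if (!nzchar(seq)) return(0L)
  tab <- .residue_nitrogens()
  as.integer(sum(tab[strsplit(seq, "", fixed = TRUE)[[1]]]))
}

#' Heavy (15N) peptide mass
#'
#' Neutral mass of the fully 15N metabolically labelled peptide: the
#' light mass plus [N15_SHIFT] per nitrogen atom. The same per-atom
#' shift is used for average masses, which is accurate well below the
#' 0.3 Da tolerances used throughout.
#'
#' @inheritParams peptide_mass
#' @return Neutral heavy mass in Da.
#' @export
heavy_mass <- function(pep, kind = c("monoisotopic", "average")) {
  peptide_mass(pep, kind) + nitrogen_count(pep) * N15_SHIFT
}

#' m/z of a charged species
#'
#' @param neutral_mass Neutral mass M in Da.
#' @param charge Positive integer charge z.
#' @return `(M + z * PROTON_MASS) / z` in Thomson.
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Describe a peptide in a label state and charge
#'
#' @inheritParams peptide_mass
#' @param label `"light"` (14N) or `"heavy"` (15N).
#' @param charge Positive integer charge.
#' @return A one-row data frame: `sequence`, `label`, `charge`, `kind`,
#'   `neutral_mass`, `mz`, `nitrogen`.
#' @export
labeled_species <- function(pep, label = c("light", "heavy"), charge = 1L,
                            kind = c("monoisotopic", "average")) {
  label <- match.arg(label)
  kind <- match.arg(kind)
  m <- if (label == "light") peptide_mass(pep, kind) else heavy_mass(pep, kind)
  data.frame(sequence = .peptide_sequence(pep), label = label,
             charge = as.integer(charge), kind = kind, neutral_mass = m,
             mz = mz(m, charge), nitrogen = nitrogen_count(pep))
}

# --- isotope envelopes -----------------------------------------------------

# Per-atom extra-neutron distributions (natural abundance), as vectors of
# probabilities over +0, +1, +2 neutrons.
.ISOTOPE_DIST <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99632, 0.00368),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9493, 0.0076, 0.0429)
)

# Convolve a distribution with itself n times, truncating at `keep` terms.
.conv_pow <- function(p, n, keep) {
  out <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) {
      out <- stats::convolve(out, rev(base), type = "open")
      out <- out[seq_len(min(length(out), keep))]
    }
    base <- stats::convolve(base, rev(base), type = "open")
    base <- base[seq_len(min(length(base), keep))]
    n <- n %/% 2
  }
  length(out) <- keep
  out[is.na(out)] <- 0
  out
}

#' Natural-abundance isotope envelope of a peptide
#'
#' Relative abundances of the first isotopologues (monoisotopic peak
#' first), computed by convolving per-element isotope distributions over
#' the peptide's elemental composition. For heavy (15N) species the
#' nitrogen atoms are fixed at 15N and contribute no envelope spread;
#' their mass shift is carried by [heavy_mass()] instead.
#'
#' @inheritParams peptide_mass
#' @param label `"light"` or `"heavy"`.
#' @param n_isotopologues Number of envelope peaks returned (default 5).
#' @return Numeric vector of abundances; sums to slightly under 1 due to
#'   truncation.
#' @export
isotope_envelope <- function(pep, label = c("light", "heavy"),
                             n_isotopologues = 5L) {
  label <- match.arg(label)
  seq <- .peptide_sequence(pep)
  validate_sequence(seq)
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- colSums(.RESIDUE_COMPOSITION[letters, , drop = FALSE])
  comp["H"] <- comp["H"] + 2  # water
  comp["O"] <- comp["O"] + 1
  if (label == "heavy") comp["N"] <- 0  # all nitrogens fixed at 15N
  env <- 1
  for (el in names(.ISOTOPE_DIST)) {
    if (comp[[el]] > 0) {
      pel <- .conv_pow(.ISOTOPE_DIST[[el]], comp[[el]], n_isotopologues)
      env <- stats::convolve(env, rev(pel), type = "open")
      env <- env[seq_len(min(length(env), n_isotopologues))]
    }
  }
  length(env) <- n_isotopologues
  env[is.na(env)] <- 0
  env
}

# Spacing between adjacent isotopologue peaks (13C-12C), Da.
.ISOTOPE_SPACING <- 1.0033548

#' m/z positions of a species' isotope envelope
#'
#' @inheritParams isotope_envelope
#' @param charge Positive integer charge.
#' @return Data frame with columns `mz` and `abundance`.
#' @export
envelope_mz <- function(pep, label = c("light", "heavy"), charge = 1L,
                        n_isotopologues = 5L) {
  label <- match.arg(label)
  m0 <- if (label == "light") peptide_mass(pep) else heavy_mass(pep)
  k <- seq_len(n_isotopologues) - 1
  data.frame(mz = mz(m0 + k * .ISOTOPE_SPACING, charge),
             abundance = isotope_envelope(pep, label, n_isotopologues))
}
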
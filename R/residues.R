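# Residue-level chemistry: elemental compositions, monoisotopic/average
# masses, nitrogen counts, and the fixed mass constants the whole package
# shares. Masses are derived from the elemental composition of each residue
# (amino acid minus water) so that isotope-envelope computations and mass
# sums can never disagree.

# Monoisotopic masses of the light isotope of each element (Da).
.ELEMENT_MONO <- c(C = 12.0000000, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)

# Standard atomic weights (Da).
.ELEMENT_AVG <- c(C = 12.0107, H = 1.00794, N = 14.0067,
                  O = 15.9994, S = 32.065)

#' @rdname mass_constants
#' @export
PROTON_MASS <- 1.007276

#' Mass constants
#'
#' Fixed constants used throughout: the proton mass added per charge,
#' the mass of water added to a residue chain to form a peptide, and the
#' mass difference between 15N and 14N that a fully metabolically
#' labelled peptide gains per nitrogen atom.
#'
#' @name mass_constants
#' @export
WATER_MONO <- 18.010565

# Average-mass water, from standard atomic weights.
#' @rdname mass_constants
#' @export
WATER_AVG <- 2 * .ELEMENT_AVG[["H"]] + .ELEMENT_AVG[["O"]]

#' @rdname mass_constants
#' @export
N15_SHIFT <- 0.997035

# Elemental composition of each residue (amino acid minus water), as
# C, H, N, O, S atom counts. Rows are the 20 standard one-letter codes.
.RESIDUE_COMPOSITION <- rbind(
  G = c(2,  3, 1, 1, 0),
  A = c(3,  5, 1, 1, 0),
  S = c(3,  5, 1, 2, 0),
  P = c(5,  7, 1, 1, 0),
  V = c(5,  9, 1, 1, 0),
  T = c(4,  7, 1, 2, 0),
  C = c(3,  5, 1, 1, 1),
  L = c(6, 11, 1, 1, 0),
  I = c(6, 11, 1, 1, 0),
  N = c(4,  6, 2, 2, 0),
  D = c(4,  5, 1, 3, 0),
  Q = c(5,  8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0),
  E = c(5,  7, 1, 3, 0),
  M = c(5,  9, 1, 1, 1),
  H = c(6,  7, 3, 1, 0),
  F = c(9,  9, 1, 1, 0),
  R = c(6, 12, 4, 1, 0),
  Y = c(9,  9, 1, 2, 0),
  W = c(11, 10, 2, 1, 0)
)
colnames(.RESIDUE_COMPOSITION) <- c("C", "H", "N", "O", "S")

#' Residue mass and composition table
#'
#' Per-residue monoisotopic mass, average mass, nitrogen count and full
#' elemental composition for the 20 standard amino acids. Residue masses
#' are the amino-acid masses minus one water; a peptide's neutral mass is
#' the sum of its residue masses plus [WATER_MONO] (or [WATER_AVG]).
#'
#' @return A data frame with one row per one-letter residue code and
#'   columns `residue`, `mono`, `average`, `nitrogen`, `C`, `H`, `N`,
#'   `O`, `S`.
#' @examples
#' residue_table()["R", "nitrogen"]  # arginine carries 4 nitrogens
#' @export
residue_table <- function() {
  comp <- .RESIDUE_COMPOSITION
  data.frame(
    residue  = rownames(comp),
    mono     = as.numeric(comp %*% .ELEMENT_MONO[colnames(comp)]),
    average  = as.numeric(comp %*% .ELEMENT_AVG[colnames(comp)]),
    nitrogen = comp[, "N"],
    comp,
    row.names = rownames(comp)
  )
}

# Cached numeric lookup vectors, built once at load.
.residue_env <- new.env(parent = emptyenv())

.residue_masses <- function(kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  key <- paste0("mass_", kind)
  if (is.null(.residue_env[[key]])) {
    tab <- residue_table()
    .residue_env[[key]] <- stats::setNames(
      if (kind == "monoisotopic") tab$mono else tab$average, tab$residue)
  }
  .residue_env[[key]]
}

.residue_nitrogens <- function() {
  stats::setNames(.RESIDUE_COMPOSITION[, "N"],
                  rownames(.RESIDUE_COMPOSITION))
}

#' Validate a peptide or protein sequence
#'
#' Checks that a sequence is a non-empty string over the 20 standard
#' one-letter amino-acid codes. Ambiguity codes (B, Z, X) and
#' non-standard residues (U, O) are rejected: guessing a mass for them
#' would corrupt every downstream quantity silently.
#'
#' @param sequence Character scalar, amino-acid sequence (upper case).
#' @param allow_empty Accept the empty string (used by mass functions,
#'   where it denotes a bare water molecule).
#' @return The sequence, invisibly, after validation.
#' @export
validate_sequence <- function(sequence, allow_empty = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string", call. = FALSE)
  if (nzchar(sequence)) {
    letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
    bad <- which(!letters %in% rownames(.RESIDUE_COMPOSITION))
    if (length(bad))
      stop(sprintf("invalid residue '%s' at position %d", letters[bad[1]],
                   bad[1]), call. = FALSE)
  } else if (!allow_empty) {
    stop("sequence must be non-empty", call. = FALSE)
  }
  invisible(sequence)
}
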
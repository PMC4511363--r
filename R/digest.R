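# In-silico tryptic digestion. Trypsin cleaves C-terminal to K or R
# unless the next residue is proline (the K.P / R.P rule); peptides with
# up to `max_missed` internal uncleaved sites are enumerated.

#' Tryptic cleavage sites of a sequence
#'
#' Positions after which trypsin cuts: every K or R not followed by P.
#'
#' @param sequence Protein sequence (standard one-letter codes).
#' @return Integer vector of cut positions (cut is after the position).
#' @export
cleavage_sites <- function(sequence) {
  validate_sequence(sequence)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(letters)
  if (n < 2L) return(integer(0))
  idx <- which(letters[-n] %in% c("K", "R"))
  idx[letters[idx + 1L] != "P"]
}

#' In-silico trypsin digestion
#'
#' Digests a protein sequence with trypsin rules (cleave after K/R, not
#' before P), enumerating all peptides with 0 to `max_missed` internal
#' missed-cleavage sites. The zero-missed-cleavage peptides tile the
#' parent exactly.
#'
#' @param sequence Parent protein sequence.
#' @param max_missed Maximum number of internal missed cleavages
#'   (default 1, the setting used for database searching).
#' @param parent Identifier recorded with each peptide.
#' @return A data frame with columns `sequence`, `parent`, `start`,
#'   `end` (1-based inclusive coordinates in the parent) and
#'   `missed_cleavages`, ordered by start position then missed count.
#' @examples
#' digest("AKPRGR", max_missed = 0)  # K.P blocked: AKPR, GR
#' @export
digest <- function(sequence, max_missed = 1L, parent = NA_character_) {
  validate_sequence(sequence)
  if (max_missed < 0) stop("max_missed must be >= 0", call. = FALSE)
  cuts <- cleavage_sites(sequence)
  bounds <- c(0L, cuts, nchar(sequence))       # fragment boundaries
  nfrag <- length(bounds) - 1L
  rows <- vector("list", nfrag * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      k <- k + 1L
      rows[[k]] <- c(start = bounds[i] + 1L, end = bounds[j + 1L], missed = m)
    }
  }
  rows <- do.call(rbind, rows[seq_len(k)])
  out <- data.frame(
    sequence = substring(sequence, rows[, "start"], rows[, "end"]),
    parent = parent,
    start = rows[, "start"],
    end = rows[, "end"],
    missed_cleavages = rows[, "missed"],
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$missed_cleavages), , drop = FALSE]
}
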
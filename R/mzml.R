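# mzML serialization for spectrum runs, via mzR (optional dependency).

#' Write a spectrum run to mzML
#'
#' Serializes a [spectrum_run()] as centroided MS1 spectra. Requires the
#' mzR package.
#'
#' @param run A [spectrum_run()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("the mzR package is required for mzML output", call. = FALSE)
  scans <- run$scans
  n <- length(scans)
  peaks <- lapply(scans, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  npk <- vapply(peaks, nrow, 0L)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(scans, function(s) sum(s$intensity), 0),
    retentionTime = vapply(scans, `[[`, 0, "rt") * 60,  # seconds
    basePeakMZ = vapply(scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0),
    basePeakIntensity = vapply(scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(scans, function(s)
      if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(scans, function(s)
      if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(peaks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a centroided mzML file into a spectrum run
#'
#' Reads MS1 spectra via mzR into the in-memory run container used by
#' [extract_xic()].
#'
#' @param path Path to an mzML file.
#' @return A [spectrum_run()].
#' @export
read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("the mzR package is required for mzML input", call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  ms1 <- which(hdr$msLevel == 1L)
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(h, i)
    list(rt = hdr$retentionTime[i] / 60, mz = pk[, 1], intensity = pk[, 2])
  })
  ord <- order(vapply(scans, `[[`, 0, "rt"))
  spectrum_run(scans[ord], metadata = list(source = path))
}
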
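# Quantification: extracted ion chromatograms from an LC-MS run, peak
# integration with a local linear baseline, light/heavy ratio
# quantification against the spiked heavy standard, and serum
# concentration back-calculation through the sample-volume ledger.

#' Construct an in-memory LC-MS run
#'
#' A run is an ordered list of centroided scans, each with a retention
#' time (minutes) and paired m/z / intensity vectors.
#'
#' @param scans List of `list(rt =, mz =, intensity =)` entries with
#'   strictly increasing retention times.
#' @param metadata Optional named list (gradient length, polarity, ...).
#' @return A `spectrum_run` object.
#' @export
spectrum_run <- function(scans, metadata = list()) {
  rts <- vapply(scans, `[[`, 0, "rt")
  if (length(rts) > 1 && any(diff(rts) <= 0))
    stop("scan retention times must be strictly increasing", call. = FALSE)
  for (s in scans)
    if (length(s$mz) != length(s$intensity))
      stop("mz and intensity arrays must have equal length", call. = FALSE)
  structure(list(scans = scans, metadata = metadata), class = "spectrum_run")
}

#' @export
print.spectrum_run <- function(x, ...) {
  rts <- vapply(x$scans, `[[`, 0, "rt")
  cat(sprintf("<spectrum_run> %d scans, RT %.2f-%.2f min\n",
              length(x$scans), min(rts), max(rts)))
  invisible(x)
}

#' An XIC extraction request
#'
#' @param mz Target m/z (Th).
#' @param rt Expected retention-time centre (minutes).
#' @param mz_width Full width of the m/z window (Th); the default 0.3
#'   means +/- 0.15 around the target.
#' @param rt_width Full width of the chromatographic window (minutes),
#'   default 4.
#' @return An `xic_request` list.
#' @export
xic_request <- function(mz, rt, mz_width = 0.3, rt_width = 4) {
  stopifnot(mz_width > 0, rt_width > 0)
  structure(list(mz = mz, rt = rt, mz_width = mz_width, rt_width = rt_width),
            class = "xic_request")
}

#' Extract an ion chromatogram
#'
#' For every scan whose retention time falls inside the request's RT
#' window, sums the intensities of centroids with
#' `|m/z - target| <= mz_width / 2`.
#'
#' @param run A [spectrum_run()].
#' @param request An [xic_request()].
#' @return A data frame with columns `rt` and `intensity` (the XIC
#'   trace); zero rows if no scan falls in the window.
#' @export
extract_xic <- function(run, request) {
  rts <- vapply(run$scans, `[[`, 0, "rt")
  lo <- request$rt - request$rt_width / 2
  hi <- request$rt + request$rt_width / 2
  keep <- which(rts >= lo & rts <= hi)
  half <- request$mz_width / 2
  intensity <- vapply(run$scans[keep], function(s) {
    sel <- abs(s$mz - request$mz) <= half
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, 0)
  data.frame(rt = rts[keep], intensity = intensity)
}

#' Integrate a chromatographic peak
#'
#' Locates the apex (global maximum; earliest RT on ties), extends the
#' integration bounds outward from the apex until the intensity falls to
#' or below the local baseline level, subtracts a linear baseline drawn
#' between the bound endpoints, and integrates by the trapezoidal rule
#' over retention time. The baseline level is the trace median; a peak
#' whose apex does not rise above the baseline by more than
#' `snr * mad(trace)` is flagged `no-peak` with area zero.
#'
#' @param trace A data frame with `rt` and `intensity` (from
#'   [extract_xic()]).
#' @param snr Signal-to-noise multiple of the trace's median absolute
#'   deviation required for a peak call (default 3).
#' @return A `peak_area` list: `apex_rt`, `bounds` (RT pair), `raw_area`,
#'   `area` (baseline-corrected, >= 0), `flag` (`"ok"`, `"no-peak"` or
#'   `"edge-clipped"`).
#' @export
integrate_peak <- function(trace, snr = 3) {
  empty <- structure(list(apex_rt = NA_real_, bounds = c(NA_real_, NA_real_),
                          raw_area = 0, area = 0, flag = "no-peak"),
                     class = "peak_area")
  if (nrow(trace) < 3L) return(empty)
  y <- trace$intensity
  x <- trace$rt
  base_level <- stats::median(y)
  noise <- stats::mad(y)
  i_apex <- which.max(y)           # earliest on ties
  if (y[i_apex] - base_level <= snr * noise || y[i_apex] <= 0) return(empty)
  lo <- i_apex
  while (lo > 1L && y[lo - 1L] > base_level) lo <- lo - 1L
  hi <- i_apex
  n <- length(y)
  while (hi < n && y[hi + 1L] > base_level) hi <- hi + 1L
  flag <- if (lo == 1L || hi == n) "edge-clipped" else "ok"
  xs <- x[lo:hi]
  ys <- y[lo:hi]
  raw <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  baseline <- ys[1] + (ys[length(ys)] - ys[1]) *
    (xs - xs[1]) / (xs[length(xs)] - xs[1])
  yc <- pmax(ys - baseline, 0)
  corrected <- sum(diff(xs) * (utils::head(yc, -1) + utils::tail(yc, -1)) / 2)
  structure(list(apex_rt = x[i_apex], bounds = c(xs[1], xs[length(xs)]),
                 raw_area = raw, area = corrected, flag = flag),
            class = "peak_area")
}

#' Analyte amount from a light/heavy area ratio
#'
#' Isotope dilution: the analyte amount equals the spiked heavy amount
#' times the light/heavy area ratio. Optionally corrects for incomplete
#' metabolic labelling via [labelling_efficiency_correction()] (the
#' default, 0, applies no correction).
#'
#' @param light_area,heavy_area Integrated peak areas.
#' @param spike_fmol Amount of heavy standard spiked (fmol), default 50.
#' @param unlabeled_fraction Fraction of the heavy standard that is
#'   unlabelled.
#' @return Analyte amount in fmol. `NA` with a warning if the heavy
#'   standard gave no signal (quantification failure, reported rather
#'   than dropped).
#' @export
quantify_ratio <- function(light_area, heavy_area, spike_fmol = 50,
                           unlabeled_fraction = 0) {
  if (spike_fmol <= 0) stop("spike_fmol must be positive", call. = FALSE)
  if (is.na(heavy_area) || heavy_area <= 0) {
    warning("heavy standard gave no peak; quantification failed",
            call. = FALSE)
    return(NA_real_)
  }
  ratio <- labelling_efficiency_correction(light_area / heavy_area,
                                           unlabeled_fraction)
  spike_fmol * (1 - unlabeled_fraction) * ratio
}

#' Sample-volume ledger
#'
#' Records the serum volume a measurement traces back to and the
#' fraction of serum-derived material that reached the analysed sample
#' at each preparation step. The defaults (0.1 ml serum, all fractions
#' 1) mean the analysed sample represents the whole serum aliquot.
#'
#' @param serum_ml Serum volume in millilitres (default 0.1).
#' @param fractions Numeric vector of aliquot fractions in `(0, 1]`.
#' @return A `volume_ledger` list.
#' @export
volume_ledger <- function(serum_ml = 0.1, fractions = 1) {
  stopifnot(serum_ml > 0, all(fractions > 0 & fractions <= 1))
  structure(list(serum_ml = serum_ml, fractions = fractions),
            class = "volume_ledger")
}

#' Serum concentration from a measured amount
#'
#' @param analyte_fmol Measured analyte amount in fmol.
#' @param ledger A [volume_ledger()].
#' @return Concentration in fmol/ml:
#'   `fmol / (serum_ml * prod(fractions))`.
#' @examples
#' serum_concentration(2.723, volume_ledger(0.1))  # 27.23 fmol/ml
#' @export
serum_concentration <- function(analyte_fmol, ledger = volume_ledger()) {
  analyte_fmol / (ledger$serum_ml * prod(ledger$fractions))
}

#' Convert between mass and molar serum concentrations
#'
#' @param ng_per_ml Concentration in ng/ml.
#' @param fmol_per_ml Concentration in fmol/ml.
#' @param molar_mass Molar mass in Da, positive.
#' @return The converted concentration.
#' @examples
#' mass_to_molar(0.56, 33000)  # about 17 fmol/ml
#' @export
mass_to_molar <- function(ng_per_ml, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  ng_per_ml / molar_mass * 1e6
}

#' @rdname mass_to_molar
#' @export
molar_to_mass <- function(fmol_per_ml, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  fmol_per_ml * molar_mass / 1e6
}

#' Quantify one peptide species pair (light analyte vs heavy standard)
#'
#' Extracts ion chromatograms for the light and heavy forms of a
#' fingerprint peptide at the given charge, integrates both peaks, and
#' converts the light/heavy area ratio into an analyte amount and serum
#' concentration. The chromatographic window is centred on the heavy
#' standard's apex by default (the standard is always present and
#' co-elutes with the analyte); XICs are summed over the first
#' `n_isotopologues` isotope-envelope peaks of each species so the
#' light/heavy ratio is not biased by the differing envelope shapes of
#' labelled and unlabelled forms.
#'
#' @param run A [spectrum_run()].
#' @param sequence Fingerprint peptide sequence.
#' @param charge Charge state to extract.
#' @param expected_rt Expected retention time (minutes) used to locate
#'   the heavy standard.
#' @param spike_fmol Heavy spike amount (fmol), default 50.
#' @param ledger A [volume_ledger()].
#' @param mz_width,rt_width XIC window widths (Th full width, minutes
#'   full width).
#' @param n_isotopologues Envelope peaks summed per species (default 5).
#' @param unlabeled_fraction Heavy-standard unlabelled fraction.
#' @param snr Peak-call threshold for [integrate_peak()].
#' @return A one-row [tibble::tibble()]: sequence, charge, light/heavy
#'   areas and flags, ratio, `analyte_fmol`, `conc_fmol_ml`.
#' @export
quantify_species <- function(run, sequence, charge, expected_rt,
                             spike_fmol = 50, ledger = volume_ledger(),
                             mz_width = 0.3, rt_width = 4,
                             n_isotopologues = 5L, unlabeled_fraction = 0,
                             snr = 3) {
  sum_trace <- function(label, rt_centre) {
    env <- envelope_mz(sequence, label, charge, n_isotopologues)
    trace <- NULL
    for (mzk in env$mz) {
      t1 <- extract_xic(run, xic_request(mzk, rt_centre, mz_width, rt_width))
      trace <- if (is.null(trace)) t1
        else data.frame(rt = trace$rt, intensity = trace$intensity + t1$intensity)
    }
    trace
  }
  # locate the heavy standard near the expected RT, then centre both
  # windows on its apex
  heavy_scout <- integrate_peak(sum_trace("heavy", expected_rt), snr = snr)
  centre <- if (is.na(heavy_scout$apex_rt)) expected_rt else heavy_scout$apex_rt
  heavy <- integrate_peak(sum_trace("heavy", centre), snr = snr)
  light <- integrate_peak(sum_trace("light", centre), snr = snr)
  fmol <- if (heavy$flag == "no-peak") {
    warning(sprintf("heavy standard for %s +%d gave no peak", sequence,
                    charge), call. = FALSE)
    NA_real_
  } else if (light$flag == "no-peak") {
    0
  } else {
    quantify_ratio(light$area, heavy$area, spike_fmol, unlabeled_fraction)
  }
  tibble::tibble(
    sequence = sequence, charge = as.integer(charge),
    light_area = light$area, light_flag = light$flag,
    heavy_area = heavy$area, heavy_flag = heavy$flag,
    ratio = ifelse(heavy$area > 0, light$area / heavy$area, NA_real_),
    spike_fmol = spike_fmol,
    analyte_fmol = fmol,
    conc_fmol_ml = serum_concentration(fmol, ledger)
  )
}
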
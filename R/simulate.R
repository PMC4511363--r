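# Synthetic LC-MS run generator: paired light/heavy fingerprint peptide
# peaks with isotope envelopes, Gaussian elution profiles whose
# integrated intensity is proportional to amount, and multiplicative
# log-normal noise. Stands in for the instrument so the whole
# quantification pipeline is testable at desk scale.

#' Specify a simulated LC-MS run
#'
#' @param species Data frame with one row per species and columns
#'   `sequence`, `label` (`"light"`/`"heavy"`), `charge`, `amount_fmol`,
#'   `rt` (elution apex, minutes) and optionally `peak_sd` (minutes;
#'   default 0.1).
#' @param response Detector response factor: integrated intensity
#'   (intensity x minutes) per fmol; default 1e4.
#' @param noise_cv Multiplicative noise coefficient of variation per
#'   scan (default 0 = noiseless).
#' @param additive_floor Intensity below which centroids are dropped
#'   (default 1e-6).
#' @param scan_interval Time between scans, minutes (default 0.02).
#' @param rt_range Run start/end retention times (minutes); defaults to
#'   covering every species apex plus 2.5 minutes either side.
#' @param seed Random seed; mandatory so runs are reproducible.
#' @param n_isotopologues Isotope-envelope peaks simulated per species.
#' @return A `run_spec` list.
#' @export
run_spec <- function(species, response = 1e4, noise_cv = 0,
                     additive_floor = 1e-6, scan_interval = 0.02,
                     rt_range = NULL, seed, n_isotopologues = 5L) {
  stopifnot(is.data.frame(species),
            all(c("sequence", "label", "charge", "amount_fmol", "rt")
                %in% names(species)))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(species$peak_sd)) species$peak_sd <- 0.1
  stopifnot(all(species$amount_fmol >= 0), all(species$peak_sd > 0))
  if (is.null(rt_range))
    rt_range <- c(max(0, min(species$rt) - 2.5), max(species$rt) + 2.5)
  structure(list(species = species, response = response,
                 noise_cv = noise_cv, additive_floor = additive_floor,
                 scan_interval = scan_interval, rt_range = rt_range,
                 seed = as.integer(seed),
                 n_isotopologues = n_isotopologues),
            class = "run_spec")
}

#' Simulate an LC-MS run
#'
#' Each species elutes as a Gaussian profile centred at its retention
#' time; its intensity density integrates to `amount_fmol * response`,
#' distributed over its isotope-envelope m/z positions (natural
#' abundances for the light form; the heavy form's envelope omits the
#' nitrogen contribution and is shifted by the 15N count). Multiplicative
#' log-normal noise with the specified CV is applied per scan and
#' species. Centroids falling on the same m/z are summed. Deterministic
#' for a fixed seed.
#'
#' @param spec A [run_spec()].
#' @return A [spectrum_run()] whose metadata records the spec's seed,
#'   response factor and noise CV.
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "run_spec"))
  sp <- spec$species
  rts <- seq(spec$rt_range[1], spec$rt_range[2], by = spec$scan_interval)
  envs <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp)))
    envs[[i]] <- envelope_mz(sp$sequence[i], sp$label[i], sp$charge[i],
                             spec$n_isotopologues)
  # one multiplicative factor per scan x species, drawn up-front so the
  # run is byte-identical for a fixed seed
  set.seed(spec$seed)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    noise <- matrix(stats::rlnorm(length(rts) * nrow(sp),
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = length(rts))
  } else {
    noise <- matrix(1, nrow = length(rts), ncol = nrow(sp))
  }
  scans <- vector("list", length(rts))
  for (k in seq_along(rts)) {
    mzv <- numeric(0)
    inv <- numeric(0)
    for (i in seq_len(nrow(sp))) {
      dens <- sp$amount_fmol[i] * spec$response *
        stats::dnorm(rts[k], sp$rt[i], sp$peak_sd[i]) * noise[k, i]
      if (dens <= spec$additive_floor) next
      mzv <- c(mzv, envs[[i]]$mz)
      inv <- c(inv, dens * envs[[i]]$abundance)
    }
    if (length(mzv)) {
      agg <- rowsum(inv, group = mzv)        # sum exact m/z collisions
      mzo <- as.numeric(rownames(agg))
      ord <- order(mzo)
      keep <- agg[ord, 1] > spec$additive_floor
      scans[[k]] <- list(rt = rts[k], mz = mzo[ord][keep],
                         intensity = agg[ord, 1][keep])
    } else {
      scans[[k]] <- list(rt = rts[k], mz = numeric(0),
                         intensity = numeric(0))
    }
  }
  spectrum_run(scans, metadata = list(seed = spec$seed,
                                      response = spec$response,
                                      noise_cv = spec$noise_cv))
}

#' Simulate a spike-in calibration series
#'
#' One run per spike level: a fixed endogenous (light) amount of the
#' fingerprint peptide plus the level's heavy amount, mirroring the
#' sensitivity/linearity experiment in which a serum fraction is
#' supplemented with increasing amounts of digested heavy standard.
#'
#' @param endogenous_fmol Fixed light amount per run (default 50).
#' @param levels Heavy spike levels in fmol, ascending
#'   (default `c(10, 30, 100, 300)`).
#' @param cv Multiplicative noise CV (default 0.03).
#' @param seed Base seed; run `i` uses `seed + i`.
#' @param sequence Fingerprint peptide (default `"LLQALR"`).
#' @param charge Charge state (default 2).
#' @param rt Elution apex, minutes (default 10).
#' @param response,scan_interval Passed to [run_spec()].
#' @return A list with `levels` and `runs` (one [spectrum_run()] per
#'   level).
#' @export
simulate_spike_series <- function(endogenous_fmol = 50,
                                  levels = c(10, 30, 100, 300),
                                  cv = 0.03, seed,
                                  sequence = "LLQALR", charge = 2L,
                                  rt = 10, response = 1e4,
                                  scan_interval = 0.02) {
  stopifnot(all(diff(levels) > 0), all(levels > 0))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  runs <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    sp <- data.frame(sequence = sequence, label = c("light", "heavy"),
                     charge = charge,
                     amount_fmol = c(endogenous_fmol, levels[i]),
                     rt = rt)
    runs[[i]] <- simulate_run(run_spec(sp, response = response,
                                       noise_cv = cv,
                                       scan_interval = scan_interval,
                                       seed = seed + i))
  }
  list(levels = levels, runs = runs, sequence = sequence, charge = charge,
       rt = rt, endogenous_fmol = endogenous_fmol)
}

#' Cohort specification for the serum simulator
#'
#' Group means and SDs default to the measured serum concentrations of
#' the two markers: DcR3 27.23 fmol/ml in healthy serum (SD 9.47 across
#' individual measurements) versus 116.94 +/- 57.37 fmol/ml in tumour
#' patients, and GDF15 98.11 +/- 34.96 versus 164.44 +/- 79.31 fmol/ml.
#'
#' @param analytes Data frame with columns `analyte`, `sequence`,
#'   `charge`, `rt`, `healthy_mean`, `healthy_sd`, `tumour_mean`,
#'   `tumour_sd` (concentrations in fmol/ml).
#' @param n_healthy,n_tumour Samples per group.
#' @param cv Multiplicative noise CV per run.
#' @param spike_fmol Heavy spike per sample (default 50).
#' @param ledger A [volume_ledger()].
#' @param seed Base seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(analytes = default_cohort_analytes(),
                        n_healthy = 3L, n_tumour = 16L, cv = 0.05,
                        spike_fmol = 50, ledger = volume_ledger(), seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(all(analytes$healthy_mean > 0), all(analytes$tumour_mean > 0),
            all(analytes$healthy_sd >= 0), all(analytes$tumour_sd >= 0))
  structure(list(analytes = analytes, n_healthy = n_healthy,
                 n_tumour = n_tumour, cv = cv, spike_fmol = spike_fmol,
                 ledger = ledger, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort analyte table
#'
#' Two serum markers with distinct fingerprint peptides and retention
#' times, using the measured healthy/tumour concentration structure.
#'
#' @return Data frame usable as the `analytes` argument of
#'   [cohort_spec()].
#' @export
default_cohort_analytes <- function() {
  data.frame(
    analyte = c("DcR3", "GDF15"),
    sequence = c("LLQALR", "TDTGVSLQTYDDLLAK"),
    charge = c(2L, 2L),
    rt = c(10, 16),
    healthy_mean = c(27.23, 98.11),
    healthy_sd = c(9.47, 34.96),
    tumour_mean = c(116.94, 164.44),
    tumour_sd = c(57.37, 79.31)
  )
}

# Truncated-at-zero normal draws.
.rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0))
    out[out <= 0] <- stats::rnorm(sum(out <= 0), mean, sd)
  out
}

#' Simulate a serum cohort with per-sample LC-MS runs
#'
#' Draws true concentrations per sample and analyte from truncated
#' normal distributions with the group parameters, converts each to the
#' light amount reaching the analysed sample through the volume ledger,
#' and simulates one run per sample containing every analyte's
#' light/heavy pair. Quantifying the runs through the standard pipeline
#' recovers the generated concentrations.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `samples` (tibble: `sample_id`, `group`,
#'   `analyte`, `true_conc` in fmol/ml) and `runs` (one
#'   [spectrum_run()] per sample, named by sample id).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  an <- spec$analytes
  groups <- c(rep("healthy", spec$n_healthy), rep("tumour", spec$n_tumour))
  ids <- sprintf("%s_%02d", ifelse(groups == "healthy", "S", "T"),
                 c(seq_len(spec$n_healthy), seq_len(spec$n_tumour)))
  set.seed(spec$seed)
  rows <- list()
  for (j in seq_len(nrow(an))) {
    mu <- ifelse(groups == "healthy", an$healthy_mean[j], an$tumour_mean[j])
    sdv <- ifelse(groups == "healthy", an$healthy_sd[j], an$tumour_sd[j])
    conc <- .rtruncnorm_pos(length(groups), mu, sdv)
    rows[[j]] <- tibble::tibble(sample_id = ids, group = groups,
                                analyte = an$analyte[j], true_conc = conc)
  }
  samples <- do.call(rbind, rows)
  scale <- spec$ledger$serum_ml * prod(spec$ledger$fractions)
  runs <- vector("list", length(ids))
  names(runs) <- ids
  for (i in seq_along(ids)) {
    light <- samples$true_conc[samples$sample_id == ids[i]] * scale
    sp <- data.frame(
      sequence = rep(an$sequence, each = 2),
      label = rep(c("light", "heavy"), nrow(an)),
      charge = rep(an$charge, each = 2),
      amount_fmol = as.vector(rbind(light, spec$spike_fmol)),
      rt = rep(an$rt, each = 2)
    )
    runs[[i]] <- simulate_run(run_spec(sp, noise_cv = spec$cv,
                                       seed = spec$seed + i))
  }
  list(samples = samples, runs = runs)
}
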
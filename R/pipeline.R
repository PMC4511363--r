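# End-to-end pipeline: assay configuration, per-run quantification of
# every configured target peptide, and cross-run summary tables.

#' Assay configuration
#'
#' Collects everything the quantification pipeline needs: the target
#' proteins with their fingerprint peptides, charges and expected
#' retention times, the heavy spike amount, the volume ledger, and the
#' extraction tolerances. Every peptide is validated against its
#' protein sequence (when given) by in-silico digestion.
#'
#' @param targets Data frame with columns `analyte`, `sequence`,
#'   `charge`, `rt` and optionally `protein` (full parent sequence) and
#'   `mass_kind`.
#' @param spike_fmol Heavy spike per peptide, fmol (default 50).
#' @param ledger A [volume_ledger()].
#' @param mz_width,rt_width XIC windows: m/z full width in Th (default
#'   0.3) and chromatographic full width in minutes (default 4).
#' @param pmf_tolerance Mass tolerance for identification steps, Da.
#' @param unlabeled_fraction Heavy-standard unlabelled fraction.
#' @param seed Seed recorded with the configuration.
#' @return An `assay_config` list.
#' @export
assay_config <- function(targets, spike_fmol = 50,
                         ledger = volume_ledger(), mz_width = 0.3,
                         rt_width = 4, pmf_tolerance = 0.3,
                         unlabeled_fraction = 0, seed = NA_integer_) {
  stopifnot(is.data.frame(targets),
            all(c("analyte", "sequence", "charge", "rt") %in% names(targets)))
  for (i in seq_len(nrow(targets))) {
    validate_sequence(targets$sequence[i])
    if (!is.null(targets$protein) && !is.na(targets$protein[i])) {
      released <- digest(targets$protein[i], max_missed = 0L)$sequence
      if (!targets$sequence[i] %in% released)
        stop(sprintf("peptide %s is not a tryptic peptide of its protein",
                     targets$sequence[i]), call. = FALSE)
    }
  }
  cfg <- structure(list(targets = targets, spike_fmol = spike_fmol,
                        ledger = ledger, mz_width = mz_width,
                        rt_width = rt_width, pmf_tolerance = pmf_tolerance,
                        unlabeled_fraction = unlabeled_fraction,
                        seed = seed),
                   class = "assay_config")
  cfg$hash <- rlang::hash(unclass(cfg))
  cfg
}

#' Read an assay configuration from YAML
#'
#' @param path YAML file with keys `targets` (list of analyte entries),
#'   and optionally `spike_fmol`, `serum_ml`, `fractions`, `mz_width`,
#'   `rt_width`, `pmf_tolerance`, `unlabeled_fraction`, `seed`.
#' @return An [assay_config()].
#' @export
read_assay_config <- function(path) {
  y <- yaml::read_yaml(path)
  targets <- do.call(rbind, lapply(y$targets, function(t)
    data.frame(analyte = t$analyte, sequence = t$sequence,
               charge = as.integer(t$charge), rt = as.numeric(t$rt),
               protein = if (is.null(t$protein)) NA_character_ else t$protein)))
  assay_config(
    targets,
    spike_fmol = if (is.null(y$spike_fmol)) 50 else y$spike_fmol,
    ledger = volume_ledger(
      serum_ml = if (is.null(y$serum_ml)) 0.1 else y$serum_ml,
      fractions = if (is.null(y$fractions)) 1 else unlist(y$fractions)),
    mz_width = if (is.null(y$mz_width)) 0.3 else y$mz_width,
    rt_width = if (is.null(y$rt_width)) 4 else y$rt_width,
    pmf_tolerance = if (is.null(y$pmf_tolerance)) 0.3 else y$pmf_tolerance,
    unlabeled_fraction = if (is.null(y$unlabeled_fraction)) 0
      else y$unlabeled_fraction,
    seed = if (is.null(y$seed)) NA_integer_ else as.integer(y$seed)
  )
}

#' Quantify every configured target in one run
#'
#' @param run A [spectrum_run()].
#' @param config An [assay_config()].
#' @param run_id Identifier recorded in the output.
#' @return A tibble with one row per analyte x peptide: areas, flags,
#'   ratio, `analyte_fmol`, `conc_fmol_ml`, plus `run_id`, `analyte`
#'   and `config_hash` columns.
#' @export
quantify_run <- function(run, config, run_id = NA_character_) {
  t <- config$targets
  rows <- vector("list", nrow(t))
  for (i in seq_len(nrow(t))) {
    row <- quantify_species(
      run, t$sequence[i], t$charge[i], t$rt[i],
      spike_fmol = config$spike_fmol, ledger = config$ledger,
      mz_width = config$mz_width, rt_width = config$rt_width,
      unlabeled_fraction = config$unlabeled_fraction)
    rows[[i]] <- tibble::add_column(row, run_id = run_id,
                                    analyte = t$analyte[i], .before = 1)
  }
  out <- do.call(rbind, rows)
  out$config_hash <- config$hash
  out
}

#' Run the full quantification pipeline over a set of runs
#'
#' Quantifies every configured target in every run and summarizes per
#' analyte across runs and peptides (unweighted mean with sample SD and
#' CV, mirroring the use of several fingerprint peptides per protein).
#' Optionally writes the per-measurement and summary tables as CSV,
#' together with a log recording the configuration hash and seed.
#'
#' @param config An [assay_config()].
#' @param runs Named list of [spectrum_run()] objects (names become run
#'   identifiers).
#' @param out_dir Optional output directory for `measurements.csv`,
#'   `summary.csv` and `pipeline.log`.
#' @return A list with `measurements` (tibble, one row per run x
#'   analyte x peptide) and `summary` (tibble, one row per analyte:
#'   `n`, `mean_conc`, `sd_conc`, `cv_percent`, `config_hash`).
#' @export
run_pipeline <- function(config, runs, out_dir = NULL) {
  stopifnot(inherits(config, "assay_config"))
  if (length(runs) == 0L) stop("no runs supplied", call. = FALSE)
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    names(runs) <- sprintf("run_%02d", seq_along(runs))
  meas <- do.call(rbind, lapply(names(runs), function(id)
    quantify_run(runs[[id]], config, run_id = id)))
  summarize <- function(d) {
    vals <- d$conc_fmol_ml[!is.na(d$conc_fmol_ml)]
    s <- if (length(vals) < 2L)  # single measurement: SD is undefined, not an anomaly
      list(n = length(vals), mean = mean(vals), sd = NA_real_,
           cv_percent = NA_real_)
    else replicate_summary(vals)
    tibble::tibble(analyte = d$analyte[1], n = s$n, mean_conc = s$mean,
                   sd_conc = s$sd, cv_percent = s$cv_percent,
                   config_hash = config$hash)
  }
  summary <- do.call(rbind, lapply(split(meas, meas$analyte), summarize))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(c(
      sprintf("qconquant %s", as.character(utils::packageVersion("qconquant"))),
      sprintf("config_hash: %s", config$hash),
      sprintf("seed: %s", config$seed),
      sprintf("runs: %s", paste(names(runs), collapse = ", "))
    ), file.path(out_dir, "pipeline.log"))
  }
  list(measurements = meas, summary = summary)
}
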
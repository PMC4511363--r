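---
title: "Absolute serum-protein quantification with QconCAT internal standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute serum-protein quantification with QconCAT internal standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qconquant)
```

## The problem and the method

Clinically interesting serum proteins are often present at fmol/ml
levels, ten orders of magnitude below albumin. Isotope dilution mass
spectrometry (IDMS) quantifies them absolutely: a known amount of an
isotopically heavy analogue of a *fingerprint peptide* — a tryptic
peptide unique to the target protein — is spiked into the digested
sample, and the analyte amount follows from the light/heavy signal
ratio,

$$ A = S \cdot \frac{\text{area}_{\text{light}}}{\text{area}_{\text{heavy}}}, $$

where $S$ is the spiked amount in fmol. The heavy standards come from a
QconCAT: an artificial protein concatenating the fingerprint peptides of
one or more targets, expressed on $^{15}$N as sole nitrogen source so
that every peptide nitrogen is heavy. Trypsin releases each peptide in
strict 1:1 molar ratio to the concatamer, so weighing the purified
construct fixes the molar amount of every standard at once
(`ug_to_pmol()`). The measured amount divides by the serum volume and
the aliquot fractions of the preparation (`volume_ledger()`,
`serum_concentration()`) to give fmol/ml of serum.

`qconquant` implements each stage of this workflow — peptide design,
identification, quantification, summary statistics — together with a
synthetic LC-MS run generator that stands in for the instrument, so the
entire pipeline is testable end to end at desk scale.

## Mass bookkeeping

Peptide masses are residue-table sums plus water; the constants are
fixed (proton 1.007276 Da, monoisotopic water 18.010565 Da,
$^{15}$N$-$$^{14}$N 0.997035 Da) so that tests are bit-stable. A fully
labelled peptide is heavier than its light twin by exactly
$N \times 0.997035$ Da, where $N$ is its nitrogen count — for LLQALR
($N = 10$) the pair is separated by almost 10 Da, or ~5 Th at charge 2,
far beyond any extraction window:

```{r}
labeled_species("LLQALR", "light", charge = 2)
labeled_species("LLQALR", "heavy", charge = 2)
```

Digestion follows the standard trypsin convention: cleavage after K or
R except before proline, applied to both residues, with an enumerated
missed-cleavage budget. Ambiguous residue codes are rejected outright
rather than assigned a guessed mass. The average-mass heavy shift
reuses the same per-nitrogen constant; at the 0.3 Da tolerances used
throughout, the difference from an exact average-isotope treatment is
negligible.

## Designing fingerprint peptides

Design rules are *scored preferences*, not filters: a preferred length
of 8–15 residues, no proline adjacent to a cleavage site, no adjacent
basic residues. A six-residue peptide can still be the right choice —
the ranking only orders candidates, and every tryptic peptide is
reported with its per-rule flags. The uniqueness screen is deliberately
cleavage-context aware: a background protein containing the peptide's
sequence only conflicts if trypsin could actually liberate it, i.e. if
the residue before the hit is K or R or the hit begins the protein (a
hit at position 1 is counted liberable, which errs toward declaring
conflicts). Matching is sequence-exact; I/L equivalence is not applied,
since the context argument itself is sequence-exact.

`assemble_qconcat()` verifies a design by digesting the concatamer
in silico and demanding that every peptide is released intact, which is
the property that makes the construct a stoichiometric standard.

## Quantification

An extracted ion chromatogram (XIC) sums, per scan, all centroid
intensity within a ±0.15 Th window ("0.3 Da mass range" is read as full
width) across a 4-minute chromatographic window. The window is centred
on the heavy standard's elution apex: the standard is always present
and co-elutes with the analyte, so it is the natural anchor when the
expected retention time is only approximate.

Peak integration is trapezoidal with a linear local baseline: the apex
is the global maximum (earliest on ties), bounds grow outward until
intensity returns to the trace median, a straight baseline between the
bounds is subtracted, and an apex that fails to exceed the baseline by
3 median-absolute-deviations of the trace is flagged `no-peak` with
zero area rather than silently integrating noise. A no-peak heavy
standard is a quantification *failure* (reported as `NA`); a no-peak
light trace is a measurement of zero.

One subtlety motivates summing XICs over the first five
isotope-envelope peaks of each species instead of the monoisotopic
trace alone. The light envelope spreads over natural-abundance
isotopologues of C, H, N, O and S; in the heavy species every nitrogen
is fixed at $^{15}$N, so its envelope lacks the nitrogen contribution
and concentrates more weight in its monoisotopic peak (for a 10-N
peptide, about 4% more). Monoisotopic-only ratios would inherit that
bias; summing each species' envelope removes it without any correction
factor. Five isotopologues cover peptides up to ~2 kDa essentially
completely.

Incomplete metabolic labelling is handled on the ratio scale:
if a fraction $f$ of the standard is unlabelled, the observed ratio
$r$ corrects to $(1-f)\,r - f$, which is exact under the signal model
and reduces to the identity at $f = 0$ — the default, appropriate when
labelling efficiency exceeds 99%. A correction that drives the ratio
negative flags the measurement instead of returning it.

## The simulator: what it emulates and what it does not

`simulate_run()` produces centroided MS1 scans in which each species
elutes as a Gaussian (default SD 0.1 min, comfortably inside the 4-min
windows) whose integrated intensity is `amount_fmol × response`
(default response 10^4 intensity·min/fmol, an arbitrary detector gain
that cancels in every ratio), placed on its isotope-envelope m/z
positions. Noise is multiplicative log-normal per scan and species,
with mean 1 so that expected areas are unbiased; runs are byte-identical
under a fixed seed. The scan interval default of 0.02 min gives ~200
points across an elution peak.

`simulate_spike_series()` reproduces the calibration experiment — a
fixed endogenous light amount (default 50 fmol) supplemented with 10,
30, 100 or 300 fmol of heavy standard, one run per level — and
`simulate_cohort()` draws per-sample true concentrations from
truncated-at-zero normal distributions with the measured group
structure of the two markers this workflow was developed on (DcR3:
healthy 27.23 ± 9.47 fmol/ml, tumour 116.94 ± 57.37; GDF15: 98.11 ±
34.96 and 164.44 ± 79.31). Truncated normals were chosen because only
means and SDs are reported for the groups; a log-normal alternative
would be equally defensible and the parameters are fully configurable.

The simulator deliberately does **not** model ionization-efficiency
physics, inter-peptide response differences (treated as free
parameters), retention-time drift between runs, chromatographic
co-elution interference, or the upstream serum preparation (solvent
precipitation, size-exclusion chromatography, MALDI spectra). Passing
tests on simulated data therefore demonstrate that the *computational*
pipeline is unbiased and linear — they say nothing about matrix
effects or digestion completeness in real serum, which are properties
of the wet protocol.

```{r}
series <- simulate_spike_series(seed = 20)
ratios <- vapply(seq_along(series$levels), function(i) {
  q <- quantify_species(series$runs[[i]], series$sequence,
                        series$charge, series$rt)
  q$heavy_area / q$light_area
}, 0)
fit_linearity(calibration_series(series$levels, ratios))$r
```

With per-scan noise at CV 3% the fitted Pearson r lands at the top of
the expected range (r ≥ 0.997): integrating over ~200 scans averages
per-scan noise down, so the simulated calibration is, if anything,
cleaner than a real one, where run-to-run variation dominates.

## Summary statistics

`replicate_summary()` uses the sample SD (n−1), which reproduces the
reference triplet summaries exactly (27.23 ± 2.49 fmol/ml, CV 9.14%,
from means 29.89/24.95/26.87). `group_stats()` uses type-7
(linear-interpolation) quantiles — the convention is configurable since
box-plot quartile definitions vary. `enrichment_factor()` exposes two
conventions: the stated bookkeeping in which x% depletion is equated
with an x-fold enrichment (94.9% depletion at 97.6% recovery →
92.62-fold, the default), and the strict dilution-factor form
$1/(1-d)$ (→ 19.61-fold at full recovery). The stated form is loose
algebra but is the arithmetic actually used in this workflow's
bookkeeping, so it is the default; both are reported for transparency.
Method comparisons default to Spearman with a two-sided p-value;
calibration linearity is fit on the raw points rather than per-level
means (the alternative is one `calibration_series()` call away).

## Problem sizes and numerical choices

The examples and tests run at desk scale by choice: runs of a few
hundred scans, cohorts of 3 + 8 to 3 + 16 samples, one or two analytes
with one fingerprint peptide each. Key tolerances: XIC m/z window 0.3
Th full width, chromatographic window 4 min, PMF tolerance 0.3 Da,
peak-call threshold 3 MADs. Noiseless simulated amounts are recovered
within 1% across 10–300 fmol (the residual is envelope truncation and
trapezoidal quadrature); at 5% per-scan noise, cohort concentrations
are recovered with median relative error well under 10%.

## Known limitations

- PMF identification is greedy nearest-match under a tolerance, not a
  probabilistic search score; on dense theoretical lists a global
  assignment could differ. Coverage percent and match count are the
  reported quantities.
- No MS2/SRM quantification, no cross-run retention-time alignment, no
  deconvolution of overlapping chromatographic peaks.
- The bundled QconCAT examples are toy constructs assembled from short
  peptides; they illustrate the design checks, not a published
  construct sequence.
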
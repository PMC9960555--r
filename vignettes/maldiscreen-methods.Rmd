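---
title: "Suspect screening of plastic additives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suspect screening of plastic additives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(maldiscreen)
```

## The problem

High-throughput screening of plastic consumer products for additives
(organophosphate and brominated flame retardants, phthalate and
non-phthalate plasticizers, antioxidants, UV stabilizers) can be done by
spotting crude extracts onto a 48-well AP-MALDI target plate and
acquiring one high-resolution qTOF spectrum per well, in positive and
negative ionization mode, in seconds per sample. There is no
chromatographic separation and no MS/MS: identification rests entirely on
exact mass and isotope pattern, which places it at confidence level 4 of
the Schymanski scheme. The analytical burden therefore shifts to the data
processing — accurate recalibration, a defensible isotope-fit score, and
strict blank and replicate filters — which is what this package
implements, openly and testably.

## Formula and ion-species model

All mass arithmetic reduces to a molecular formula: a map from element
symbols to counts, with masses taken from a single isotope table bundled
with the package (`inst/extdata/isotopes.tsv`, IUPAC/CIAAW-style values)
so that results are pinned to one reference set. An *ion species* is a
label in a small grammar — `M` followed by signed formula deltas, e.g.
`M+H`, `M+O+K`, `M-C6H2Br3-H` — plus a polarity. Adducts, in-source
fragments and oxidation products are deliberately not distinguished
beyond the label: screening only needs the resulting mass. A species
whose losses exceed the compound's atoms is inapplicable to that
compound and is skipped with a note during database expansion.

Singly charged theoretical m/z values are neutral-fragment monoisotopic
masses with **no electron-mass correction**. This matches how annotated
screening m/z values are conventionally printed (e.g. the TPhP fragment
anion at 249.0317 and the BPA fragment cation at 213.0916, which the
package reproduces to 4 decimals); the alternative convention differs by
one electron mass (≈ 0.55 mDa), well inside the 5 mDa tolerance, and is
available behind the `electron_correction` flag of `theoretical_mz()`.

Compounds with empty species lists are screened with the mode-wide
defaults `{M+H, M+K, M+Na}` (positive; potassium adducts dominate for
KCl-salted extracts) and `{M-H}` (negative). Compound-specific chemistry
— `[M+Cl]−` for chlorinated paraffins, `[M+Br]−`/`[M−Br+O]−` for
brominated analytes, diagnostic fragments for aryl phosphates and
brominated triazines, `[M+O+K]+` for oxidation-prone phosphites — lives
in the database's species columns.

## Isotope patterns

`isotopologue_distribution()` computes the exact fine distribution:
per-element multinomial enumeration (every isotope composition of the
element's n atoms) convolved across elements, with an internal
probability floor of 1e-16 that is far below any tolerance used
downstream. The unit test suite checks this convolution peak-for-peak
against an independent exhaustive enumeration (≤ 1e-12 in probability,
≤ 1e-9 Da in mass) over formulas with up to 4 elements and 30 atoms.

`isotope_pattern()` then emulates what a centroiding TOF instrument
reports:

* **prune** (default 1e-4, relative to the most probable isotopologue)
  drops negligible fine structure while keeping heavily brominated
  envelopes (Br4 and beyond) complete;
* peaks closer than half a peak width, `(m/z / R) / 2` with
  **R = 25,000 FWHM** treated as constant across m/z (a good
  approximation for TOF analyzers), are merged into intensity-weighted
  centroids — the same rule the synthetic generator applies to simulated
  peaks, so theory and simulation describe the same instrument;
* intensities are renormalised to sum to 1.

One consequence worth knowing: heavily brominated envelopes are wide, and
different species of the same compound can collide. For the brominated
triazine TTBP-TAZ, the `[M+K]+` monoisotopic peak sits ≈ 10 mDa from the
8-⁸¹Br isotopologue of its own `[M+Na]+` envelope — unresolvable at
R = 25,000 — so that adduct is not reliably matchable even in clean
simulated data, while the compound is still identified through `[M+H]+`
and its diagnostic `[M−C6H2Br3−H]−` fragment. The pipeline surfaces such
physics rather than hiding it.

## Calibration

Each plate carries a PFSA calibration mixture (C4/C6/C8 perfluoroalkyl
sulfonic acids) in its first and last well. `fit_calibration()` matches
each reference ion to its nearest peak within a coarse tolerance
(default 0.05 Da) and fits corrected = polynomial(observed) by least
squares; `linear` is the default, `quadratic` is available, and a model
degrades (quadratic → linear → identity) with a warning when too few
references match. `plate_calibration()` assigns models to wells by
policy: `average` (default — the mean of the first/last-well models,
appropriate when drift is stable within a run), `nearest`, or `first`.
It also reports the between-calibrant reference-intensity RSD used to
track plate-to-plate reproducibility.

The reference-ion list is a user-editable TSV. The negative-mode
defaults are the three `[M−H]−` monomers plus proton-bound dimers
(≈ m/z 299–1000). Vendor software does not document its positive-mode
reference species over the corresponding range, so the shipped
positive-mode series (`[M+2K−H]+` and a dimer analogue, ≈ m/z 377–1077)
is an explicit package convention, chosen to be chemically plausible for
KCl-salted extracts; the synthetic generator uses the same list, so the
system is self-consistent and the list is trivially replaceable for real
instruments.

## Screening criteria and the isotope-fit score

The three criteria and their defaults (`screening_criteria()`):

| parameter | default | meaning |
|---|---|---|
| `mass_tol` | 0.005 Da | max absolute mass deviation (5 mDa) |
| `sigma_max` | 100 | max isotope-fit score (bands: < 25 excellent, < 50 good, < 100 acceptable) |
| `blank_factor` | 3 | peak height must strictly exceed 3 × highest blank signal |
| `replicate_rule` | all | validated only if detected in every replicate |

Vendor isotope-fit statistics are proprietary, so the package defines an
open sigma-style analogue: restrict the theoretical pattern to peaks
covering ≥ 99 % cumulative intensity, pair each with the nearest measured
peak within tolerance (missing → 0), normalise both vectors to sum 1,
and report `1000 · sqrt(mean((t − m)²))`. Zero means a perfect pattern
match, the score is provably monotone as a measured isotope intensity is
perturbed away from theory, and the conventional < 25/50/100 bands are
kept as configurable labels — but no numeric equivalence with any vendor
score is claimed. The pattern is anchored on the species' matched
monoisotopic peak, making the score insensitive to residual mass offset;
isotope peaks contribute to the score but are not independently required
to match within the mass tolerance.

The blank threshold is computed per plate (blanks are plate-resident):
`3 ×` the highest blank signal at the target m/z, where a blank with no
peak in the window contributes its noise floor (median peak intensity)
instead of 0, so a clean blank does not trivially pass everything. The
inequality is strict: a sample peak exactly at the threshold fails.

`consensus()` reduces per-well matches to per-sample detections in the
times-detected / times-measured style (`3/3`, `9/9`, …). For samples
measured as triplicate extracts × triplicate spots, validation applies
the all-of-n rule to the pooled nine measurements, which is equivalent
to requiring all three spots in all three extracts; this is the stricter
reading of the replicate rule and the one adopted here. One measured
peak may support several compounds: isobars (identical post-species ion
formulas, e.g. DEHP/DNOP `[M+K]+`, or a fragment coinciding with another
compound's `[M−H]−`) share an isobar group id and are all reported —
never resolved winner-take-all, because exact mass and isotope pattern
genuinely cannot distinguish them.

## Reproducibility statistics

For one compound × species in one sample, peak heights form an
extract × spot matrix with `NA` for non-detects. The
**extract-to-extract RSD** is the RSD (sd/mean × 100) over per-extract
mean heights (undefined below two extracts); the **spot-to-spot RSD** is
the mean over extracts of the within-extract RSD, where extracts with
fewer than two detected spots are dropped with a note and the effective
n is reported (one non-detect among 3 × 3 spots yields n = 8, flagged).
Non-detects are excluded, never zero-filled. The standard deviation uses
the n−1 (sample) denominator — the usual choice for replicate
measurements, documented here because both conventions exist in
reporting practice.

## The synthetic plate generator

`simulate_plate()` generates what the analysis assumes and nothing more:

* **layout** — 48 wells, calibrant wells first and last, 3 blanks,
  remaining wells as triplicate-spot samples (explicitly requested
  samples, e.g. 3 extracts × 3 spots, are allocated first; leftover
  wells become extra spots of the last sample);
* **mass error** — `mz_obs = (1 + slope)·mz + offset + N(0, σ)` with
  defaults slope 1e-5 (10 ppm), offset 2 mDa, σ 1 mDa: typical raw TOF
  accuracy before internal recalibration, and large enough that
  screening *must* recalibrate to stay inside 5 mDa at high m/z;
* **intensity noise** — two-level lognormal, σ_extract 0.12 and σ_spot
  0.15 (≈ 12 % and 15 % coefficients of variation), sitting inside the
  1–46 % extract-to-extract and 6–48 % spot-to-spot RSD ranges observed
  for replicate well measurements of real consumer-product extracts;
  the spot-to-spot RSD of simulated data approaches the analytic
  `100·sqrt(exp(σ²) − 1)` in the median;
* **spikes** — each spiked species contributes its full merged isotope
  envelope, scaled so the monoisotopic anchor equals the spike's base
  height (default 5000, ≈ 50 × the blank-derived thresholds produced by
  the default noise level) times the extract and spot factors;
* **background** — 150 peaks per spectrum, uniform in m/z over 100–1100,
  exponential intensities (mean 30); blanks contain only background plus
  any configured contamination; calibrant wells contain the reference
  ions under the same drift;
* **determinism** — one integer seed fixes everything; writing a bundle
  twice with the same seed is byte-identical, and the caller's RNG state
  is restored.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show about real data: detector saturation (approximated
only by an optional per-peak `height_ceiling`), isotope-pattern
distortion at very high analyte concentration, matrix and polymer
background chemistry, ionization suppression, and compound-specific
response factors. A compound can also evade detection on a real
instrument for reasons outside this model (as observed in practice for
some highly brominated compounds); the generator makes spiked compounds
detectable by construction, so end-to-end recovery tests validate the
*pipeline logic*, not instrumental detectability.

## Numerical choices and degenerate inputs

* Convolution floor 1e-16 (absolute probability); pattern prune 1e-4
  (relative); both far from the 5 mDa / score-100 decision boundaries.
* `nearest_peak()` ties on distance resolve to the higher intensity,
  then the lower m/z; the function is total (empty spectrum → no match).
* Calibration models must be monotone over the spectrum range when
  applied; a non-monotone (ill-conditioned quadratic) correction is an
  error rather than a silent peak reordering.
* Empty blanks give threshold 0 (any positive peak passes the blank
  criterion); an absent calibrant degrades to the identity model with a
  warning and `n_refs_used = 0` flagging the report as uncalibrated.
* Duplicate m/z rows in a peak-list file are preserved as read — the
  reader never merges; merging is an instrument property modelled only
  in the simulator and the theoretical pattern.

## Problem sizes used by the test suite

The suite validates end-to-end recovery on 20 seeded default plates
(48 wells, both polarities, ~30-compound database), drift recovery and
sub-mDa post-calibration accuracy on single seeded plates, and the
isotope-convolution oracle on ~20 formulas per run; this keeps the whole
suite around a minute on one CPU while covering every stage at full
fidelity. Larger plates, databases (the screening practice this package
mirrors uses >1300 suspects) and replication counts only scale these
sizes linearly.

## Known limitations

* Confidence is capped at level 4 by design; isobars stay unresolved and
  are reported as groups (MS/MS would be required to go further).
* The sigma-style score shares only its decision structure, not its
  numeric scale, with vendor isotope-fit statistics.
* The positive-mode reference-ion list is a package convention (see
  above) and should be replaced with the instrument's actual reference
  species for real acquisitions.
* Scan-level data are out of scope: one pre-summed centroid spectrum per
  well per polarity is the unit of analysis, and profile-mode mzML is
  rejected rather than peak-picked.
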
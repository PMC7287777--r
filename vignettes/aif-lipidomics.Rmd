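---
title: "Annotating phospholipids from HILIC all-ion-fragmentation runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating phospholipids from HILIC all-ion-fragmentation runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiflipid)
```

## The measurement this package models

In data-independent acquisition (DIA) lipidomics on a quadrupole-orbitrap
instrument, an *all-ion-fragmentation* (AIF) scan fragments every ion in
the source beam at once — no precursor is isolated. Alternating a full MS1
scan with an AIF scan on every cycle therefore yields, per retention time
point, both the intact lipid ions and the pooled fragments of everything
co-eluting. On its own such a fragment soup is unreadable; it becomes
interpretable when the chromatography in front of the source is
*hydrophilic interaction* (HILIC) chromatography on silica, which separates
glycerophospholipids by head-group polarity. Each lipid class then elutes
as one compact band (canonically PG < PI < PE < LPE < PC < SM < LPC), so
every AIF spectrum inside a band is, to good approximation, the fragment
spectrum of one class.

Two fragment families carry the information:

* **Class-diagnostic head-group ions** localize the band of a class:
  protonated phosphocholine at m/z 184.073 (PC, LPC, SM; positive mode),
  the demethylated glycerophosphocholine head at 224.069 (PC/LPC,
  negative), the glycerophosphoethanolamine head at 196.038 (PE/LPE,
  negative), the dehydrated inositol phosphate anion at 241.012 (PI,
  negative), and the doubly dehydrated sphingoid-base cations (264.269,
  236.237, 262.253) shared by sphingolipid classes.
* **Fatty-acyl carboxylate anions** `[RCOO]`⁻ released in negative mode
  report which acyl chains the class carries; their relative intensities
  under a band are a snapshot of the class's fatty-acyl composition,
  obtained without derivatization or per-precursor MS/MS.

The pipeline implemented here: read (or simulate) an interleaved
full-MS/AIF run in one polarity → locate class bands from diagnostic-ion
XICs over the AIF scans → annotate intact species by accurate mass within
each band → read per-class fatty-acyl profiles from band-averaged AIF
spectra → link products back to precursors by XIC shape alignment.

## Exact-mass chemistry

All m/z values are computed, never stored. Monoisotopic atomic masses
(NIST; C = 12 exactly, H = 1.0078250, O = 15.9949146, ...) are strictly
additive over an elemental formula, and every charged species carries the
electron-mass correction (0.00054858 Da per charge). Adduct deltas are
assembled from the same constants: the proton (1.0072765), sodium minus an
electron, and for choline-bearing classes the in-source demethylation ion
`[M-CH3]`⁻ (loss of a methyl radical, gain of an electron, −15.0229 Da),
which is how PC, LPC and SM are observed in negative mode after
source-induced dissociation of their formate/acetate adducts.

Neutral formulas come from shorthand nomenclature (`"PC 16:0/18:0"`,
`"PC 34:0"`, `"LPE 13:0/0:0"`, `"PC O-38:6"`, `"SM d18:1/16:0"`): class
glycerophospho-core plus condensed fatty acids, with the ether (`O-`)
subclass exactly `- O + 2H` relative to the diacyl form. Sum compositions
(total carbons:double bonds) map to formulas directly — the chain split
does not change the elemental composition, so annotation can work on sum
species while chain resolution stays with the fragment rules.

```{r masses}
ion_mz("PG 18:0/20:4", "[M-H]-")
ion_mz("PC 16:0/18:0", "[M-CH3]-")
carboxylate_mz(20, 4)
```

A useful consequence of exact bookkeeping: `[PE 40:6 − H]`⁻ and
`[PC 38:6 − CH3]`⁻ have the *same* elemental formula, so no mass analyzer
can separate them. The package keeps them apart the way the chromatography
does — they sit in different class bands.

## Fragment rules and the sn-position bias

For a negative-mode diacyl glycerophospholipid the predicted fragment set
per acyl chain is: the carboxylate anion, the fatty-acid neutral loss
`[M−H−RCOOH]`⁻ and the ketene loss `[M−H−RCH=C=O]`⁻; PI additionally loses
dehydrated inositol (162.0528 Da) from both loss ions. Loss-ion
intensities encode regiochemistry: losses of the *sn-2* chain give the
stronger ions, so the chain whose FA + ketene loss signal is *lower* sits
at sn-1 (`sn_assignment_rule()`). Carboxylate intensities carry the same
bias in the opposite direction — the sn-2 carboxylate is typically 1.1 to
1.5 times the sn-1 one. The package uses a single bias factor (default
1.3, configurable within [1.1, 1.5]) consistently in the simulator and in
interpretation, and *does not* correct FA profiles for it by default:
reported percentages are raw signal shares, which is what the measurement
itself delivers (an optional flat correction exists in `fa_profile()`).

The diagnostic-ion set and class table ship as a versioned YAML file under
`inst/extdata/`; every m/z is recomputed from its formula at load time.

## Chromatographic machinery

* **XICs** (`extract_xic()`): one point per scan of a kind, summed
  centroid intensity within ±5 ppm by default. The 5 ppm XIC window and
  the 0.005 m/z *annotation* tolerance are deliberately two separate
  knobs: the first tracks instrument mass precision for narrow traces,
  the second is the accurate-mass search width for matching candidates.
* **Peak detection** (`detect_peaks()`): the noise level is
  1.4826 × MAD of the low-intensity half of the trace; apexes must clear
  `min_snr` × noise. Topology (segments, apexes, valleys) is read from a
  cleaned copy of the trace — interior runs of ≤ 2 exact zeros (a jittered
  centroid missing the ppm window for a scan) are interpolated and a
  3-point moving mean damps ripple — while heights and areas always come
  from the raw trace (trapezoidal integration). Two apexes remain separate
  peaks only if the valley between them drops below 0.8 of the lower apex:
  two equal Gaussians 3σ apart split (their summed valley is ≈ 0.65 of the
  apex), while noise dimples (a few percent) merge. No model fitting is
  attempted; band-slice work uses manual windows anyway.
* **Spectrum averaging** (`average_spectrum()`): centroids of member scans
  are clustered within ±0.003 m/z; cluster intensity is the mean over the
  member scans with absent scans counting zero, so averaging N identical
  spectra is the identity.

## Annotation workflow

`locate_class_bands()` turns each diagnostic-ion AIF trace into bands; a
diagnostic shared by several classes (224.069 → PC and LPC) yielding the
same number of bands as classes is disambiguated by the canonical elution
order; otherwise all sharing classes are reported on the band (ambiguity
is surfaced, not resolved silently). Classes without a negative-mode
diagnostic (PG, PS, PA) are handled mass-only: bands are supplied manually
(`manual_band()`) or from precursor traces.

`annotate_species()` matches the band-averaged full-scan spectrum against
a combinatorial sum-composition candidate list
(`enumerate_candidates()`; odd chain totals included) within 0.005 m/z,
and requires a confirming full-scan XIC peak apexing inside the band.
Centroids below 0.01% of the band's base peak are not considered —
species below that relative abundance are inside the baseline and not
meaningfully annotatable. Multiple candidates within tolerance of one
centroid are all reported with an `ambiguous` flag. With the natural
per-class ion choice (PI/PE as `[M−H]`⁻, PC/LPC as `[M−CH3]`⁻) candidate
lists stay free of the exact-isobar duplicates that arise when both ions
are enumerated for choline classes.

`fa_profile()` reads carboxylate intensities from the band-averaged AIF
spectrum (the default chain universe is the plasma reference set) and
normalizes over detected chains to percentages; replicates combine to
mean ± sd (`combine_fa_profiles()`). An `"area"` mode integrating
carboxylate XIC peaks inside the band exists because replicate-filtered
tables are naturally area-based; the spectrum mode is the default and the
one used in the acceptance checks. `replicate_filter()` implements the
keep-if-RSD ≤ 20%-in-all-replicates rule and the within-class
percentage normalization.

`align_precursor_product()` links an AIF product trace to annotated
precursors when the apex RT difference is ≤ 0.1 min and the Pearson
correlation of the traces (precursor interpolated onto the product grid
over the product peak bounds) is ≥ 0.8. The defaults were chosen so that
clean simulated co-elutions link while 1-min-offset decoys do not; both
are configurable, and all qualifying precursors are reported ranked by
correlation — a product shared by several precursors legitimately yields
several links. `ratio_trace()` reports pointwise XIC ratios with gaps
(never zeros) where the denominator does not exceed its noise floor.

## The simulator and what passing it shows

`simulate_run()` exists so that every stage is testable against known
ground truth. It emulates the acquisition scheme being modelled —
alternating full/AIF scans on a 0.02 min cycle, Gaussian class elution
bands (sd 0.08 min) at the canonical HILIC retention times (PG 7.2,
PE 10.2, LPE 14.0, PC 15.3, LPC 17.3 min; PI is placed at 8.5 min, between
PG and PE, as the package's own choice since only the relative elution
position of PI is established), per-precursor AIF fragments taken from
`predict_fragments()` with configurable yields (defaults: carboxylates
0.50 of the precursor signal — they are the base peaks of class AIF
spectra — FA loss 0.05, ketene loss 0.05, head fragment 0.15, residual
precursor 0.20, inositol follow-ups at half their parent loss ion), the
sn-2/sn-1 bias of 1.3, Gaussian m/z jitter (2 ppm sd), multiplicative
intensity noise (5% cv) and uniform-m/z baseline centroids (3 per scan,
mean 0.1% of the largest signal). Within a band, species with longer or
more saturated total acyl chains elute earlier
(offset = 0.003·(34 − C~total~) + 0.003·DB~total~ min), implementing the
qualitative retention trend only. Identical seeds give identical runs;
intensities scale exactly linearly with abundances.

`plasma_like_config()` maps the plasma reference fatty-acyl table to a
species list: each chain of a class becomes one same-chain diacyl species
(PI 18:0 → PI 18:0/18:0) or one lyso species (LPC), with abundance
proportional to its percentage. Same-chain pairing makes the generated
per-class carboxylate ground truth equal the reference column *exactly*
and independent of the sn bias — the recovery test then probes the
pipeline (band location, averaging, windowing, normalization), not an
arbitrary chain-pairing model. The cost is that the simulated *intact*
species are not the real plasma species; the simulation validates the
acyl-profile readout, not plasma species inventories.

What the simulator deliberately does not emulate: isotope envelopes,
ion suppression and cross-class matrix effects, retention drift between
runs, profile-mode peak shapes, chemical noise with structure (the
baseline is uniform in m/z). Passing the recovery tests therefore shows
the pipeline is correct *given* centroided, calibrated, single-polarity
data with class-resolved chromatography; it does not certify performance
on uncalibrated or heavily suppressed real runs.

Problem sizes used in the tests and the acceptance script: runs of about
1300 scans (6–19 min at 0.02 min cycle), 60 species in the plasma-like
configuration, three seeds for the replicated recovery estimate.

## Numerical choices and degenerate inputs

* Annotation tolerance 0.005 m/z (absolute); XIC window 5 ppm; spectrum
  clustering 0.003 m/z — all configurable.
* Ties in sn assignment or missing loss signals → `"unknown"`, never a
  guess; a lyso chain is sn-1 by convention.
* Empty carboxylate signal under a band → empty profile plus warning, not
  an error; a window with no scans of the requested kind → error naming
  the window.
* Formula arithmetic refuses negative element counts; chain grammar
  refuses more double bonds than carbons/2; `[M−CH3]`⁻ is refused for
  classes without a choline head.
* The printed loss-ion values of the PI 18:0/20:4 series are instrument
  readings; the package always computes exact theoretical values (the
  loss-series arithmetic closes to < 1e-3 Da) and matches observed values
  through tolerance windows rather than storing any number it cannot
  derive. The same policy stores the sphingoid d18:1 diagnostic at its
  computed 264.2686 rather than a rounded literature 264.270.

## Known limitations

Double-bond positions and geometry are out of scope (nothing in an AIF
carboxylate readout resolves them). Quantification is relative within a
class; no absolute amounts, no isotope-pattern scoring, no cross-sample
statistics beyond the replicate RSD filter. Ether species are annotated
by exact mass but their fragment chemistry is not modelled beyond the
formula rule. Sphingolipid support covers diagnostics and exact masses;
acyl-profiling of sphingolipids via N-acyl fragments is not implemented.
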
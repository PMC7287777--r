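# aiflipid

Annotation of phospholipids from HILIC-ESI high-resolution MS runs
acquired with interleaved full-MS and **all-ion-fragmentation (AIF)**
scans — a data-independent acquisition mode in which every ion in the
source beam is fragmented without precursor isolation.

## The problem and who this is for

Lipidomics wants two things at once from one LC-MS run: the inventory of
intact phospholipid species and the fatty-acyl chains they carry.
Conventional answers need either per-precursor MS/MS or derivatization
plus GC-MS. When the chromatography is hydrophilic-interaction (HILIC) on
silica, each phospholipid class elutes as a single head-group band
(PG < PI < PE < LPE < PC < SM < LPC), and an AIF scan taken inside a band
is effectively the fragment spectrum of one class. Negative-mode AIF
spectra then deliver the class's fatty-acyl composition through the
carboxylate anions [RCOO]⁻, while head-group diagnostic ions
(184.073⁺ for choline lipids, 224.069⁻ PC/LPC, 196.038⁻ PE/LPE,
241.012⁻ PI, 264.269⁺ sphingoid base) localize the class bands, and
accurate precursor masses annotate the intact species.

`aiflipid` is for mass-spectrometrists and computational lipidomics
people who want that workflow as composable, testable R functions:

* **Exact-mass chemistry** — shorthand parsing (`PC 16:0/18:0`,
  `PC O-38:6`, `SM d18:1/16:0`), elemental formulas, adduct and
  carboxylate m/z from NIST monoisotopic masses with electron-mass
  correction: e.g. `[PG 18:0/20:4 − H]⁻` = 797.534,
  `[PC 16:0/18:0 − CH3]⁻` = 746.571, `[FA C20:4]⁻` = 303.233.
* **Fragment rules** — per-chain carboxylates, fatty-acid and ketene
  neutral losses, the PI dehydrated-inositol (162.0528 Da) follow-up
  series, head-group diagnostics, and the sn-position rule (losses of the
  sn-2 chain are the stronger ions; sn-2 carboxylates run 1.1–1.5× sn-1).
* **mzML I/O** (via mzR), XIC extraction, robust peak detection, spectrum
  averaging under retention windows.
* **Annotation** — diagnostic-trace band location, accurate-mass species
  annotation (0.005 m/z) with band-confined XIC confirmation, per-class
  fatty-acyl profiles, band slicing, precursor–product XIC alignment,
  replicate RSD filtering.
* **A deterministic run simulator** with ground truth, so the whole
  pipeline is testable end to end without instrument data.

## Worked example

Simulate a plasma-like negative-mode run (per-class acyl ground truth
from the built-in plasma reference table), locate the class bands from
diagnostic AIF traces, and profile the LPC band:

```r
library(aiflipid)

res <- simulate_run(plasma_like_config(seed = 1))
res$run
#> <aif_run> 1302 spectra (651 full / 651 AIF), negative mode, RT 6-19.01 min

bands <- locate_class_bands(res$run)
bands[, c("lipid_class", "apex_rt", "rt_start", "rt_end", "diagnostic_mz")]
#> # A tibble: 4 x 5
#>   lipid_class apex_rt rt_start rt_end diagnostic_mz
#> 1 PI             8.49     8.17   8.83          241.
#> 2 PE,LPE        10.2      9.87  10.5           196.
#> 3 PC            15.3     15.0   15.6           224.
#> 4 LPC           17.3     17.0   17.7           224.

prof <- fa_profile(res$run, bands[bands$lipid_class == "LPC", ])
tidy(prof)
#> # A tibble: 13 x 4
#>   lipid_class chain       mz relative_pct
#> 1 LPC         FA C14:0  227.        0.270
#> 2 LPC         FA C16:0  255.       39.8
#> 3 LPC         FA C16:1  253.        0.720
#> 4 LPC         FA C17:0  269.        1.20
#> ...
```

The bands appear in head-group elution order (PI < PE < PC < LPC; the
196.038 band carries both PE and LPE labels because a single band cannot
be disambiguated). The LPC profile recovers the generator's FA C16:0
fraction of 40.0% as 39.8% — the kind of agreement the acceptance script
quantifies. `autoplot()` methods exist for traces and profiles;
`annotate_species()`, `align_precursor_product()` and `replicate_filter()`
continue the pipeline. A thin CLI (`exec/aiflipid`) wraps
simulate/inspect/xic/bands/annotate/faprofile for shell use.

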
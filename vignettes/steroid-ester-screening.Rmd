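---
title: "Multi-voltage fingerprint screening of steroid esters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-voltage fingerprint screening of steroid esters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asapscreen)
```

# The screening problem

Oily injection preparations seized in food-control and anti-doping work
contain anabolic steroid esters at high concentration, usually as
cocktails. A transportable ASAP–MS system — ambient ionization of a 2 µL
extract on a glass capillary, single quadrupole analyzer — can flag such
samples in about a minute, but it has neither chromatographic separation
nor tandem MS. Specificity is recovered from **in-source fragmentation**:
each run records four full-scan channels at cone voltages 12, 20, 30 and
40 V. At 12 V the protonated molecule dominates; higher voltages add
characteristic fragments (ester cleavage, B-ring fission). A reference
library of the 17 target esters holds one thresholded spectrum per
(compound, voltage); an unknown is matched channel-by-channel, the four
scores are fused, and hits are finally cross-checked against selected-ion
recording (SIR) chronograms of each compound's [M+H]⁺.

This vignette explains the models and numerical choices; empirical
behaviour quoted here is exactly what the test suite and
`scripts/acceptance.R` compute.

# The compound registry

`default_registry()` fixes the panel: names, abbreviations, neutral
formulas, nominal [M+H]⁺, the m/z monitored in SIR mode, and annotated
fragments. Neutral formulas follow from standard chemical identity
(steroid + acid − H₂O) and each is validated against the published
protonated-molecule value at package test time; nominal masses use integer
mass numbers (C = 12, H = 1, N = 14, O = 16, S = 32), the resolution regime
of a unit-resolution quadrupole, with no electron-mass correction.
Monoisotopic masses (IUPAC values, ≥ 6 decimals) are provided for future
high-resolution use only.

One registry record is deliberately inconsistent: the SIR list monitors
testosterone isocaproate at m/z 289 — protonated testosterone, the free
steroid — although its ester [M+H]⁺ is 387. The registry stores **both**
values and flags the record (`sir_discrepancy`) rather than silently
correcting either; silent correction would make the package disagree with
the acquisition list actually used, silent adoption would hide a real
anomaly from the analyst. Fragments whose pathway is unassigned (m/z 279,
159 of the estradiol esters) are stored without formulas. The two
ester-cleavage ions that follow the printed cleavage rule but are not
themselves printed (nortestosterone phenylpropionate → 257, drostanolone
enanthate → 287) are annotated as inferred.

# Preprocessing

`preprocess()` applies, in order: restrict to the acquired window
(50–600 Da, boundary-inclusive) → bin to nominal m/z (round-half-to-even,
R's default IEC 60559 rule; centroids from this analyzer are near-integer
already, and binning sums intensities, conserving the total) → normalize
(base peak 100; relative intensities rounded to 4 decimals so normalized
spectra have an exact decimal representation) → threshold at 5 % of the
base peak. The order matters: the percent cut must apply to binned
relative intensities. The chain is idempotent, and the identical chain runs
at library build and at query time. No background subtraction is performed
anywhere.

The threshold comparison is **inclusive** (≥ 5 %): a peak recorded at
exactly the threshold is kept. The convention is configurable
(`preprocess_params(inclusive = FALSE)`), since either reading of
"above 5 %" is defensible; inclusive was chosen so a value printed at the
boundary survives.

# The reference library and its MSP serialization

`build_library()` preprocesses each standard acquisition and stores the
spectra **post-threshold** — the library holds exactly what matching sees.
If replicate acquisitions are supplied they are averaged peak-wise on the
binned relative scale before thresholding, which reduces
acquisition-to-acquisition variance without changing the contract.

Entries are quantized to an integer 0–999 intensity scale (base peak 999)
at build time, which is also the scale written to MSP. Because the match
score is invariant to overall intensity scale, this makes the library →
MSP → library round trip **bit-identical** and guarantees that screening
against an original and a round-tripped library yields identical scores —
a property the suite asserts on the full 68-entry library under both Unix
and Windows line endings.

The MSP dialect is one entry per (compound, voltage), named
`"<abbr>@<V>V"`, with machine-readable `Comment:` fields
(`Compound=…; ConeVoltage=…; ThresholdPct=…; …`) so a library reconstructs
losslessly from its own serialization while remaining readable by generic
NIST-style MSP consumers. Parsing tolerates `;`- and `=`-separated comment
fields and both line-ending conventions; serialization is
byte-deterministic.

# The match score

The commercial score behind the original workflow is proprietary, so the
package defines an open one on the same fixed 0–1000 scale: cosine
similarity between square-root-transformed intensities on nominal m/z
bins, × 1000, rounded half-up. Square-root weighting is the de-facto
standard for unit-resolution library search; the exponent is configurable
(`intensity_power`).

Two bin supports are offered, and the choice is the package's central
design decision:

* **`mode = "union"`** — the classical symmetric identity search over the
  union of both peak sets. Appropriate for pure standards, but provably
  unusable as the default here: a separation-free acquisition of a
  k-component mixture is the *sum* of its constituents, so the union
  cosine of any constituent is bounded by √(1/k) — score ≤ 577 for a
  3-compound cocktail, below every hit threshold. A screening tool built
  on it could never flag a cocktail, while real cocktails are the typical
  positive sample.
* **`mode = "reference"`** (default) — the cosine is evaluated over the
  reference fingerprint's bins only, so sample peaks outside the
  fingerprint (other constituents, oil matrix) are ignored. Additionally,
  the fingerprint is scaled to the query at the reference's base bin
  (highest m/z on ties) and query intensity exceeding the scaled
  fingerprint **by more than `interference_factor` = 3** is truncated to
  the fingerprint's proportion. Rationale: multiplicative measurement
  noise (lognormal, sdlog ≈ 0.1) cannot produce a three-fold excess, so
  such excess must be another species sharing the bin — e.g. trenbolone's
  protonated molecule (m/z 271) landing on the minor ester-cleavage bin of
  every testosterone-ester fingerprint. Without the cap that interference
  masks genuinely present compounds; with an *unconditional* cap the
  opposite failure appears: moderate ratio mismatches — the signal that
  distinguishes free trenbolone's 271/253 pattern from the same two ions
  inside a trenbolone-ester spectrum — would be erased, and a fingerprint
  that is a subset of another compound's spectrum would score a perfect
  1000. The factor-3 gate keeps both: gross excess is interference,
  moderate mismatch is evidence. If the base bin itself is absent the
  compound is scored 0.

Both modes give 1000 for identical peak sets, 0 for disjoint ones, and
both reproduce the worked fixture: query {331: 100} against reference
{331: 100, 271: 100} gives 1000 × 100∕(10·√200) → 707. The union mode is
symmetric; all score properties are cross-checked in the suite against a
brute-force oracle that recomputes the cosine with explicit loops.

# Score fusion and hit criteria

Channel scores (integers, rounded before fusion) are combined as a
weighted arithmetic mean; the weighting is unspecified upstream, so the
default is equal weights, configurable via `match_criteria()`. A **hit**
requires, conjunctively and with inclusive boundaries: channel 1 (12 V)
≥ 850, each remaining channel ≥ 825, fused average ≥ 800. The boundary
vector (850, 825, 825, 825 / average 831.25) is a hit; violating any
single threshold defeats it. Because the full rule conjoins the
average-only rule with further conditions, hits under the full criteria
are always a subset of hits under "average ≥ 800" — hence the full rule's
false-positive rate can only be lower, the mechanism behind staged
criteria in screening. Reports are sorted by fused average (ties broken
lexicographically for determinism).

# SIR confirmation

Each compound's monitored m/z is recorded as a 12 V chronogram; the
desorption event is a ≈ 2 s peak. `integrate_peak()` takes the global
maximum as apex (earliest on ties), bounds the peak region at 5 % of apex
(harmonized with the spectral threshold) and integrates by trapezoid.
`snr_peak_to_peak()` is (apex − median of a noise window) ∕ (max − min of
the window); the default window is the first fifth of the trace, which
precedes the desorption event in this acquisition geometry, and a
zero-amplitude window returns `Inf`. A hit is confirmed iff its trace
reaches S/N ≥ 3 — the estimator is fixed upstream but the cut is not
stated, so the conventional detection limit is used and exposed
(`snr_min`). Hits lacking a trace are warned about and left unconfirmed;
non-hits are never promoted, so confirmation can only remove detections
and the post-SIR false-positive count is never above the pre-SIR count.

# The synthetic-acquisition generator

The generator supplies the statistical structure the workflow assumes, not
a physical model of desorption or ionization:

* **Fragmentation profiles** (`default_profiles()`): per compound and
  voltage, the monitored precursor at relative level 100/100/60/30
  (12/20/30/40 V) and fragments at a leading level of 7/35/70/100
  decaying geometrically (× 0.7) in the registry's listed order. True
  relative abundances per voltage are unpublished, so these are free
  parameters chosen once to realize the qualitative facts: [M+H]⁺ is the
  12 V base peak, fragments at 12 V stay ≤ 10 %, and the count of peaks
  above the 5 % cut never decreases with voltage. Generated spectra are
  structurally, not quantitatively, faithful.
* **Mixtures** are exactly additive before noise (no separation), scaled
  by concentration ∕ dilution (default 100-fold, the sample-prep
  convention for these oily preparations; 100 mg/L per constituent is the
  level at which the decision criteria were established).
* **Oil matrix**: 150 seeded interference ions on 100–600 Da with an
  exponential low-mass bias (scale 120 Da, mimicking the ion-rich
  100–300 Da region of oil extracts), mean intensity 2000 counts —
  roughly 1 % of a constituent's base response (2 × 10⁵ counts at
  100 mg/L ∕ 100).
* **Noise and saturation**: multiplicative lognormal noise (sdlog 0.1) on
  every peak; intensities clipped at 10⁶ counts, emulating the detector
  ceiling that undiluted oily samples hit.
* **Chronograms**: Gaussian peaks, σ = 0.25 s, sampled at 10 Hz on a 5 s
  trace with additive baseline (50 ± 10 counts). The σ realizes the
  points-per-peak geometry: the span above 5 % of apex is
  2σ·√(2 ln 20) ≈ 1.22 s, i.e. 12–13 points at 10 Hz and only ~3 at 2 Hz —
  the reason the method acquires at 10 Hz.

Everything is reproducible from a single integer seed; per-channel and
per-trace seeds are derived arithmetically, so the same sample definition
always yields the same acquisition.

What the generator does **not** emulate: temperature-dependent desorption
order, real matrix-effect magnitudes, carry-over, and the true fragment
abundance ratios. Passing tests therefore demonstrate the pipeline's
logic — preprocessing identity, score behaviour, criteria strictness,
confirmation monotonicity — not instrument-level performance on real
samples; published performance values (matrix effects, MLODs of
1–22 mg/L, RSDs, r > 0.977) are instrument data and are not reproduction
targets of this package.

# Performance statistics

`matrix_effect_pct()` is 100·(A_matrix − A_solvent)/A_solvent (negative =
suppression); `rsd_pct()` the sample-sd based RSD; `linear_fit()` ordinary
least squares with Pearson r. `estimate_mlod()` fits S/N against
concentration over the lowest levels with finite S/N and interpolates to
the target S/N (default 3); the fit-through-low-levels procedure keeps the
estimate local to the detection region, where the S/N–concentration
relation is closest to linear. `confusion_rates()` defines the screening
error rates per panel compound: FP over non-spiked library compounds, FN
over spiked ones — the denominators are a package convention, since the
published percentages do not state theirs.

# Problem sizes and known limitations

The test suite and acceptance script run the end-to-end experiment on 100
seeded samples (singles and 3-compound cocktails at 100 mg/L, oil matrix
on) against the 68-entry synthetic library — a size that exercises every
code path while keeping a full run in tens of seconds on one CPU. Under
those conditions the suite asserts FN = 0, rank-1 identification on all
singles, and a post-SIR false-positive count never above the pre-SIR one.

Known limitations: the reference-mode score deliberately ignores sample
peaks outside the fingerprint, so spectrally thin fingerprints (free
trenbolone's two ions, a subset of its esters' spectra) screen positive
whenever their esters are present — an ambiguity that is real at the
spectral level and is resolved by SIR confirmation, not by the score;
compounds outside the registry are invisible; saturation is modeled as a
hard clip; and no attempt is made to quantify, only to identify.
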
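---
title: "Models, parameters and design choices in mosaicR7"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in mosaicR7}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mosaicR7 bundles five analyses that together connect a 1 bp regulatory
insertion to a photoreceptor-mosaic phenotype: image-based ON/OFF
counting, a hemizygosity-cross association scan, binding-affinity
statistics from selection-sequencing reads, haplotype-based selection
statistics, and two-choice behavioral statistics. Every analysis has a
matching synthetic-data generator with known ground truth, so each claim
a test makes is checked against a quantity the generator controlled. This
vignette records the models, the tunable parameters and why their
defaults are what they are, and the places where the design was genuinely
open.

## The synthetic world

**Retina images.** Ommatidia are hexagonally packed, so R7s are laid out
on a hexagonal lattice (default 15 × 14 = 210 cells, matching the scale
at which real retinas are scored: at least 100 R7s per retina). Each cell
is an isotropic 2-D Gaussian spot (σ = 3 px, spacing 16 px, amplitude 800
over a background of 60) rendered into exactly one channel according to a
Bernoulli(on_fraction) draw; on_fraction defaults to 0.65, a typical
wild-type ON proportion. Both channels are multiplied by a smooth
low-order polynomial illumination field (amplitude 0.3) — precisely the
artifact class a homomorphic filter removes — and corrupted with additive
Gaussian noise (SD 15). Small positional jitter (5% of spacing) keeps the
lattice from being unrealistically perfect. Bit depth, pixel size and
magnification are free parameters of the rendering, not modeled optics;
there is no PSF, no z-dimension, no bristle autofluorescence. A green
segmentation test therefore establishes that the chain recovers truth
under mosaic geometry, illumination bias and moderate noise — not that it
matches any particular microscope.

**Inbred cohorts.** Lines are homozygous draws at per-variant frequencies
(uniform 0.1–0.9), with 2% residual heterozygous and 1% missing calls so
the cross-remapping rule for "all other genotypes" is exercised. The
phenotype is `100 * plogis(qlogis(0.65) + effect * carrier + N(0, 0.4))`:
an ON-percentage bounded in (0, 100) by construction. With
`n_subpops > 1`, per-subpopulation frequencies come from a
Balding–Nichols model so relationship-matrix PCs have real structure to
recover.

**SELEX cycles.** Cycle 0 is uniform random sequence; each subsequent
cycle resamples reads with probability ∝ exp(score / temperature), where
the score is the best PWM log2-odds on either strand. The temperature
default (2 bits) gives strong but not winner-take-all enrichment over
four cycles. This Boltzmann scheme is a modeling choice — the underlying
experiment's generative process is unknown — chosen because it makes
enrichment strength a single tunable knob and is monotone in affinity in
expectation.

**Haplotype panels.** A copying/mosaic model, not a coalescent: every
haplotype is a mosaic of 8 founders with founder switches at
`1 − exp(−ρ·gap)` per inter-site gap (ρ = 1e-5/bp) plus 1% per-site flip
noise. Under a sweep, each derived-allele carrier is overwritten with one
designated founder across an Exp(mean = sweep_strength × 50 kb) window
around the focal site. At `sweep_strength = 0` derived labels are
assigned to exchangeable neutral haplotypes, which makes the neutral null
exact by construction rather than approximately calibrated. What this
buys: direct control of shared-haplotype length. What it lacks:
coalescent-realistic frequency spectra and LD decay — so sweep tests here
validate the statistics' sign and ordering behavior, not their power on
real data.

**T-maze trials.** `N_G ~ Binomial(n_flies, green_prob)`,
`N_B = n_flies − N_G`, 100 flies per trial as in the standard protocol.
Flies that never choose are simply absent from the counts; the PI formula
uses only the two tube counts.

## Segmentation: parameters and numerical choices

The classic form of this chain fixes the operators (homomorphic filter, Gaussian
blur, Canny, convex hull, active contours, watershed, size/distance
exclusion, normalized two-channel comparison) but no parameter values, so
all knobs live in `seg_params()` with defaults tuned once on the
generator:

* `homomorphic_cutoff = 0.03` (normalized frequency). The filter
  subtracts 75% of the log-image's Gaussian low-pass (scale
  `1/(2π·cutoff)` ≈ 5.3 px) around its mean. A spatial, edge-renormalized
  convolution is used instead of an FFT because wrap-around ringing at
  image borders otherwise dominates the very illumination signal being
  removed. The image is offset before the log only when it contains
  non-positive values; shifting an already-positive image would distort
  the multiplicative model.
* `canny_low = 0.08`, `canny_high = 0.20`, as fractions of the maximum
  gradient magnitude, so the same settings work across exposure scales; a
  blank image yields an empty edge map rather than dividing by zero.
  Non-maximum suppression quantizes gradient direction into four bins;
  the 1-px gaps this occasionally leaves in a contour are bridged by
  labeling a 1-px dilation of the edge map (hulls still use original
  edge pixels only).
* Active contours are a Chan–Vese-style binary evolution confined to a
  2-px dilation of the input hull — a bounded refinement, so a grossly
  wrong hull cannot grow without limit. Zero iterations is the identity.
* Watershed seeds are strict local maxima (Chebyshev radius 4) of the
  lightly blurred summed channels inside the union of refined regions;
  flooding proceeds in order of decreasing intensity with deterministic
  FIFO tie-breaking, so the whole chain is reproducible bit-for-bit.
* `min_area = 8`, `max_area = 500` px², `max_center_distance = 0.95` of
  the half-diagonal: with ~3 px spots these bounds only exclude
  speckle and fused blobs; the center-distance rule exists for curvature
  artifacts at the rim of real retinas.
* Classification uses a background-corrected contrast per channel:
  `(region mean − channel median) / (99th percentile − median)`. The
  median estimates background, the high percentile the signal level
  (robust to single saturated pixels); without the median correction a
  channel containing no true signal — an all-OFF retina's Rh4 channel —
  would let noise around its own percentile win calls. Whether such a
  chain should pool statistics over the whole image or only segmented
  foreground is a genuine fork; the whole-image pool is the default and
  is flagged as a choice, not a fact. Ties within
  `ambiguity_margin = 0.05` are called AMBIGUOUS and excluded from the
  `%ON` denominator — in quantized images exact ties do occur, and
  silently assigning them would bias the ratio.
* A retina is `scorable` only when at least 100 regions received an
  RH3/RH4 call, mirroring the scoring floor used for real retinas.

## GWAS choices

The cross is simulated by three exact remapping rules (reference stays
reference; alternate stays alternate inside the deficiency, becomes
heterozygous outside; everything else becomes missing). Dosage coding is
additive (0/1/2); missing calls drop the line for that variant only.
PCs are computed on the post-cross matrix — the analyzed genotypes —
with missing dosages mean-imputed per variant; both points are design
choices this implementation fixes explicitly. The permutation scheme permutes the raw
phenotype vector and refits covariates each time (the simplest scheme
consistent with max(T)); empirical p-values use the add-one formula so
they can never be zero. The minor-allele-count floor defaults to 5
(OLS stability); Bonferroni's m counts tested variants only.

## k-mer and site statistics

Two orientation conventions coexist deliberately: counting uses
lexicographic-minimum canonicalization (both strands collapse onto one
key), while reporting/alignment orients k-mers to minimize Hamming
distance to a consensus, ties keeping the forward orientation. The
frequency-rank percentage divides by the full canonical universe
`(4^k + 4^(k/2))/2` — under which rank counts such as 506 and 366
round to 0.10% and 0.07% — with the observed-distinct denominator available
but non-default. McNemar's statistic is the uncorrected
`(a − b)²/(a + b)` with a chi-square 1-df p; an exact binomial p is
reported alongside when the discordant total is below 25. Reads
containing both sites are tallied but excluded from the test. Site
containment scans both strands — the defensible default for
double-stranded binding, and a convention callers can see in the code.

## Population-genetic choices

F_ST uses the Hudson estimator (fewest sample-size pathologies for
two-population comparisons; Weir–Cockerham-style estimators add little here).
EHH uses the unordered-pair form; iEHH integrates over physical distance
with trapezoids, truncating exactly at the linear interpolated crossing
of the 0.05 threshold — so a threshold of 1 integrates nothing, and a
profile that never crosses is integrated to the last site and flagged
`unbounded`. IHS is implemented exactly as the plain `log2` ratio of the
two iEHH values, deliberately *not* the standardized, frequency-binned
iHS of the wider literature: the two statistics are not interchangeable,
and the package documents its choice at the function level. The control
set keeps 1–2 bp autosomal indels within 25 ± 5% frequency; empirical
two-sided p-values are twice the smaller tail proportion, floored at
1/(N+1).

## Behavior

Per-line PI is the mean of per-trial PIs (matching per-trial SEM
reporting), not the PI of pooled counts; the suite contains a test
documenting that the two differ. Group comparison uses Welch's t-test —
when only a significance level is reported, unequal line counts
argue against assuming equal variances.

## Known limitations

* The segmentation defaults are tuned to the generator's spot scale;
  real confocal data would need re-tuning (and 3-D stacks must be
  projected upstream).
* The haplotype generator's allele-frequency spectrum is not
  coalescent-realistic; IHS calibration against it validates internal
  consistency only.
* PNG image output is 8-bit in this build (the available PNG writer does
  not emit 16-bit); the intensity scale is preserved in a JSON sidecar
  and the pipeline's statistics are insensitive to the quantization.
* `run_pipeline()` orchestrates the synthetic end-to-end path; applying
  the chain to external data goes through the individual readers.
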
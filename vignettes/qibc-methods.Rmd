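---
title: "Quantitative image-based cytometry of DNA-damage foci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative image-based cytometry of DNA-damage foci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Quantitative image-based cytometry (QIBC) treats an automated microscope
as a flow cytometer that keeps the images. Thousands of adherent cells
are imaged in multi-channel fluorescence; each nucleus is segmented from
the DNA stain (DAPI), per-nucleus features are extracted, and the
population is analyzed cytometry-style: total DAPI as the DNA-content
axis, EdU and Cyclin A as cell-cycle markers, and discrete
ionizing-radiation-induced foci (53BP1, gammaH2AX, RAD51, ...) as the
damage readout.

The quantitative crux this package addresses is a confound: IR-induced
DNA damage scales with the amount of DNA in a nucleus. A G2 cell carries
twice the genome of a G1 cell, intercepts roughly twice the damage, and
therefore shows roughly twice the foci — before any biology of the damage
*response* enters. Any per-cell damage metric must therefore be
normalized to that cell's DNA content (its total DAPI signal) before
cell-cycle-resolved comparisons mean anything. After this
divide-by-DNA-content step, a purely damage-proportional marker such as
gammaH2AX is flat across the cycle, and a genuine suppression — such as
the decline of 53BP1 recruitment on replicated chromatin — stands out as
a residual trend.

## The synthetic-microscopy generator

No real image data ship with the package, so every stage is validated
against a generative model whose ground truth is known exactly.

### Cell-cycle states

`sample_population()` draws an asynchronous population with default phase
fractions G1/S/G2 = 0.5/0.3/0.2. S-phase progress `s` is uniform on
[0, 1]; noiseless DNA content is `2 + 2s` genome equivalents (N), i.e. 2N
in G1 and 4N in G2. Measured DNA content multiplies this by lognormal
noise with CV 0.05 — the tight spread of a well-stained DAPI profile —
while marker levels use CV 0.15. Marker means (arbitrary units):

* EdU: 1.0 baseline, 10.0 during S — a clearly bimodal arc;
* Cyclin A: 1 in G1, `1 + 4s` through S, 6 in G2 — monotone accumulation;
* H4K20me2 per N: 1.0 in G1, diluted linearly to 0.35 at the end of S by
  incorporation of new unmethylated histone H4, partially restored to
  0.6 in G2. The A-196 condition models a SUV4-20H1/2 inhibitor that
  blocks this restoration.

### The focus-rate model

The core generative assumption: at DNA content `c` (in N), the genome
splits into unreplicated chromatin, `4 - c` N, and replicated chromatin,
`2(c - 2)` N (template plus nascent copy). Each unreplicated N
contributes `r` expected foci; each replicated N contributes
`r (1 - d)`, where `d` is the *decline strength*:

$$\lambda(c) = r\,\big[(4 - c) + 2m(1 - d)(c - 2)\big]$$

with `m` a replicated-chromatin condition multiplier. The form was chosen
as the simplest accounting that satisfies two boundary behaviors at once:

* `d = 0` gives strict proportionality, `lambda = r c`, so a 4N cell has
  exactly twice the expected foci of a 2N cell — the gammaH2AX behavior;
* `d > 0` gives a monotone decline of per-DNA recruitment with
  replication, with normalized 4N/2N recruitment equal to `1 - d` — the
  53BP1 behavior.

Defaults: `r = 5` foci per N (about 10 foci in a G1 cell, an
early-timepoint load after ~0.5 Gy), `d = 0.6` for 53BP1 in control
cells, halved to 0.3 under siBRCA1/siBARD1/BRCA1-mutant conditions
(attenuated, not abolished), `d = 0` for gammaH2AX, and `m = 0.5` for
53BP1 under A-196 (recruitment to replicated chromatin depressed, never
zeroed). The magnitudes of `d` are synthetic choices — the biology
constrains the orderings and boundary behaviors, not these numbers —
and are exposed as parameters. Per-cell counts are Poisson(`lambda`).

### Rendering

Nuclei are axis-aligned elliptical paraboloid domes on the DNA channel;
the dome integrates to `dna_gain x dna_content` (default gain 2e5 counts
per N, so the nuclear interior sits well above the read noise and the
zero-clipping bias of background subtraction stays below ~1% of the
total). Nuclear area is 4000 px^2 in G1 (a U-2 OS-like nucleus at a 40x
objective) and grows as `dna_content^(2/3)` with 10% jitter; nuclei are
placed with a minimum centroid spacing that forbids overlap. Marker
channels are uniform nuclear fills; foci are Gaussian spots (sigma 1 px,
amplitude 3000 counts) planted uniformly in the inner 65% of the
ellipse with a minimum pairwise spacing of 9 px — foci are modeled as
*resolvable* discrete damage sites; spots closer than one blurred
diameter would merge under any detector, and the detector's merge rule
(no splitting) is documented as the contract instead. Every channel is
blurred with a Gaussian PSF (sigma 1 px), offset by a 100-count
background, and given Gaussian read noise (SD 10) on a 16-bit scale.

One master seed governs everything; per-field seeds are derived by a
deterministic integer mix, so a dataset is a pure function of its
configuration.

### What the generator does not emulate

No optical depth, vignetting or chromatic shift; no mitotic or apoptotic
morphologies; no nucleoli or chromatin texture; no clumped/overlapping
nuclei (beyond an optional spacing override); pan-nuclear focus-channel
signal is uniform rather than textured. Passing tests therefore
demonstrate correctness of the *computational* pipeline under controlled
conditions, not robustness to every artifact of real microscopy — the
segmentation and detection parameters are exposed precisely because real
data differ.

## Pipeline algorithms and numerical choices

**Background correction.** Three estimators: white top-hat and
rolling-ball (both built on flat-disc grayscale morphology implemented
via chord-decomposed running minima/maxima), and a least-squares plane
fit to the dim half of the field. The plane fit is the default for
whole-field correction of nuclear channels: it is unbiased at the
borders, fast, and matches the generator's constant-plus-tilt
backgrounds; the morphological methods are preferred when the background
varies on scales comparable to a nucleus. Subtraction clips at zero,
which biases clipped noise positively by ~0.4 SD per pixel — with
default gains this is <1% of a nuclear total.

**Nucleus segmentation.** Gaussian smoothing (sigma 1), Otsu threshold
scaled by 0.3 (the shoulder factor: with *integrated* intensity as the
DNA-content proxy, a mask cut at the raw Otsu level loses ~10% of each
dome's signal; the scaled threshold keeps totals within a few percent of
truth while staying ~10 noise SDs above background), hole filling,
connected labeling, then a per-component distance-transform watershed
(tolerance 0.25 sqrt(min_area/pi)) to split touching nuclei. Size
window 1500-16000 px^2 by default — bracketing the generator's G1-G2
range — and border-touching nuclei are excluded (their intensities are
truncated). Labels are relabeled contiguously in raster order, which
makes the watershed deterministic given the mask.

**Focus detection.** White top-hat with a disc of radius twice the spot
scale suppresses pan-nuclear signal; the response support is eroded by
five spot scales so the step at the nuclear rim cannot masquerade as
foci. Thresholding is per nucleus at `median + 5 MAD` of the in-mask
response (MAD floored at one count, the quantization limit, so a
degenerate noise-free response cannot collapse the threshold);
suprathreshold components of at least 4 px become foci. Touching foci
are *not* split — counts are conservative. `total_intensity` uses
fixed-aperture photometry (radius 4 px around the centroid): unlike a
suprathreshold-pixel sum, it is linear in spot brightness, which the
amplitude-doubling invariant tests exploit. A global-threshold policy is
available; per-nucleus is the default because nucleoplasmic levels vary
between cells in real data.

**Cell-cycle staging.** The 2N anchor is the lowest substantial mode
(>= 25% of the tallest) of a log-domain KDE of total DAPI with Silverman
bandwidth; the 4N anchor is the dominant mode between 1.6x and 2.4x the
2N anchor, with a logged fallback to exactly 2x. The interphase filter
keeps totals in [0.75 anchor_2n, 1.25 anchor_4n]. EdU positivity is an
Otsu antimode in log space (declared unreliable, with all-negative
fallback, if the classes separate by less than 3-fold). Phases: S = EdU+;
G1/G2 split EdU-negative cells at the anchor midpoint, cross-checked
against a log-Otsu Cyclin A threshold when that channel exists —
conflicting calls are marked `excluded` rather than guessed. The
late-S/early-G2 subphase flags EdU+ cells in the upper DAPI tertile
between anchors, and EdU-negative near-4N cells with intermediate-high
Cyclin A. Every threshold is anchor- or antimode-relative, so a global
gain change alters no call. Gates are declared rectangles/polygons with
lower-inclusive/upper-exclusive rectangle boundaries (adjacent gates add
up); default 2N/4N gates are +/-10% windows around the anchors — a
declared convention, not a reconstruction of any published window.

**Normalization and analysis.** `normalize_to_dna()` divides the chosen
metric by total DAPI per cell, then rescales by the smallest power of
ten that puts the G1 median into [1, 100] (the exponent is logged and
held fixed within an experiment). Group summaries are Tukey box
statistics with medians *and* means always reported. Recruitment ratios
default to medians (robust to focus-count skew) with a seeded bootstrap
95% CI — the CI is a convenience of this implementation and is labeled
as such in the outputs. Decline profiles use
equal-count DAPI bins between the anchors with a Spearman rho of bin
center versus bin median as the monotonicity statistic; a constant
metric reports rho = 0 with a `rho_defined = FALSE` flag. No hypothesis
tests are attached: the analysis is descriptive.

**Pipeline.** `run_pipeline()` chains simulate - validate - segment -
quantify - stage - analyze. Anchors are fitted on the pooled experiment
(identical acquisition settings across conditions is the QIBC
convention), conditions are compared within it, and every table row
carries `(field_id, nucleus_label)` resolvable against the label masks
written alongside the CSVs. Bootstrap and per-field seeds derive from
the one master seed, so rerunning a configuration reproduces every
output byte for byte. The run report records counts, anchors,
thresholds, exponents, timings and versions.

## Design decisions that were genuinely open

* **Coordinates** are 1-based row/column pixel indices (the R and
  EBImage convention) with half-open bounding boxes; an origin-zero
  convention would be equally defensible but foreign to the host
  language.
* **Pooled versus per-condition anchors**: pooled, because conditions
  within one experiment share acquisition settings; per-condition
  anchoring would silently absorb genuine ploidy shifts.
* **Threshold policy for foci** (global per experiment versus adaptive
  per nucleus): both implemented; per-nucleus is the default.
* **Counts versus accumulated intensity** as the recruitment metric:
  both are first-class and flow through the same normalization and
  summaries.
* **No focus splitting** by default: conservative counts; a
  local-maxima splitter would trade false merges for false splits and
  is deliberately left out of the default path.

## Problem sizes used in the shipped checks

The package's own validation runs use 1024x1024 fields of 50 nuclei:
about 2,000 cells per condition for the population-level checks (anchor
ratio, gammaH2AX doubling and flattening, the 53BP1 decline and its
attenuation under BRCA1/BARD1 depletion and A-196), about 2,000
full-channel cells for staging-accuracy and recovery checks, and small
constructed fields for the exact pixel-loop oracles. These sizes echo
the large-cohort acquisition the method is designed for while keeping a
full validation run in the minutes range on a single CPU.

## Known limitations

* 2-D only; no z-stacks, no 3-D foci.
* The focus-rate magnitudes (`r`, `d`, `m`) are synthetic: orderings and
  flatness/doubling behaviors are the validated claims, not absolute
  focus numbers.
* Segmentation is classical (threshold + watershed); heavily clumped or
  textured real data would need parameter tuning or an external
  segmenter, whose label masks can be fed directly into
  `extract_features()`.
* The interphase filter is purely DAPI-window-based; it does not detect
  mitotic figures morphologically.
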
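# qibcr — quantitative image-based cytometry of DNA-damage foci

`qibcr` analyzes high-content fluorescence microscopy the way a flow
cytometrist would, for people studying the DNA-damage response across
the cell cycle: it segments interphase nuclei from a DNA stain (DAPI),
detects sub-nuclear ionizing-radiation-induced foci (53BP1, γH2AX,
RAD51, …), stages every cell in the cycle from DAPI/EdU/Cyclin A/
H4K20me2 features, and normalizes each cell's damage readout to its own
DNA content. A seeded synthetic-microscopy generator with complete
ground truth makes the whole pipeline testable without any external
image data.

## The problem and the model

Ionizing radiation damages DNA in proportion to how much DNA is there:
a G2 nucleus (4N) intercepts about twice the double-strand breaks of a
G1 nucleus (2N), and its total DAPI signal is about twice as high. Raw
focus counts therefore rise through the cell cycle for reasons that
have nothing to do with the damage *response*. The pipeline's central
operation divides each cell's readout by its total DAPI,

    normalized value = metric / total DAPI × 10^k ,

with `k` the smallest integer putting the G1 median on a 1–100 scale.
Under this normalization a damage-proportional marker (γH2AX) is flat
across DNA content, while a genuine suppression — 53BP1 recruitment
declining on replicated chromatin — remains as a monotone trend along
the DAPI axis.

The bundled generator plants foci per cell as Poisson with mean

    λ(c) = r · [ (4 − c) + 2·m·(1 − d)·(c − 2) ],   c = DNA content (N),

where unreplicated chromatin (`4 − c` genome equivalents) yields `r`
foci per equivalent and replicated chromatin (`2(c − 2)` equivalents)
yields a fraction `1 − d` of that. `d = 0` reproduces γH2AX
proportionality (λ = r·c, doubling from 2N to 4N); `d = 0.6` gives the
control 53BP1 decline; BRCA1/BARD1 depletion halves `d` (attenuated,
not abolished); an A-196-like condition halves the replicated-chromatin
term `m` for 53BP1.

## Worked example

Simulate a two-condition 53BP1 experiment (control vs siBRCA1, 300
cells each), run the full pipeline, and inspect the headline numbers:

```r
library(qibcr)

cfg <- qibc_config(
  simulate = list(conditions = c("control", "siBRCA1"), n_fields = 6,
                  cells_per_field = 50, image_shape = c(1024, 1024),
                  marker = "53BP1", min_cells_per_condition = 300),
  out_dir = "qibc_demo", seed = 11)
res <- run_pipeline(cfg)

res$anchors
res$ratios[res$ratios$metric == "focus_count",
           c("condition", "raw_4n_over_2n", "norm_4n_over_2n")]
```

```
DAPI anchors: 2N = 4.137e+05, 4N = 8.089e+05 (ratio 1.955)
interphase window: [3.103e+05, 1.011e+06]
  condition raw_4n_over_2n norm_4n_over_2n
1   control            0.8       0.4136714
3   siBRCA1            1.4       0.7068860
```

Reading these: the fitted 4N/2N DAPI anchor ratio is ≈ 2 (total DAPI
doubles as the genome replicates). In the control, normalized 53BP1
recruitment at 4N is ≈ 0.41 of the 2N level — the decline on replicated
chromatin; under siBRCA1 the ratio rises to ≈ 0.71 — the decline is
attenuated but still present. Per-condition decline profiles
(`res$profiles`) carry the Spearman ρ of normalized recruitment along
the DAPI axis, and `res$cells` is the per-cell table (one row per
nucleus, traceable to its field and label mask under
`qibc_demo/masks/`).

`plot_qibc_scatter(res$cells, "norm_focus_count", res$anchors)` draws
the classic QIBC view: DAPI on x, the metric on y, one dot per cell.

## Package layout

| | |
|---|---|
| `sample_population`, `focus_model_params`, `expected_focus_count`, `render_field`, `generate_experiment` | synthetic microscopy with ground truth |
| `correct_background`, `segment_nuclei`, `extract_features` | nucleus segmentation and per-nucleus features |
| `enhance_foci`, `detect_foci`, `aggregate_foci` | focus detection and per-nucleus aggregates |
| `fit_dapi_anchors`, `filter_interphase`, `classify_edu`, `call_phase`, `gate_spec`, `apply_gate` | cell-cycle staging and gating |
| `normalize_to_dna`, `summarize_groups`, `recruitment_ratio`, `decline_profile` | DNA-content normalization and group analysis |
| `qibc_config`, `validate_inputs`, `run_pipeline` | the end-to-end driver |

The methods vignette (`vignettes/qibc-methods.Rmd`) documents the
generative model, every algorithmic default and its rationale, and the
known limitations.
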
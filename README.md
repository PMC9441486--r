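# zonequant

Zone-resolved compositional analysis of histological whole-slide images
of abdominal aortic aneurysm (AAA) biopsies, for vascular biology groups
quantifying inflammation and extracellular-matrix remodeling in excised
tissue. The package covers the full analysis path:

* **Segmentation** of the wall architecture on elastin-stained sections
  into five classes — vascular wall (*zone 1*), loose perivascular
  tissue (*zone 2*), residual *thrombus*, *background*, and an *ignore*
  class for uncertain borders — with a natively implemented U-Net
  variant: BSConv2 blocks (reflection-padded 3×3 convolution → batch
  normalization → trainable Swish `x·σ(βx)`), strided-convolution
  down/up-scaling, concatenation skips, He-normal initialization.
* **Training** with the squared soft-Jaccard loss
  `L = 1 − Σpg / (Σp² + Σg² − Σpg)` over non-ignored pixels, Adam
  optimization, per-epoch Jaccard/F1 curves and best-validation-loss
  checkpointing (`fit_zoneseg()` returns a classed fit with
  `print`/`summary`/`plot`/`predict`/`coef` methods).
* **Evaluation** with classification reports (precision, recall, F1,
  Jaccard `J = F/(2−F)`, support), macro/weighted aggregates with
  optional ignore-exclusion, and the background-precision correction for
  partially annotated ground truth.
* **Quantification** per zone via optical-density colour deconvolution:
  positive-cell detection (hematoxylin-channel nucleus detection, DAB
  compartment thresholds for CD8/MPO), DAB stained-area measurement
  (CD68), and elastin/collagen fiber classification, reported as
  per-patient CSV tables.
* **Synthetic slides** with exact ground truth
  (`generate_weigert_slide()`, `generate_ihc_slide()`) so every stage is
  testable without patient data.

## Worked example

Reconstructing aggregate metrics from a per-class validation report, and
applying the background-precision correction:

```r
library(zonequant)
rep <- reference_validation_report()
aggregate_report(rep, "macro")
#>   precision recall     f1   jaccard    support
#> 1    0.5992  0.728 0.6268 0.4564521 1520156957

cor <- correct_background(rep, estimated_precision = 0.980)
aggregate_report(cor, "weighted", exclude = "ignore")
#>   precision    recall        f1   jaccard    support
#> 1 0.9151453 0.9209048 0.9166289 0.8460895 1478484265
```

The macro precision (0.599) averages the five per-class precisions; the
corrected, support-weighted Jaccard excluding the ignore class (0.846,
i.e. 84.6%) is obtained by substituting an estimated 0.98 background
precision, recomputing the background F1 and converting the weighted F1
through `J = F/(2−F)`. For scale: a DICE of 0.7 — a common adequacy
threshold in biomedical segmentation — corresponds to
`jaccard_from_dice(0.7)` = 0.538.

A complete synthetic run (generate → tile → train → segment → masks →
quantify) on a small configuration:

```r
cfg <- default_run_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)
read.csv(file.path(cfg$out_dir, "zone_quantification.csv"), check.names = FALSE)
#>        Class Detections Positive Positive % Positive per mm2    Area mm2
#> 1      zone1          6        3         50              984 0.003048347
#> 2      zone2          5        2         40              358 0.005587190
#> 3   thrombus          0        0          0                0 0.000000000
#> 4 background          0        0          0                0 0.004904959
```

Here six cells were planted in zone 1 and five in zone 2 of a small
synthetic slide (half of them DAB-positive), the network was trained on
two sibling slides, and every planted cell is detected and assigned to
the zone predicted for it; the density columns follow from the tiny
synthetic zone areas (a few thousandths of a mm²).

A per-zone cell report from raw counts (detections, positives, zone
area) derives the density columns:

```r
counts <- reference_cell_counts()
zone_quant_rows(counts$class, counts$detections, counts$positives, counts$area_mm2)
#>      class detections positives positive_pct positives_per_mm2 area_mm2
#>      zone1     129824     12308          9.5               545     22.6
#>      zone2      48472      1680          3.5                76     22.0
#>   thrombus       1920       148          7.7               370      0.4
#> background         80         0          0.0                 0     85.0
```

A thin command-line wrapper over the same functions lives at
`inst/cli/zonequant.R` (subcommands `synth`, `tile`, `train`, `segment`,
`masks`, `quantify`, `run`, `evaluate`).

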
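# k7quant

Automated quantification of cytokeratin-7 (K7) immunohistochemistry in
liver biopsies.

In chronic cholestatic liver disease (the canonical example being primary
sclerosing cholangitis), hepatocytes near the portal tracts begin to
express K7, a keratin normally confined to bile-duct epithelium. On a
DAB/hematoxylin-stained slide these cholestatic hepatocytes appear as
brown periportal cells, and their extent is a quantitative marker of
disease severity. Pathologists grade this by eye with an ordinal 0–3
deposition score; `k7quant` computes it, and the continuous statistic it
approximates, directly from the image.

The package is aimed at image-analysis researchers and computational
pathologists who need a fully open, deterministic, testable reference for
this class of pipeline — every stage runs on CPU in plain R, and a bundled
synthetic-histology generator provides pixel-exact ground truth so the
whole chain can be validated without any patient data.

## What it computes

**Nested segmentation.** Three layers, each clipped by its parent:

1. *liver tissue* vs glass background (total optical density),
2. *portal areas* vs *parenchyma* within tissue (smoothed hematoxylin
   density plus DAB-positive ductal structures, dilated to absorb the
   ductular reaction; parenchyma is the exact complement),
3. *K7-positive hepatocytes* within parenchyma (DAB concentration from
   H-DAB color deconvolution, thresholded, speckle-filtered).

Because each layer is clipped by the previous one, DAB-positive bile ducts
and ductular reaction can never be counted as K7-positive hepatocytes —
they live in the portal layer. The same clipping makes upstream errors
guaranteed downstream false negatives; the metrics module accounts for
that share explicitly (`clipped_fn_pct`).

**Per-specimen statistics.** With masks in hand:

- `K7%area = 100 · |K7 mask| / |parenchyma mask|` — the core statistic,
- layer areas (mm²) and portal/parenchyma proportions of tissue,
- per-cell instances (connected components, watershed-split when merged)
  with Euclidean distance to the nearest portal tract,
- periportal zone labels: zone 1 is the third of the portal-sinusoid
  length `L` nearest the portal tract (`d < L/3`, default `L = 584` µm,
  midpoint of the normal 447–721 µm range),
- the automated deposition score (0–3): a periportal region is positive
  when ≥ 10 K7⁺ hepatocytes lie in its zone-1 band; score 1 with one
  positive region (or positive fraction < 1/3), 2 for 1/3–2/3, 3 above
  2/3, 0 with none.

**Validation and cohort statistics.** Pixel-level FP%/FN% (their sum is
the total area error), precision and sensitivity per layer against ground
truth; Spearman correlations on raw values and Pearson on ln-transformed
values (zeros excluded or offset, both reported) across a cohort table.

## Worked example

```r
library(k7quant)

# a synthetic biopsy tile: 1.0 x 0.5 mm at 2 um/px, 4 portal tracts,
# moderate cholestasis (severity 0.6)
cfg <- generator_config(image_height_px = 250, image_width_px = 500,
                        pixel_size_um = 2, n_portal_areas = 4,
                        portal_radius_um = 50, severity = 0.6, seed = 42)
sp <- generate_specimen(cfg)

masks <- run_pipeline(sp$image, config = pipeline_config(pixel_size_um = 2))
q <- quantify_specimen(masks, "demo", pipeline_config(pixel_size_um = 2))
q$record[, c("k7_area_pct", "portal_fraction_pct", "n_k7_cells",
             "mean_distance_um", "k7_score")]
#>  k7_area_pct portal_fraction_pct n_k7_cells mean_distance_um k7_score
#>     15.13416            8.354825        116         98.63946        3

sp$metadata$true_k7_area_pct   # generator ground truth
#> [1] 15.0542

validate_layers(masks, sp$gt_masks)
#>        layer fp_pct fn_pct total_area_error_pct precision_pct sensitivity_pct clipped_fn_pct
#> 1     tissue 0.0008  0.000               0.0008         100.0           100.0              0
#> 2     portal 0.4878  0.000               0.4878          94.2           100.0              0
#> 3 parenchyma 0.0000  0.488               0.4878         100.0            99.5              0
#> 4         k7 0.0000  0.000               0.0000         100.0           100.0              0
```

Reading this: the pipeline measured a K7%area of 15.13% against a true
value of 15.05%; 116 K7⁺ hepatocytes were detected at a mean distance of
~99 µm from the nearest portal tract (well inside zone 1, boundary
194.7 µm), and the specimen scores 3 because more than two thirds of the
periportal regions hold ≥ 10 positive cells. The validation table shows
per-layer area errors of < 0.5% with no clipping losses.

A command-line front-end covers the same flow
(`inst/cli/k7quant generate|segment|quantify|validate|cohort|correlate`);
see `?cli_main`.

## Layout

- `R/` — generator (`synthgen`), stain physics (`stains`), nested pipeline
  (`segment`), statistics (`quantify`), scoring (`score`), validation
  metrics (`metrics`), cohort batch + correlations (`cohort`), raster
  morphology, plain-format I/O (PPM/PGM/JSON/CSV), CLI.
- `src/` — Rcpp primitives: connected components, exact Euclidean distance
  transform, marker watershed.
- `vignettes/k7quant-methods.Rmd` — model, parameters, design choices and
  limitations.
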
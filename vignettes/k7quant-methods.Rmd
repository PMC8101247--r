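---
title: "Methods: quantifying K7 immunohistochemistry in liver biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying K7 immunohistochemistry in liver biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k7quant)
```

## The measurement problem

Chronic cholestasis induces cytokeratin-7 expression in periportal
hepatocytes. On a DAB/hematoxylin slide, three visually similar things are
brown: K7⁺ hepatocytes (the signal), bile-duct epithelium, and the
ductular reaction at the portal interface (both confounders). A credible
quantification therefore needs more than a color threshold: it needs to
know *where* a brown pixel sits. `k7quant` resolves this structurally,
with a nested three-layer segmentation in which each layer is clipped by
its parent:

1. tissue vs background,
2. portal areas vs parenchyma, *within tissue* — with bile ducts and
   ductular reaction assigned to the portal layer,
3. K7⁺ hepatocytes, *within parenchyma*.

Ductal DAB can then never contaminate the hepatocyte count, by
construction rather than by shape heuristics. The cost of clipping is that
upstream misses are unrecoverable downstream; `clipped_fn_pct` in the
metrics module reports exactly that share, so users can attribute child
false negatives to the parent where they belong.

## Stain physics

Brightfield absorbance follows Beer–Lambert: per channel
`OD_c = -log10(I_c / I_0)` with `I_0 = 255` for 8-bit images (intensities
are floored at 1 and clipped to `I_0`, so OD is finite and non-negative).
A pixel's OD vector is modelled as a non-negative combination of unit
stain vectors, `OD = c_H v_H + c_D v_D`, using the published
Ruifrok–Johnston H-DAB directions (`v_H = (0.650, 0.704, 0.286)`,
`v_D = (0.268, 0.570, 0.776)`, each normalized; the residual vector
completes the basis via a cross product). Deconvolution is the 3×3 linear
solve per pixel, clamped at zero.

**Numerical caveat.** The H and DAB vectors are far from orthogonal, so
the inverse matrix amplifies per-channel OD quantization noise by a factor
of about 1.7. With 8-bit rendering this puts a worst-case relative error
of roughly 3% on recovered hematoxylin concentrations even at
mid-range values; DAB recovers within 2% for concentrations ≥ 0.4, which
is the regime the positivity decision lives in. The test suite asserts
the exactly propagated per-pixel quantization bound (`|M⁻¹|·|δOD|`)
rather than a blanket percentage.

## Positivity cutoff

The field's practice distinguishes "deep brown" (positive) from "lightly
stained" (negative) hepatocytes by eye. We encode this as a DAB
concentration threshold with default **0.7**, calibrated once against the
synthetic generator, whose palette renders light cells at 0.4 and deep
cells at 1.0 — the default sits midway, giving margin on both sides. It is
a config value (`positivity_config()`), not a constant in code: faded
older specimens are handled by lowering it per run, not by automatic
normalization. Components smaller than a 10 µm-diameter disc
(≈ 78.5 µm², well under the ~25 µm hepatocyte) are removed as speckle.

## Segmentation backend

The original workflow this reproduces used three proprietary CNNs; the
layer semantics, not the classifier, carry the scientific content. This
package substitutes deterministic operators with the same contracts, so
results are bit-reproducible and every stage is auditable; a learned model
could be dropped in behind the same stage interface.

- *Tissue*: total OD > 0.1, closed (5 µm), hole-filled, fragments
  < 0.01 mm² dropped.
- *Portal*: smoothed hematoxylin concentration (box filter, 8 µm
  half-width) > 0.5 marks the nuclei/stroma-dense portal core; cores
  smaller than a 30 µm disc are dropped; the core is dilated by **15 µm**
  (configurable) to absorb the immediately adjacent ductular reaction, and
  DAB-positive ductal components touching the dilated core are merged in.
  Parenchyma is the exact complement within tissue, so the partition
  invariant holds on every run. Boundary ownership of DAB-positive cells
  straddling the portal edge follows this dilation radius — a stated
  tunable, since no ground truth defines it.
- *K7 layer*: the positivity cutoff applied inside parenchyma.

All parameters are in physical units (µm, mm²), so behaviour is
resolution-independent; the defaults assume the native 0.221 µm/px scan
resolution but tests run at 2 µm/px unchanged.

## Quantities

- **K7%area** `= 100·|k7|/|parenchyma|` in pixel counts; `NA` (with a
  warning) when parenchyma is empty, never an exception.
- **Instances**: 8-connected components; equivalent diameter
  `2·sqrt(A/π)`; components under 10 µm dropped. Merged cells are split by
  marker-based watershed on the interior distance transform: markers are
  the connected cores above 55% of the component's distance maximum, so a
  lone convex cell (one core) never splits while a touching-disc barbell
  (two cores) always does. This follows the package's oracle fixtures; a
  pure size-threshold rule would leave two touching 25 µm cells
  (equivalent diameter 35.4 µm) unsplit.
- **Distances**: Euclidean distance transform of the portal complement,
  sampled at centroids (a per-cell scalar robust to cell shape), in µm.
- **Zones**: zone 1 if `d < L/3`, zone 2 if `L/3 ≤ d < 2L/3`, else zone 3,
  with `L = 584` µm by default (midpoint of the 447–721 µm normal
  portal-sinusoid range). The interval convention (strict left, closed
  right) is a choice; the boundary case is not defined by any reference.

## The deposition score

A periportal region is the zone-1 band (default width `L/3`) around one
connected portal component. Each cell is assigned to its *nearest* portal
component (ties to the lower id) and counts for that region only if it
lies within the band — bands may overlap, but a cell is never counted
twice. A region is positive with ≥ 10 assigned cells ("at least ten
hepatocytes"). With positive fraction `f` over `n` regions:

| situation | score |
|---|---|
| no cells at all, or cells but no positive region | 0 (latter flagged `subthreshold_positive`) |
| exactly one positive region, or `f < 1/3` | 1 |
| `1/3 ≤ f ≤ 2/3` | 2 |
| `f > 2/3` | 3 |

The protocol's categories leave a gap between "one periportal area" and
"1/3–2/3 of periportal areas"; we close it by giving score 1 the open
interval below 1/3 and score 2 the closed middle interval, which reads
the "1/3–2/3" wording literally and keeps the score monotone in the set
of positive regions (adding cells can never lower it — a tested
invariant). An empty portal mask returns an explicit `unscorable` status
rather than a fabricated 0.

## Validation metrics

Within an evaluation region: `fp_pct` and `fn_pct` are FP and FN pixel
counts as percentages of the region, and the total area error is exactly
their sum; precision `= TP/(TP+FP)` and sensitivity `= TP/(TP+FN)` are
reported as absent (never 0 or 100) when their denominators are empty.
The evaluation region defaults to the ground-truth *parent* layer (whole
frame for tissue, tissue for portal/parenchyma, parenchyma for K7),
standing in for the original annotation regions, whose geometry is not
public; it is overridable. Metrics are pixel-level throughout, consistent
with the area-error language of the protocol (object-level variants are
out of scope).

## The synthetic world

`generate_specimen()` renders a stated world, not a tuned one:

- a horizontal needle-core strip with wavy edges on white glass; strip
  height is 80% of the tile (capped at 1 mm) — the default
  2000×1000 px tile at 0.221 µm/px is a 0.44×0.22 mm crop of a core, so
  the full 1 mm core width cannot fit, and all statistics are
  area-normalized so tile size does not change their definitions;
- quasi-circular portal tracts (default radius 40 µm, mutually exclusive
  positions; placement failure after a bounded number of attempts raises
  an "over-dense" error): a dense hematoxylin core (conc. 0.75) with a
  15 µm outer annulus of lighter stroma (0.35) carrying small DAB-positive
  ductular rings (0.8) — the ductular reaction, *inside* the ground-truth
  portal mask. Rendering the reaction in the annulus is what makes the
  pipeline's 15 µm dilation meaningful rather than a systematic
  over-segmentation;
- parenchyma as hematoxylin-outlined hepatocyte discs (25 µm) without
  nuclear detail — the pipeline never uses nuclear morphology;
- K7⁺ hepatocytes: non-overlapping 25 µm discs at DAB 1.0, placed by
  rejection sampling with acceptance `exp(-d/λ)` where `d` is the distance
  to the nearest portal tract and `λ = severity · L/3` — so severity
  pushes cells outward while zone 1 keeps the majority; the target K7 area
  fraction is `0.25 · severity` of parenchyma (a scale choice: severity 1
  is florid cholestasis at ~25% of parenchyma, and the cohort's severity
  distribution is otherwise unconstrained by published data). Severity 0
  places nothing. Lightly stained nuisance cells (DAB 0.4, ~30% of the
  positive count) exercise the cutoff and are excluded from ground truth;
- a global `stain_fade` scalar attenuates DAB at render time (old
  specimens); no other scanner artifacts are emulated;
- covariates: Nakanuma stage `clamp(round(3·severity)+ξ, 0, 3)` and
  Metavir `clamp(round(4·severity)+ξ, 0, 4)` with categorical noise
  `ξ ∈ {-1,0,+1}` (P = 0.1/0.8/0.1 per tail at the default 0.2 noise
  probability), and simulated plasma ALP
  `80 + 150·severity + LogNormal(log 40, 0.5)` U/l — a weak-to-moderate
  positive association of the kind seen clinically. Any monotone map
  suffices for the sign-recovery tests; zero-noise settings make the maps
  strictly monotone for exact checks.

Everything is deterministic given `(config, seed)`, bit-for-bit, and
`metadata$true_k7_area_pct` is exactly recomputable from the ground-truth
masks — an identity the tests assert, closing the loop between generator
and quantifier.

**What a green test does not establish.** The generator draws crisp discs
with exact palette concentrations; real histology has nuclear texture,
sinusoid lumens, inflammation, steatosis, section artifacts and staining
gradients. Passing the Dice/precision bars here demonstrates the
*contracts* (nesting, clipping, arithmetic, score logic) and the backend's
correctness in its stated world — not clinical-grade segmentation of real
slides. Likewise the cohort correlations recover *built-in* dependencies;
they say nothing about effect sizes in patients.

## Statistics

Spearman is Pearson on mid-ranks (average ranks for ties); both use the
two-sided t-approximation `t = r·sqrt((n-2)/(1-r²))` for p-values.
Correlation reports pair Spearman-on-raw with Pearson-on-ln. For ln of
zero-valued K7%area the default policy excludes zeros and reports the
count; an offset policy (`ln(v + ε)`, `ε` = half the smallest positive
value) is also implemented since published practice on this point is
unstated. Degenerate inputs (constant columns, n < 3) produce explicit
statuses, never silent NaNs.

## Numerical and degenerate-input choices

- Coordinates are 0-based, x = column, y = row, origin top-left; areas
  are pixel counts × (pixel size)². Distance transforms are exact
  Euclidean (Felzenszwalb–Huttenlocher), not chamfer approximations.
- Blank image → all-empty masks with a warning; empty parenchyma → `NA`
  K7%area; empty portal → `NA` distances and `unscorable` score. No stage
  throws on emptiness; only genuine contract violations (shape
  mismatches, invalid polygons, non-invertible stain matrices) are errors.
- Watershed floods 4-connectivity with FIFO tie-breaking, so splits are
  deterministic.
- Image I/O uses plain PPM/PGM (the environment provides no PNG/TIFF
  codec for R); masks use the hierarchical label encoding 0 background /
  1 tissue / 2 parenchyma / 3 portal / 4 K7⁺ hepatocyte.

## Known limitations

- The segmentation backend is tuned to H-DAB brightfield with the
  standard stain vectors; no automatic stain-vector estimation.
- Pyramidal whole-slide formats are not read; tiles up to ~10⁸ px are.
- The 0.7 positivity default is a calibration against the synthetic
  palette, flagged as such; real cohorts need a one-time visual
  calibration.
- Zone analysis is purely portal-distance-based; no central-vein
  detection or lobule reconstruction.
- Test-suite segmentation checks run at 2 µm/px tiles for speed; the
  physical-unit parameterization makes the operators scale-equivalent,
  but sub-micron behaviour is only exercised by the single
  native-resolution case in the suite.
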
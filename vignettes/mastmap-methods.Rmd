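---
title: "Quantifying mast-cell CPA3 mRNA and protein in lung tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mast-cell CPA3 mRNA and protein in lung tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastmap)
```

## The measurement problem

Mast cells store preformed proteases — tryptases, chymase, and
carboxypeptidase A3 (CPA3) — in cytoplasmic granules. In chronic lung disease
the amount of CPA3 a tissue can release depends on two quantities that
ordinary bulk assays confound: how much CPA3 each mast cell makes, and how
many mast cells the tissue holds. `mastmap` implements a histology-based
single-cell decoding of both, from multiplex-stained slide scans:

* the **tryptase channel** defines where mast cells are (their lineage
  proteases are constitutively and strongly expressed);
* the **RNAscope in-situ-hybridisation channel** reports CPA3 mRNA as
  punctate per-transcript dots;
* the **immunofluorescence channel** reports granule-stored CPA3 protein as
  diffuse intracellular signal;
* the **nuclei channel** defines the analysed tissue area.

The segmentation philosophy mirrors locked-exposure slide cytometry: one
intensity threshold on the tryptase channel, applied identically to every
section of a study run, followed by connected-component labelling and an
inclusive cell-size window. The resulting mask is superimposed unchanged on
the mRNA and protein channels, so all three quantities are measured over the
identical pixel sets. No watershed splitting is attempted: the protocol is
threshold + size filtration, and objects merged by contact are handled by the
maximum-area cut.

Per cell, the pipeline reports background-corrected mean intensities
(`mrna_corr`, `protein_corr`), their ratio

$$Q = \frac{\text{mRNA}_\text{corr}}{\text{protein}_\text{corr} + \varepsilon},$$

locked-threshold high/low gates, the anatomical compartment containing the
cell centroid, and per-patient summaries (means, densities per mm² of
compartment, gated fractions). Patients — not cells — are the inference unit
for group statistics, so every test operates on mean patient values.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tryptase_threshold_value` | 300 | AU | locked mast-mask threshold (`otsu` available per section) |
| `min_cell_area_um2`, `max_cell_area_um2` | 20, 700 | µm² | inclusive ROI size window; brackets mast-cell cross-sections and cuts debris/merges |
| `quotient_epsilon` | 1 | AU | keeps protein-negative cells finite in the quotient |
| `mrna_high_threshold`, `protein_high_threshold` | 300 | AU | locked high/low gates on corrected intensity (strictly greater than) |
| `tissue_threshold` | 50 | AU | smoothed-nuclei level defining analysed tissue |
| `pixel_size_um` | 0.5 | µm | physical pixel size; supplied by config, never parsed from TIFF metadata dialects |
| `od_threshold` | 0.15 | OD | chromogen immunoreactivity threshold |
| `gene_min/max`, `umi_min/max`, `mito_max_frac` | 1000/75000, 1000/75000, 0.20 | — | inclusive scRNA-seq cell QC window |
| `cpa3_split_threshold` | 1.5 | log-norm. expr. | CPA3-high iff strictly above; at the threshold is low |

The size-filter bounds and the tryptase threshold are declared defaults, not
values inferred from data: they are exposed in `study_config()` and recorded
with every run so a study can lock its own.

## What the synthetic generator emulates

Every stage is testable without patient material because
`make_compartment_layout()`, `simulate_section()`, `simulate_cohort()`,
`simulate_brightfield()` and `simulate_counts()` produce data with known
ground truth. The generator emulates:

* **anatomy** — airways as concentric lumen/epithelium/subepithelium discs,
  elliptical pulmonary vessels, an alveolar-parenchyma remainder; the lumen
  is an `excluded` region;
* **cells** — elliptical tryptase-positive blobs, areas uniform on 50–250 µm²
  (mast-cell cross-sections), placed by rejection sampling with a soft
  hard-core repulsion (minimum centre separation 0.9 × the summed equivalent
  radii). Close pairs still touch and merge in the rendered mask — the
  segmentation must face real merges — but pathological stacking is avoided;
* **texture** — mRNA as RNAscope-like puncta (dot count Poisson with mean
  `dot_density_per_au` × level × area, so mean intensity tracks the level
  independent of cell size), protein as diffuse fill, plus constant
  autofluorescence, a low-frequency background field, Gaussian read noise,
  and 16-bit quantisation;
* **disease structure** — group presets plant the reported effect shapes:
  COPD raises mRNA 3× in small airways and 2× in vessels (1.7× parenchyma)
  with unchanged protein; IPF raises parenchymal mRNA 3.2× and protein 1.8×
  with a 7× parenchymal density increase. mRNA-high cells are planted as an
  explicit mixture component (median 700 AU versus a ~100 AU base), with
  fractions 0.5% (control), 10% (COPD) and 40% (IPF parenchyma), so the
  locked 300 AU gate recovers ≲1% of control cells and ~40% of the IPF pool;
  base medians are solved in closed form so the planted group-mean folds
  equal the targets exactly in expectation (`preset_expected_means()`);
* **patients** — a log-normal multiplicative random effect (CV 0.25) on each
  patient's mRNA and protein medians. At n = 9/10/6 this leaves a
  Mann–Whitney power well above 0.9 for a 3× effect, while making
  group-mean folds drift by ±12% (1 SE) between cohorts — which is why
  recovery is judged against the cohort's *planted* truth-table folds, with
  the nominal fold targets checked exactly at the preset-arithmetic level.

What it deliberately does **not** emulate: optics (point-spread functions,
spectral bleed-through — the staining panel shows minimal bleed), 3-D tissue
context (all measurements are 2-D profiles), autofluorescent erythrocytes,
staining-batch effects, or irregular real-world compartment shapes. Passing
tests therefore demonstrate the *algorithms* recover known truth under
realistic noise — not that any specific biological dataset would behave
identically.

Default problem sizes (package choices, config-exposed): a 2 × 2 mm default
section at 1 µm/px carrying ~500 planted control cells; cohorts of one
1.2 × 1.2 mm section per patient; repeated-seed experiments use 0.7 mm
sections so twenty cohorts stay cheap. Real studies analysed >1,500 cells
per patient; fold recovery and test calibration do not depend on that scale
factor.

## Numerical choices and degenerate inputs

* **Coordinates**: origin top-left, x rightward, y downward, µm = pixel
  index × pixel size; cell tables store µm so annotations are
  resolution-independent.
* **Containment**: even-odd rule with half-open edges; nested regions
  resolve innermost-first (smallest containing polygon), ties by annotation
  order; centroids outside every region become `unassigned`. Compartment
  areas are nesting-aware (the epithelium disc is carved out of the
  subepithelium disc, both out of the parenchyma).
* **Connectivity**: 8-connected components, the blob-detection convention;
  ids in raster order of first pixel.
* **Backgrounds**: per section *and* per channel, as the median of tissue
  pixels outside all labelled ROIs dilated by 2 px; corrected intensities
  floor at zero (negative fluorescence is unphysical) with the floored count
  reported; no eligible pixels yields background 0 with a warning.
* **Quotient**: ε = 1 AU in the denominator keeps protein-negative cells —
  which demonstrably exist — in the analysis; ε is config and reported.
  Noise-free recovery analyses use the diffuse mRNA renderer because the
  puncta renderer has irreducible Poisson dot noise.
* **Gates and QC bounds**: gates are strictly-greater; the scRNA QC window
  and the size filter are inclusive on both ends; CPA3 exactly at 1.5 is
  low.
* **Otsu degenerate case**: a constant tryptase channel raises an error
  rather than emitting an arbitrary threshold.
* **Statistics**: Mann–Whitney uses the exact U distribution for groups of
  ≤ 8 without ties, otherwise the tie-corrected normal approximation without
  continuity correction; Kruskal–Wallis is tie-corrected, with Dunn's z and
  Bonferroni adjustment (the Prism convention) for pairs; Spearman is exact
  for n ≤ 9 without ties. Stars follow ns/*/**/***/**** at
  0.05/0.01/0.001/0.0001 (boundary-inclusive).
* **Spatial maps**: Gaussian kernels, default bandwidth 150 µm on a 50 µm
  grid (resolves airway-scale structure); density maps scale to cells per
  grid cell so the grid sums to the cell count; value maps are
  Nadaraya–Watson local means, masked as no-data where kernel mass
  < 10⁻³ cells to avoid extrapolated contours in cell-free space.
* **Chromogens**: Ruifrok–Johnston optical-density deconvolution,
  OD = −log₁₀((I+1)/256), with the published DAB vector and a calibrated
  Vina-green vector matching the generator's forward model; negative
  densities floor at zero; area fractions are immunoreactive tissue pixels
  over total tissue pixels.

## Open design points, decided

* *Intensity semantics*: per-ROI **means**, not integrated sums (sums are a
  trivial transform via area and are available from the table).
* *"Small airway" readout*: the union of airway epithelium and
  subepithelium when a single airway number is needed; per-compartment rows
  are always reported.
* *scRNA split scale*: the 1.5 CPA3 threshold applies to log-normalised
  values — z-scaled values are signed, which would make a 1.5 cut
  implausible.
* *Mast-cell selection*: ≥ 2 of the 4 markers (TPSB2, TPSAB1, MS4A2, CPA3)
  positive; rule and threshold are config and logged.
* *High/low differential test*: Wilcoxon rank-sum with Benjamini–Hochberg,
  ranked by difference of class means; a permutation route exists in the
  test-suite oracles.
* *Mean reads per cell* (a dataset-level sequencing descriptive) is not a
  per-cell filter — it is not expressible as one.
* *Images on disk*: unsigned 16-bit pages, the scanner-native form; the
  generator emits integer AU, and integer content round-trips bit-exactly.
  Pixel size travels in the config, not TIFF metadata.
* *Interfaces*: the package's functions and this vignette are the interface;
  pipelines chain tibble-in/tibble-out verbs (`simulate_section()` →
  `segment_mast_cells()` → `quantify_section()` → `summarize_patient()` →
  `cohort_report()`), and result objects provide `tidy()`/`glance()`/
  `autoplot()` methods.

## Known limitations

2-D profiles under-estimate per-cell totals relative to 3-D volumes; merged
touching cells are counted once (at IPF-like densities this biases density
recovery ~5–8% low, within the validated tolerance); the Vina-green stain
vector is calibrated to the synthetic forward model, so real double-IHC
slides need a slide-calibrated vector; and the kernel bandwidth of the
spatial maps is a descriptive choice — no bandwidth selection is attempted.

## A worked example

```{r example, eval = FALSE}
library(mastmap)
cfg <- study_config()

layout <- make_compartment_layout(2000, 2000, seed = 1)
section <- simulate_section(layout, default_presets()$control, seed = 2)
cells <- quantify_section(section$image, layout, cfg, patient_id = "ctrl_01")
summarize_patient(cells, layout, group = "control")

study <- run_study(seed = 1)
report <- cohort_report(study$summaries)
print(report)
autoplot(value_map(study$cells[study$cells$patient_id == "ipf_01", ],
                   "quotient"))
```
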
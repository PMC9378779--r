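# mastmap

Single-cell spatial quantification of mast-cell carboxypeptidase A3 (CPA3)
mRNA and protein in lung tissue.

## The problem

Mast cells store CPA3 in secretory granules, and chronic lung diseases shift
both how much CPA3 each cell expresses and how many mast cells the tissue
holds. Bulk assays confound the two. `mastmap` decodes them separately from
multiplex-stained slide scans: a tryptase lineage channel defines a
mast-cell mask, which is superimposed unchanged on the RNAscope (CPA3 mRNA)
and immunofluorescence (CPA3 protein) channels, so expression, stored
protein, their per-cell quotient, spatial distribution, and tissue density
are all measured over identical pixel sets. It is written for quantitative
tissue-cytometry users: image analysts reproducing a locked-threshold slide
pipeline, and statisticians consuming the per-cell and per-patient tables it
emits.

The core per-cell statistic is the background-corrected mRNA/protein
quotient

    Q = mRNA_corr / (protein_corr + epsilon),

a turnover indicator: transcription without storage gives high Q, granule
storage without active transcription gives low Q. Around it the package
implements:

- **segmentation** — locked intensity threshold on tryptase (or Otsu),
  8-connected components, inclusive 20–700 µm² size filtration;
- **quantification** — per-section per-channel tissue background
  (median of cell-free tissue), zero-floored corrected means, locked
  high/low gates, centroid-based compartment assignment (airway epithelium
  / subepithelium, pulmonary vessel, alveolar parenchyma), per-patient
  summaries with densities per mm²;
- **spatial maps** — Gaussian-kernel density maps, Nadaraya–Watson quotient
  contour maps, density-weighted expression maps, and Mann–Whitney
  comparisons of pre-determined spatial ROIs;
- **chromogen quantification** — Ruifrok–Johnston colour deconvolution of
  DAB / Vina-green double IHC into immunoreactive area fractions normalised
  to tissue area;
- **statistics** — Mann–Whitney (exact for small groups), Kruskal–Wallis
  with Dunn's post-hoc (Bonferroni, Prism convention), Spearman
  correlations, significance stars, and a cohort report keyed on mean
  patient values;
- **scRNA-seq** — cell QC (genes and UMIs each within 1,000–75,000,
  mitochondrial fraction ≤ 20%), log-normalisation, marker-based mast-cell
  selection (≥ 2 of TPSB2, TPSAB1, MS4A2, CPA3), the CPA3-high/low partition
  at 1.5, and rank-sum marker ranking with BH correction;
- **synthetic data** — generators for sections, cohorts (control/COPD/IPF
  with planted 3×/2×/3.2×/7× effects), brightfield slides and count
  matrices, all with exact ground truth, so every stage is verifiable
  without patient material.

## A worked example

```r
library(mastmap)
cfg <- study_config()

layout  <- make_compartment_layout(2000, 2000, seed = 1)
section <- simulate_section(layout, default_presets()$control, seed = 2)
cells   <- quantify_section(section$image, layout, cfg, patient_id = "ctrl_01")
#> tryptase threshold (fixed): 300 AU
#> size filter [20, 700] um2: removed 0 small, 0 large of 504 ROIs
summarize_patient(cells, layout, group = "control")
#>   compartment          n_cells mean_mrna_corr mean_quotient density frac_high
#>   airway_epithelium         10            107          1.00     250   0
#>   airway_subepithelium      56            106          1.06     438   0
#>   alveolar_parenchyma      398            105          1.10     107   0.0075
#>   pulmonary_vessel          40            118          1.14     430   0.025
```

The segmentation log records the locked 300 AU tryptase threshold and the
inclusive 20–700 µm² size filter (nothing was cut on this section: 504
candidate ROIs, 504 kept). The summary holds one row per anatomical
compartment: the parenchyma of this synthetic control section carries 398
mast cells at 107 cells/mm² with mean corrected CPA3 mRNA ≈ 105 AU against
a planted median of 100 AU, a mean mRNA/protein quotient near 1, and under
1% mRNA-high cells — the control preset's planted values, recovered through
the full imaging pipeline.

```r
study  <- run_study(seed = 1)   # 9 control / 10 COPD / 6 IPF patients
report <- cohort_report(study$summaries)
print(report)
#> <cohort_report> 72 descriptive rows, 48 pairwise tests vs 'control'
#> significant vs control:
#>   compartment          measure        group  p_value   stars
#> 1 airway_epithelium    mean_mrna_corr copd   0.000239  ***
#> 2 airway_subepithelium mean_mrna_corr copd   0.000239  ***
#> 3 alveolar_parenchyma  mean_mrna_corr copd   0.000239  ***
#> 4 pulmonary_vessel     mean_mrna_corr copd   0.00550   **
#> ...
```

Mean patient CPA3 mRNA separates COPD airways and vessels from control
(with COPD protein non-significant), and IPF shows the joint parenchymal
mRNA/protein/density increase — the planted disease structure, recovered
through the full imaging pipeline. `tidy()`, `glance()` and
`autoplot()` methods cover the test and map objects:

```r
autoplot(value_map(subset(study$cells, patient_id == "ipf_01"), "quotient"))
```

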
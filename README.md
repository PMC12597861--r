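# erymorph

Objective morphometry of dyserythropoiesis from imaging flow cytometry
(IFC), for haematology researchers who want the morphological hallmarks of
myelodysplastic neoplasms (MDS) — abnormal and bilobed nuclei, binucleation,
megaloblastoid change, cytoplasmic complexity — as reproducible numbers
instead of smear reads.

IFC captures a brightfield and several fluorescence images of every cell.
`erymorph` turns those image stacks into a per-event feature table and a
per-sample dysplasia report:

* **Masks and features** — eroded brightfield cell mask (M01-style), eroded
  DRAQ5 nuclear mask (M12-style, keeping both lobes of bilobed nuclei),
  cytoplasm = cell − nucleus; areas, aspect ratio and intensity-weighted
  nuclear aspect ratio (ARI = √(λ₂/λ₁) of the weighted second moments),
  focus score, circularity, compactness, a bilobedness score, a
  topographic-prominence lobe counter, bright detail intensity
  (BDI: Σ max(0, I − opening₃(I)), a chromatin-clumping measure), and the
  Haralick texture statistics of the cytoplasm (contrast = Σ(i−j)²P(i,j),
  energy = ΣP², entropy = −ΣP log₂P, homogeneity = ΣP/(1+(i−j)²), variance,
  correlation) from a 32-level symmetric co-occurrence matrix.
* **Gating** — focus/singlet/DRAQ5⁺/artifact QC, the erythroid gate
  CD36⁺/CD45^dim OR CD105⁺/CD45^dim, maturation split (CD117⁺/CD105⁺
  ProEry, CD117⁻/CD105⁺ Baso, CD117⁻/CD105⁻ Mature), the aberrant
  CD36⁻/dim ± CD71⁻/dim gate within Mature, and lymphocyte/granulocyte
  control gates.
* **Dysplasia metrics** — % abnormal nuclei (ARI < 0.8, excluding confirmed
  binucleates), % binucleates (lobe count 2 confirmed by calibrated
  refinement gates), their G1/G2M split from DNA-content windows around the
  DRAQ5 G1 peak (G2/M ≈ 2× the euploid signal), megaloblasts (area > normal
  stage mean + 2SD), nuclear condensation (BDI per µm² of nucleus) and N:C
  ratio.
* **Cohort statistics** — Student's t, paired t, one-way ANOVA, Bonferroni
  correction, Cohen's d.
* **A calibrated synthetic cohort generator** — renders multi-channel
  single-cell images with ground truth for two cohorts whose dysplasia
  fractions follow published MDS and normal-bone-marrow distributions, so
  the entire pipeline is testable by parameter recovery without any data
  download.

## Worked example

Simulate a small two-cohort study, run the whole measurement chain and
compare cohorts:

```r
library(erymorph)

cfg <- simulation_config(n_mds = 8, n_nbm = 6, events_per_sample = 800)
study <- run_study(cfg, seed = 3)

study_recovery(study)[c("abnormal_pct_mds", "abnormal_pct_nbm",
                        "binucleate_pct_mds", "aberrant_pct_mds")]
#> $abnormal_pct_mds
#> [1] 11.51799
#> $abnormal_pct_nbm
#> [1] 9.022702
#> $binucleate_pct_mds
#> [1] 0.8341509
#> $aberrant_pct_mds
#> [1] 6.046753
```

The MDS-like cohort shows ~11.5% of erythroid events with abnormal nuclei
against ~9.0% in the normal cohort, ~0.8% confirmed binucleates and a ~6%
aberrant CD36⁻/dim mature population — each recovering the fractions the
generator injected. `study$summary` is the per-sample metric table (one row
per sample), `study$comparison` the cohort statistics:

```r
dplyr::select(study$comparison, metric, mean_1, mean_2, p_value, cohens_d)[1:3, ]
#> # A tibble: 3 × 5
#>   metric                mean_1 mean_2  p_value cohens_d
#>   <chr>                  <dbl>  <dbl>    <dbl>    <dbl>
#> 1 abnormal_pct          11.5    9.02  0.0808       1.03
#> 2 abnormal_mature_share 68.2   53.3   0.000606     2.49
#> 3 binucleate_pct        0.834   0.433 0.0223       1.42
```

Plots: `plot_maturation(study$features)` (CD105 × CD117 stage scatter),
`plot_ploidy(study$features, fit_ploidy(study$features))` (DNA-content
histogram with G1/G2M windows), `plot_condensation(study$summary)`,
`autoplot(study$comparison)` (effect sizes).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/erymorph.R simulate --out store/ --seed 7 --events 200 --mds 2 --nbm 2
Rscript inst/cli/erymorph.R features --store store/ --out features.csv
Rscript inst/cli/erymorph.R run-all --out results/ --seed 7
```

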
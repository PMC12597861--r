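---
title: "Quantifying dyserythropoiesis from imaging flow cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyserythropoiesis from imaging flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erymorph)
```

## The measurement problem

Dyserythropoiesis — abnormal maturation of red-cell precursors in the bone
marrow — is a defining feature of myelodysplastic neoplasms (MDS), and its
morphological hallmarks (irregular and bilobed nuclei, binucleation,
megaloblastoid change, cytoplasmic abnormalities) are traditionally scored by
eye on stained smears, with well-known inter-observer variability. Imaging
flow cytometry (IFC) captures a brightfield image and several fluorescence
images of every event in a flow stream, so the same hallmarks can be turned
into objective morphometric parameters computed on masks: pixel regions of
interest derived from each channel.

`erymorph` implements that translation end to end for an erythroid panel
(CD71, CD105, CD117, CD36, CD45 and the DNA dye DRAQ5, plus brightfield):

1. **Masks.** The cell mask is an automatic global threshold of the
   brightfield image (cells are darker than the illuminated background),
   keeping the largest connected component and eroding it with a 2 px disc
   so it hugs the cell. The nuclear mask is the thresholded DRAQ5 signal
   restricted to the cell and eroded by 1 px; it deliberately keeps *all*
   thresholded components inside the cell, so both lobes of a bilobed
   nucleus remain part of the nucleus. The cytoplasm mask is cell MINUS
   nucleus, which makes the decomposition exact: cell area = nuclear area +
   cytoplasmic area. Thresholds are computed on log intensities, because
   fluorescence histograms are a near-zero background plus a bright-tailed
   object and the log histogram places the bimodal split in the
   background/object valley rather than inside the object's own bright
   structure.
2. **Features.** Areas in µm² (default pixel scale 0.33 µm/px, the 60×
   configuration); the cell aspect ratio and the intensity-weighted nuclear
   aspect ratio (ARI) from second central moments; a brightfield focus
   score (RMS central-difference gradient over the un-eroded cell mask,
   normalised by mean intensity — the un-eroded mask is essential, because
   the sharp cell boundary carries the focus information); boundary-based
   circularity (mean/SD of boundary-to-centroid distances); compactness and
   a bilobedness score ("symmetry-2") as documented surrogates for
   proprietary equivalents; a topographic-prominence lobe counter; bright
   detail intensity (BDI: residual above a 3 px grayscale opening, a
   chromatin-clumping measure); the six Haralick statistics of a 32-level,
   four-offset, symmetric gray-level co-occurrence matrix of the
   cytoplasmic brightfield; and per-channel intensity sums.
3. **Gating.** The QC cascade (focus → singlets → DRAQ5⁺ → artifact
   removal) followed by the erythroid gate CD36⁺/CD45^dim OR
   CD105⁺/CD45^dim, the maturation split CD117⁺/CD105⁺ ProEry →
   CD117⁻/CD105⁺ Baso → CD117⁻/CD105⁻ Mature, the aberrant
   CD36⁻/dim (± CD71⁻/dim) gate inside Mature, and lymphocyte/granulocyte
   control gates.
4. **Dysplasia metrics.** Abnormal nuclei (ARI below a cutoff, excluding
   confirmed binucleates), binucleates (lobe count 2 refined by rectangular
   gates on symmetry-2/circularity and ARI/compactness), DNA-content ploidy
   windows around the G1 peak, megaloblasts (cell area above the normal
   stage mean + 2SD), the nuclear condensation ratio BDI/nuclear area, and
   the nuclear:cytoplasmic area ratio.
5. **Cohort statistics.** Student's pooled-variance t tests (Welch by
   flag), paired t, one-way ANOVA, Bonferroni correction over the family of
   metrics tested together, and Cohen's d with the df-weighted pooled SD.

## Key parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| erosion radii (cell, nucleus) | 2 px, 1 px | modest shrinkage so eroded masks exclude the halo; 2 px on a ~14 px cell radius removes the boundary band without biting into cytoplasm |
| GLCM | 32 levels, 4 unit offsets, symmetric, per-event min–max quantisation | texture should describe *relative* granularity independent of staining intensity |
| entropy base | log2 | bits; any fixed base works, this one is documented and constant |
| BDI radius | 3 px | structures smaller than the disc count as "detail"; chromatin clumps are sub-resolution (≈2 px FWHM) |
| lobe counting | smooth σ = 1.8 px, prominence ≥ 25% of max | merges chromatin clumps (spacing ≈ 3–5 px) while keeping nuclear lobes (spacing ≳ 10 px) distinct |
| circularity cap | 100 | guards the SD→0 limit of a perfect disc |
| ARI abnormality cutoff | 0.8 (fixed) | the published value, derived as normal-cohort mean − 2SD; `build_reference()` recomputes mean − 2SD when preferred, but the pooled recomputation is contaminated by the abnormal subpopulation itself (it inflates the pooled SD), so the fixed published value is the default for cohort analysis |
| ploidy windows | [0.75, 1.40)× and [1.60, 2.40]× the G1 density mode | G2/M cells carry twice the euploid DRAQ5 signal; the windows are generous relative to an 8% CV |
| gate cutpoints | valleys between the generator's populations on log10(1+x) of *extracted* sums | thresholds live on the measured scale: mask erosion retains only ~70–85% of a cell's total signal, which shifts every population down ~0.1–0.15 log units relative to its true intensity |
| marker transform | log10(1 + x) | standard display transform; keeps zero finite |

All cutpoints are scalar thresholds, not hand-drawn polygons: that is the
price and the benefit of removing the human from the loop — every gate is
reproducible bit-for-bit.

## The synthetic cohort generator

No imaging data are distributed with this package; the generator is a
first-class module that stands in for a two-cohort bone-marrow study and is
itself the test harness for everything downstream. Its defaults encode the
study conditions: 26 MDS-like and 12 normal (NBM-like) samples, 2000 events
per sample (a deliberately reduced acquisition relative to the 50 000-event
protocol being emulated; see *Problem sizes* below), 64×64 px frames at
0.33 µm/px.

Per-sample dysplasia fractions are drawn from truncated normal
distributions whose **truncated mean equals the published cohort mean** and
whose **support equals the published range** (abnormal nuclei: MDS 11.5%
[5.3–19.9], NBM 9.1% [6.1–12.9]; binucleates: 0.9% / 0.4%;
euploid-among-binucleates: 58.4% [26.3–92.8] / 34.8% [0–82.3]; aberrant
population: present in 23/26 vs 3/12 samples with cohort means 6.2% /
0.3%). The location parameter is solved numerically so truncation does not
bias the mean, and the SD defaults to range/6. Draws are
**quantile-stratified** by default: each sample receives one draw from a
distinct equal-probability stratum (in random order), so the finite cohort
realises the calibrated distribution instead of wandering by O(sd/√n).
Stratified draws are not exchangeable, so null-calibration studies of the
statistics layer use `stratified = FALSE`; that iid mode is the correct
null for a t test and is what the type-I calibration test exercises.
Within a sample, label counts are exact (e.g. `round(fraction × n)` events
are made abnormal, placed across maturation stages by the calibrated stage
distribution — MDS 15.1/18.3/66.6% for ProEry/Baso/Mature), so recovery
error measures the *pipeline*, not label-assignment shot noise.

Rendering choices worth knowing about:

* **Brightfield texture is granule density, not noise amplitude.** Because
  the co-occurrence matrix is quantised per event between the in-mask
  minimum and maximum, a pure amplitude change cancels out of the Haralick
  features. Cytoplasmic complexity is therefore modelled structurally, as
  sparse dark granules (blurred point absorbers) whose *density per cell
  pixel* is the texture parameter — MDS erythroid 0.014, NBM 0.008,
  lymphocytes 0.0015, granulocytes 0.025, identical across groups for the
  two control lineages. More granules mean more intensity transitions and
  higher contrast/variance, which is exactly the published direction.
* **Chromatin is a clump field.** DRAQ5 is a soft nuclear base plus
  sub-resolution Gaussian clumps; the clump mass fraction (the condensation
  parameter) rises with maturation (0.20 → 0.35 → 0.50), is attenuated
  (×0.6) in MDS megaloblasts (the nuclear–cytoplasmic asynchrony being
  modelled) and boosted (×1.3) in the aberrant population. The integrated
  DRAQ5 signal is proportional to DNA content with an 8% CV. Clumps carry
  intensity, so they add noise to intensity-weighted shape moments; the
  clump field is kept dense (one clump per ~6 nuclear pixels) precisely so
  the ARI of a round normal nucleus stays well above the 0.8 cutoff.
* **Nuclear shape classes are separated on purpose.** Normal nuclei draw
  axis ratios in [0.88, 1.0]; abnormal nuclei are either elongated (ratio
  0.40–0.62) or indented (two unequal overlapping lobes); binucleates are
  two clearly separated equal lobes sized to fit inside the cell. The
  classes are disjoint in ARI by construction, which reflects the biology
  being modelled (an "abnormal" label is a shape statement) and makes
  recovery errors attributable to the measurement chain.
* **Artifacts are rendered per class** — defocus (σ = 3 px blur), doublets
  (two touching cells), cropped cells (centred at the frame edge),
  apoptotic events (quarter-intensity DRAQ5) — so each QC step has a real
  population to remove.
* One RNG stream per sample is derived from the master seed; any sample
  regenerates independently and the whole run is deterministic given
  (config, seed).

What the generator does **not** emulate: optical point-spread realism,
spectral spillover between channels, side scatter, staining batch effects,
instrument drift, or the long-tailed debris continuum of real marrow.
Passing recovery tests therefore demonstrates that the measurement chain is
faithful under controlled morphology — not that the fixed default cutpoints
would transfer to a real instrument, where gates would be placed on the
observed distributions.

## Replacing the manual steps

Two steps of the emulated workflow are interactive in the original form and
are made algorithmic here:

* **Binucleate confirmation.** The lobe counter alone yields a mixture of
  real binucleates and abnormally shaped nuclei. Confirmation uses
  rectangular gates on the two published axis pairs (symmetry-2 versus
  circularity, then ARI versus compactness). Rather than hand-drawing
  them, `calibrate_binucleate_gates()` sets each interval to the
  0.2–99.8% quantile box (expanded 10%) of labelled true binucleates on a
  dedicated calibration sample rendered with enriched binucleate content;
  the calibrated bounds are kept in the study object for audit.
* **Abnormal-nucleus cutoff.** Fixed at the published 0.8 by default, with
  the reference-derived mean − 2SD available via `build_reference()`.

## Numerical choices and degenerate inputs

Degenerate features return `NA` (never silent zeros) and propagate to empty
CSV cells: empty masks, zero total weight, zero marginal SD in the
co-occurrence correlation, zero denominators in per-sample metrics (the
count columns are retained so a zero is distinguishable from missing). Ties
on intensity plateaus in the lobe counter are broken by an infinitesimal
deterministic ramp; peak prominence is computed by a 24-level threshold
sweep (granularity ≈ 4% of the peak height, far below the 25% prominence
cutoff). Grayscale morphology runs on [0, 1]-normalised crops (opening
commutes with positive scaling). The provisional G1 peak in QC and the
ploidy G1 peak are density modes (`stats::density`, n = 512). Percentages
use strict inequalities on the abnormal side of every cutoff.

## Problem sizes

The acceptance-grade study runs 26 + 12 samples × 2000 events at 64×64 px —
about 77 000 rendered and fully measured events, roughly 8–10 minutes on
one CPU. 2000 events per sample keeps per-sample binucleate counts (~10–15)
in the same regime as the emulated study while keeping the full run
routinely repeatable; unit tests use samples of 100–800 events. The type-I
calibration runs 200 null replicates at the metrics level (parameter draws
only), because its subject is the statistics layer, not the renderer.

## Known limitations

* The compactness, symmetry-2 and lobe-count definitions are documented
  surrogates for undisclosed commercial counterparts; they are contracts of
  this package, not claims of bit-equivalence.
* Default gate cutpoints are calibrated to the generator's populations; on
  real data every cutpoint in `gating_config()` should be re-placed against
  the observed log-intensity distributions.
* The binucleate refinement gates assume a labelled calibration sample; on
  real data that means a hand-labelled gallery, reintroducing one manual
  (but auditable and one-off) step.
* Doublet nuclei are not segmented per cell; doublets are removed at QC,
  never analysed.
* CD117⁺/CD105⁻ events do not belong to the published maturation scheme;
  they are labelled `Ambiguous` and excluded from stage statistics.
* Per-event min–max quantised contrast is sensitive to cytoplasm rim
  thickness: cells whose cytoplasm is a thin ring (high-N:C lymphocytes,
  small mature erythroblasts) score high because boundary-gradient pairs
  dominate the co-occurrence mass. Group comparisons within a lineage are
  unaffected (the artifact is identical in both cohorts), but absolute
  contrast values should not be compared across lineages with very
  different N:C ratios.
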
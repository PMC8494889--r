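# sncascreen

Analysis pipeline for a reporter cell-line high-throughput drug screen
targeting **alpha-synuclein (SNCA) transcription**. Increased *SNCA* gene
dosage drives Parkinson's disease pathology, which makes transcriptional
down- (or up-) modulators of the endogenous locus a therapeutic and
tool-compound target. The screening cell line couples luciferase to the
endogenous *SNCA* promoter, so luminescence tracks transcription; a
counter-screen line carries the same reporter at a random genomic site and
exposes pleiotropic transcriptional effects.

The package owns every computation of the analysis chain:

- **Plate model** — validated 384-/96-well plate tables (long CSV),
  fixed control layouts, per-plate QC.
- **Hit calling** — per-plate fold change normalization to untreated
  controls, a symmetric hit band `1 ± k·σ̂` from the pooled control
  fold-change SD (`k = 4`; e.g. SD 0.0825 → offset 0.33, bounds
  0.67/1.33), replicate-consensus classification into
  activator / inhibitor / inactive.
- **Viability** — resazurin ratios and live/dead-count fractions over a
  0.25–40 µM dose series; rule-based toxic/non-toxic verdict
  (either assay below threshold at ≤ screen dose), applied to inhibitors
  only.
- **qPCR quantification** — efficiency-corrected relative expression with
  multiple reference genes,
  `R = E_t^ΔCT_t / geomean_r(E_r^ΔCT_r)`, `ΔCT = CT_ctrl − CT_treated`;
  reduces exactly to `2^(−ΔΔCT)` for one reference at efficiency 2.
- **Protein quantification** — ICW/WB signals normalized to loading
  references (CellTag700, actin, Lamin B1) and to the vehicle mean, with
  per-batch handling and background subtraction.
- **Statistics** — one-way ANOVA and Dunnett's many-to-one test computed
  from first principles: the family-wise adjusted p comes from the joint
  max-|t| null via nested adaptive quadrature over the shared control
  variate and pooled SD (unbalanced designs via
  `λ_i = sqrt(n_i/(n_i+n_0))`), with a seeded Monte-Carlo validator.
- **Triage** — the staged cascade (hits → toxicity → screening-line qPCR →
  counter-screen specificity → wildtype qPCR → protein confirmation) with
  a per-compound append-only audit trail.
- **Synthetic data** — a generator for every input table with known ground
  truth (re-randomized compound placement, log-normal well noise, Hill
  toxicity, CT shifts), used to validate the pipeline end to end.

## Worked example

A 200-compound screen with three specific activators, two pleiotropic
activators and seven inhibitors (five cytotoxic) spiked in:

```r
library(sncascreen)

ids <- sprintf("C%03d", 1:200)
fc <- rep(1, 200); specific <- rep(TRUE, 200); ic <- rep(NA_real_, 200)
fc[1:3] <- c(1.8, 1.6, 1.5)                  # specific activators
fc[4:5] <- 1.7; specific[4:5] <- FALSE       # pleiotropic activators
fc[6:12] <- 0.55; ic[6:10] <- 2              # inhibitors, five cytotoxic
effects <- effect_model(ids, true_luc_fc = fc, specific = specific,
                        toxic_ic = ic)
bundle <- generate_validation_bundle(effects, noise_model(seed = 101))

records <- normalize_run(bundle$screen)
(threshold <- estimate_control_sd(records, k = 4))
#> <hit_threshold> control SD 0.0645 (n = 66), k = 4, offset 0.258, bounds (0.742, 1.258)
table(call_hits(records, threshold)$classification)
#> activator inhibitor  inactive
#>         5         7       188

report <- run_triage(bundle)
report
#> <triage_report> 200 compounds called; 12 primary hits; 5 final candidate(s)
#>   candidates: C001, C002, C003, C011, C012
```

The threshold is four standard deviations of the pooled untreated-control
fold changes around 1, so at this seed's control SD (0.0645) compounds
beyond 0.742/1.258 are hits; all 12 spiked effects are recovered. The
cascade then removes the five cytotoxic inhibitors at the toxicity stage
(`report$exclusion_log` records `"toxic at or below assay concentration"`
per compound), the two pleiotropic activators at the counter-screen stage,
and confirms the rest through wildtype qPCR and both protein assays — the
final candidates are exactly the three specific activators plus the two
non-toxic, specific inhibitors.

## The analysis workflow

Numbered drivers under `analysis/` run the same machinery at full study
scale (1649 compounds, 3 replicate experiments on 15 plates each, defaults
in `analysis/00_config.R`) and write their tables under `results/`:

| script | step |
|---|---|
| `01_simulate.R` | generate all input tables + separate ground truth |
| `02_hit_calling.R` | normalization, 4×SD threshold, hit table |
| `03_viability.R` | toxicity verdicts for the inhibitor hits |
| `04_qpcr.R` | LUC (A1/A6) and wildtype SNCA expression ratios + Dunnett |
| `05_protein.R` | ICW/WB fold changes + Dunnett |
| `06_triage.R` | full cascade, audit trail, candidate list |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

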
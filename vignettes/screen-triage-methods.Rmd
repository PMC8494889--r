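---
title: "Methods: reporter-screen hit calling, qPCR quantification and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-screen hit calling, qPCR quantification and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncascreen)
```

## The problem

`sncascreen` analyses a luciferase reporter cell-line drug screen for
modulators of alpha-synuclein (*SNCA*) transcription. The screening line
carries a luciferase cassette fused to the endogenous *SNCA* locus, so
luminescence tracks *SNCA* transcription; a counter-screen line carries the
same reporter at a random genomic position, so compounds that move both
reporters are pleiotropic transcriptional modulators rather than
*SNCA*-specific ones. The package implements the full analysis chain: plate
normalization and hit calling, viability-based toxicity filtering,
efficiency-corrected relative qPCR quantification, protein-signal
normalization, many-to-one significance testing, and the staged triage that
produces the final candidate list. A synthetic-data generator emulates the
whole study design with known ground truth, which is how the pipeline is
validated end to end.

## Plate model and normalization

Screens run on 384-well plates (16 × 24; 96-well supported) with controls in
a fixed layout and compounds re-randomized across the three replicate
experiments to avoid well-location artifacts. Every well's signal is divided
by the mean signal of its own plate's untreated-control wells
(`normalize_plate()`), which cancels any per-plate multiplicative factor
(reagent age, reader gain, cell density): fold changes are comparable across
plates by construction, and the per-plate mean of control fold changes is
exactly 1. Validation demands at least 3 usable untreated controls per
plate; wells with missing signals are retained and flagged rather than
silently dropped, and excluded from all statistics.

Vehicle (DMSO) wells are a separate control class: the primary screen
normalizes to untreated controls, while the validation assays (qPCR,
protein) normalize to DMSO; `control_type` selects the reference per run.

## Hit threshold: k standard deviations of the control fold changes

The hit rule is a symmetric additive band around the unit ratio,

$$\text{bounds} = 1 \pm k \cdot \hat\sigma_{\text{ctrl}}, \qquad k = 4,$$

where $\hat\sigma_{\text{ctrl}}$ is the sample SD (n − 1 denominator) of the
untreated-control fold changes pooled across every plate of the run. Pooling
gives one global cutoff for the screen, matching how a single printed offset
(e.g. 0.33 at control SD 0.0825) describes the whole campaign; per-plate SDs
would imply per-plate cutoffs. The offset is read on the linear fold-change
scale — the printed cutoff arithmetic (1 ± 0.33) only works as an additive
offset, so a log-scale band is deliberately not used. "More than" the cutoff
is strict: a fold change exactly on a bound is inactive.

Replicate consensus is configurable (`mean`, `majority`, `all`); the default
compares the mean fold change over the three replicates to the bounds, which
is the least noisy single-number summary. A control SD of zero produces a
degenerate (1, 1) band with a warning — every non-unit compound is then a
hit, which is exactly the behavior wanted for noise-free validation data. A
band whose lower bound would be ≤ 0 is an error: such a threshold is
meaningless for positive ratios.

## Viability and the toxicity verdict

Two readouts over a 0.25–40 µM dose series: a bulk resazurin assay
(mean treated / mean vehicle signal, clamped to [0, 1] with a warning) and
per-well live/dead counts (live / (live + dead)). A compound is toxic when
viability falls below the threshold in **either** assay at **any** tested
concentration at or below the screen's treatment concentration; doses above
the screen dose are ignored, since toxicity beyond the tested dose cannot
have confounded the screen signal. The OR-combination is the conservative
choice for excluding toxic compounds. The threshold defaults to 0.70, the
conventional cytotoxicity bound (ISO 10993-5 style); it is a parameter, not
a measured constant. No dose-response curve is fitted — the verdict is
rule-based on measured points, because the decision does not need an IC50
and a Hill fit would add fragility on 5-point series.

Toxicity filtering applies to inhibitors only: a cytotoxic compound trivially
lowers a viability-coupled reporter signal, so inhibition cannot be
interpreted without it, whereas an activating signal cannot be produced by
cell death. Activators therefore pass the filter unconditionally (flagged
ones with a logged note).

## qPCR: efficiency-corrected ratios with multiple reference genes

Relative expression uses the efficiency-corrected ratio

$$R \;=\; \frac{E_t^{\Delta CT_t}}
  {\left(\prod_{r=1}^{m} E_r^{\Delta CT_r}\right)^{1/m}},
  \qquad \Delta CT = CT_{\text{control}} - CT_{\text{treated}},$$

with per-gene amplification efficiency $E \in (1, 2.2]$ (default 2, i.e.
perfect doubling, since no standard curves are assumed) and the reference
genes aggregated by geometric mean. The ΔCT orientation control − treated
makes an up-regulated target (earlier threshold crossing) give $R > 1$,
matching how activator fold increases are plotted. With one reference and
$E = 2$ everywhere the ratio reduces exactly to the classic
$2^{-\Delta\Delta CT}$. Technical replicates are averaged on the CT scale —
CT is the measured quantity and this is the dominant field convention.
Useful invariants, all tested: adding a constant to every CT leaves every
ratio unchanged; the ratio is invariant under permutation of the reference
genes; it is strictly increasing in the target ΔCT and decreasing in each
reference ΔCT.

The reporter assays use UBC + GUSB as references; the wildtype *SNCA* assay
uses UBC + HPRT1 + GUSB.

For significance testing the package also computes per-sample ratios
(`relative_expression_samples()`): each sample against the mean control CTs,
so the vehicle samples scatter around 1 and form the control group of the
many-to-one test.

## ANOVA and Dunnett's test, owned

Every significance claim runs through one-way ANOVA (α = 0.05) followed by
Dunnett's many-to-one comparison against the vehicle group. Both are
implemented from first principles. The Dunnett family-wise adjusted p-value
needs $P(\max_i |T_i| \le q)$ under the joint null of the $k$ statistics

$$T_i = \frac{\bar X_i - \bar X_0}{S\sqrt{1/n_i + 1/n_0}},$$

which are correlated through the shared control mean and pooled SD
($\lambda_i = \sqrt{n_i/(n_i + n_0)}$; no equal-n assumption). Conditioning
on the standardized control mean $z$ and the pooled scale $u = S/\sigma$
factorizes the probability into a double integral

$$P = \int_0^\infty f_U(u) \int_{-\infty}^{\infty} \varphi(z)
  \prod_i \left[\Phi(b_i(z, qu)) - \Phi(a_i(z, qu))\right] \, dz \, du,$$

evaluated by nested adaptive quadrature to absolute tolerance 1e−8 (well
inside the 1e−6 the results need). Because the product depends only on the
*distinct* group sizes, equal-size treatments collapse to a power of one
factor, so a family of hundreds of equal-n comparisons costs no more than
one — this is what makes Dunnett testing over a whole screen's survivor set
practical. A seeded Monte-Carlo evaluator of the same tail
(`dunnett_prob_mc()`) validates the quadrature; with one treatment group the
adjusted p equals the pooled two-sample t-test p to machine precision.
Two-sided comparisons are the default, and star binning uses the
0.05 / 0.01 / 0.001 / 0.0001 ladder (a 0.1 first rung appears in some figure
legends but contradicts the stated α = 0.05; 0.05 is used and the ladder is
configurable).

On perfectly noise-free validation data the pooled within-group variance is
zero and no t statistic exists; the triage's significance helper then falls
back to exact mean comparison (any difference counts as significant, equality
as not), which is the correct limit of the test as noise vanishes and is what
lets zero-noise round trips run through the same code path.

## Protein quantification

Target signals are divided by their loading reference (actin or Lamin B1 on
blots, the CellTag700 whole-cell stain in In-Cell Westerns) and then by the
mean vehicle ratio, so the vehicle group's mean fold change is exactly 1 and
the result is invariant to scanner gain. For the ICW, the mean of the
secondary-antibody-only background wells is subtracted per channel *before*
the loading division (subtract-then-divide; the alternative order is not
scale-consistent for an additive background), with sub-zero signals clamped
to 0 under a warning. Fold changes are computed within each membrane/plate
batch before pooling, since loading references are only comparable within a
blot.

## The triage cascade

`run_triage()` chains the stages: hit classes → toxicity filter (inhibitors
only) → reporter qPCR in the screening line (Dunnett-significant and
direction-concordant) → counter-screen specificity → wildtype *SNCA* qPCR →
protein confirmation. Specificity requires a significant screening-line
response **and** a counter-screen ratio inside an inactive band; the band is
1 ± k·SD of the counter-screen's own vehicle sample ratios when at least
`min_band_controls` (default 6) are available, else a configured fallback
(default 0.8–1.25). Protein confirmation requires both ICW and WB to show a
significant, direction-concordant change (`protein_rule = "either"`
relaxes this). The follow-up entry set can be capped per class by potency
rank — ranking by |mean fold change − 1| is a documented utility choice, the
original potency ranking being unstated. The cascade requires candidates to
pass *both* the screening-line and the wildtype qPCR stages (neither
supersedes the other), a documented assumption.

Each compound's verdicts are append-only: a compound excluded at stage *s*
carries `NA` for all later stages, survivors at each stage are a subset of
the previous stage's, and exclusion reasons plus survivors add up to the
hits entering triage. Given identical inputs and configuration the report
(and its serialized JSON/CSV form) is byte-identical.

## The synthetic-data generator

The generator is first-class, tested code and defines the validation
conditions. Its defaults emulate the study design: 384-well plates, three
replicate experiments, compound placement re-randomized per replicate,
controls at fixed addresses. Parameters the study does not print were fixed
once at values realistic for this assay class and are documented as
generator parameters, not study facts:

| parameter | default | meaning |
|---|---|---|
| `well_cv` | 0.08 | log-normal multiplicative well noise (CV); screens are multiplicative, hence log-normal, and CV parameterization is scale-free |
| `plate_factor_sd` | 0.10 | SD of log per-plate scale factor; cancelled by normalization |
| `ct_sd` | 0.15 | additive CT noise in cycles, typical SYBR triplicate scatter |
| `count_n` | 500 | cells counted per live/dead well |
| untreated controls/plate | 22 | layout block, with 8 vehicle + 2 positive wells |
| base signal | 1000 counts | arbitrary scale, cancelled by normalization |

Well signals are `base × plate_factor × true_fold_change × lognormal(cv)`
(mean-1 noise, so normalized fold changes are unbiased); viability follows a
descending Hill curve `1/(1 + (c/IC)^slope)`; live counts are binomial at
the true viability; treated target CTs sit `log_E(fold change)` cycles below
base. Counter-screen tables silence compounds flagged `specific` and leave
pleiotropic ones active. Ground truth is always emitted separately from the
assay tables so pipeline code cannot read it by accident. The seed is
mandatory, every generator restores the caller's RNG state, and each
generator draws from its own derived sub-stream so tables can be regenerated
independently.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial plate artifacts (edge effects, dispenser
striping), signal drift within a run, compound fluorescence interfering with
the readout, heteroscedastic CT noise at high CT, and partial toxicity
confounding of the reporter signal below the toxicity threshold. The
round-trip guarantees are about the correctness of the computations, not
about robustness to artifact classes the model excludes.

## Validation strategy and problem sizes

The test suite validates three layers: forced-arithmetic unit cases per
operation; property-style invariants over generated cases under fixed seeds
(normalization scale invariance, threshold monotonicity, ΔCT shift
invariance, Dunnett p dominance and family-size monotonicity, stage
nesting); and end-to-end acceptance runs. The end-to-end suite uses a
500-compound, 3-replicate screen for exact zero-noise round trips, 100 seeds
of 500 compounds at 5% well CV for operating characteristics (spike recall
at true fold change 1.6; inert-compound false positives compared against the
control wells' own exceedance under the same bounds, a two-proportion test
that avoids a hypersensitive analytic 4-sigma tail), 1000 random CT tables
for the Livak equivalence, a (k ∈ {2,3,5}) × (n ∈ {5,10}) grid at 10⁶
Monte-Carlo draws for the Dunnett quadrature, and 100 seeds of 10 compounds
for effect-size recovery in the reported 1.4–2.0 (mRNA) and 1.3–2.0
(protein) ranges. These sizes keep every layer's evidence at the resolution
the corresponding claim needs while staying fast enough to run routinely.
The `analysis/` scripts run the same machinery once at full study scale
(1649 compounds, 15 plates × 3 replicates).

## Known limitations

- The hit threshold's additive band becomes asymmetric in log-space; for
  screens with very large control CVs a multiplicative band would be more
  natural, but is not what the printed cutoff arithmetic describes.
- Efficiency defaults to 2.0 per gene; no standard-curve estimation is
  provided, only per-gene overrides.
- The ANOVA gate means a stage with many null compounds and one strong hit
  relies on the omnibus test passing first; with hundreds of groups this is
  essentially always the case when any real effect exists.
- The triage assumes one screen concentration; dose-dependent triage (e.g.
  confirming at multiple doses) is out of scope.
- Image segmentation for the live/dead counts, primer/construct design, and
  DNA-methylation analysis are outside the package: counts and CT values are
  consumed as given inputs.
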
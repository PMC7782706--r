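---
title: "Methods: multimodal analysis of PV interneuron Patch-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal analysis of PV interneuron Patch-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvpatchseq)
```

## Scope and data model

`pvpatchseq` implements the computational stages of a Patch-seq workflow for
hippocampal parvalbumin (PV) interneurons: cells are patch-clamped (yielding
voltage- and current-clamp sweeps), morphologically classified (vertical or
horizontal axo-axonic, basket, and bistratified types, plus an SST-OLM
control type), and single-cell RNA-sequenced (yielding a gene × cell TPM
matrix). The package consumes TPM matrices and metadata tables — alignment
and quantification are upstream and out of scope — and provides quality
control, differential-expression gating, gene selection, classification
protocols, reference mapping, CAM similarity, an age-transition detector,
and an electrophysiology feature extractor.

Expression is stored in **linear TPM** at rest; logarithms are applied
per-operation. This is deliberate: every threshold in the pipeline (0.6 TPM
expressed cutoff, TPM > 15 testing gate, TPM > 32 variable-gene cutoff) is
stated in linear units, and keeping one canonical scale avoids silent
double-transformation. Duplicate gene symbols (several transcript IDs
collapsing to one symbol) are summed at read time. When an expression matrix
and a metadata table are aligned, the metadata order wins, because the
transition detector sorts cells by the metadata age column.

## Quality control

For each cell two library metrics are computed: the number of unique genes
detected and the number of aligned reads. Cells more than three median
absolute deviations below the cohort median *on either metric* fail.
The MAD is **unscaled** — `median(|x - median(x)|)` — with no 1.4826
normal-consistency constant, since the rule is a rank-based fence, not a
variance estimate. Aligned-read counts are not recoverable from a TPM
matrix; `qc_metrics()` substitutes total TPM mass and flags the
substitution in its output attribute. QC is applied per declared cohort:
cells from different regions can be filtered against their own medians.

## Differential expression and gating

Genes enter testing only if expressed at TPM strictly above 15 in at least
five cells *pooled* across the two groups being compared (the per-group
reading of this rule is a documented alternative; pooled was chosen because
the rule exists to guarantee the test has data to work with, which pooling
does). The two-sample test is pluggable — the default is a two-sided
rank-sum test on log2(TPM + 1), with Welch's *t* on the same scale as an
alternative — because the gating logic, not the test internals, is the
contribution here; results are labeled with the test used. The fold
difference is `log2((mean_a + 1) / (mean_b + 1))` on linear-TPM means, with
the 1 TPM pseudo-value keeping the ratio finite for silent genes. A gene is
flagged DE only when |logFD| > 1 **and** BH-adjusted p < 0.05; strong
significance at 1.5-fold is deliberately not enough. Benjamini–Hochberg is
the FDR procedure throughout the package.

## Gene selection

Six strategies sit behind `select_genes()`, all deterministic and invariant
to cell order, all returning a ranked set of (by default) 150 genes with
alphabetical tie-breaking:

* **chi2** on log2(TPM + 1) — class-wise expression totals against their
  expected share under the class proportions. The +1 pseudocount keeps
  zeros at zero; the score requires non-negative features, which the log
  scale preserves.
* **mutual_info** and **anova_f** on the binary expressed indicator. The
  binarization cutoff is 0.6 TPM, the same cutoff as the transition
  detector: no value is stated for these selectors upstream, and using one
  cutoff for "expressed" everywhere keeps the package self-consistent. The
  choice is recorded in the result's metadata.
* **reference_list** — a supplied panel intersected with the matrix, order
  preserved.
* **correlated_with_reference** — the genes with maximal |Pearson r| (log2
  scale) against any reference gene, the reference genes themselves
  excluded; constant genes score 0 rather than erroring.
* **rate_adjusted_variable** — genes on the low-detection-rate /
  high-expression frontier: with `d` the fraction of cells above 32 TPM and
  `m` the mean log2 TPM over those cells, a gene is selected when
  `d < exp(-1.5 (m - b)) + 0.02`. The functional form (decay 1.5, rate
  floor 0.02) is a reconstruction of the cited approach, not a reprint, and
  both constants are arguments. The prescribed bisection on `b` has a
  closed form — a gene enters the selection as soon as
  `b > m + log(d - 0.02)/1.5` — so the implementation ranks genes by that
  threshold directly; the result is identical to bisection but exact.

## Balanced random-forest protocol

`balanced_rf_accuracy()` asks whether two cell classes are separable:
each of 100 repeats randomly downsamples the larger class to parity, draws
a stratified 80/20 split, trains a fresh 100-tree forest on log2(TPM + 1),
and scores the held-out cells, so that 50% is the no-difference baseline.
Forest hyperparameters beyond tree count are the implementation defaults
(mtry = sqrt(genes), fully grown trees) and are recorded in the result.
Per-cell accuracy is defined as the fraction of a cell's *test-set
appearances* that were classified correctly — the natural conditioning,
since a cell contributes no information about generalization when it is in
training.

One property of this protocol deserves emphasis: the 50% baseline is an
expectation over datasets. Conditional on a *single* finite null dataset
(60 cells, 200 genes), chance multivariate separability gives the
protocol mean an intrinsic spread of a few percentage points that more
repeats cannot remove, because repeats only resample splits of the same
cells. The calibration tests therefore check a band (45–55%) rather than a
point.

`svm_rfe()` ranks genes by iteratively training a linear SVM on
log2(TPM + 1), scoring by absolute hyperplane weight, and dropping the
lowest 20% until 50 genes remain. Multi-class problems are handled
one-vs-rest with max-|weight| aggregation, chosen because it keeps a gene
that strongly separates *any* class.

## Reference mapping

`knn_map()` places each query cell at the component-wise median of the
embedding coordinates of its k = 10 nearest reference cells, with
correlation distance (1 − Pearson r on log2(TPM + 1)) over a caller-chosen
gene set. k is an argument because no canonical value exists; the median
(not mean) makes the mapped position robust to one aberrant neighbor and
guarantees it lies inside the neighbors' bounding box. Ties at the k-th
distance break by reference cell order, making the map deterministic.
Because query and reference datasets can differ in sequencing depth by
orders of magnitude, a Spearman option is exposed rather than guessing a
depth harmonization.

## CAM similarity

`cam_similarity()` computes between-type similarity as the mean pairwise
Pearson correlation of cells on a CAM (synaptic cell-adhesion molecule)
panel, after `cam_expression_filter()` keeps CAMs expressed (> 0.6 TPM) in
at least three PV cells. Correlations use log2(TPM + 1) by default (a
linear option exists). Diagonal entries average within-type pairs
*excluding* self-pairs: self-correlations are identically 1 and would bias
the diagonal upward. The CAM panel itself is an input, not shipped: it is a
curated catalogue from the literature, and users supply their own list.

## Transition detection

The detector asks, gene by gene, whether binary expression state switches
at some age. Cells are ordered by age; a gene is "expressed" above 0.6 TPM
(strictly); genes expressed, or not expressed, in fewer than six cells are
ineligible. For an eligible gene the statistic is the maximal loss of Gini
impurity `1 - sum(p_i^2)` over candidate split points, where the loss of a
split is the parent impurity minus the size-weighted mean impurity of the
two sides.

Candidate splits are restricted to boundaries **between different ages**.
A per-cell sliding window would depend on the arbitrary order of cells
sharing an age, which is unreproducible; restricting candidates to age
boundaries makes the statistic invariant to within-age permutation. The
null distribution respects the same structure.

Significance is calibrated by Monte Carlo: holding the number of expressed
cells fixed, arrangements are drawn uniformly at random (100,000 per
expressed count, cached across genes) and the maximal loss recomputed.
Because the statistic depends on the arrangement only through the expressed
counts per age block, the simulator draws those counts directly from
sequential hypergeometrics — an exact, vectorized equivalent of permuting
the vector. Simulated p values carry an add-one correction,
`(1 + exceedances) / (1 + n_sims)`, so they are never exactly zero. An
`enumerate` mode computes the exact fraction over all `choose(n, k)`
arrangements (practical to n ≈ 20) and serves as the oracle for the
simulator in the tests; it reports the uncorrected exact fraction.

Detected genes are gated at BH FDR < 0.10 by default; both raw p and FDR
are always reported, and a flag allows gating on raw p instead, since both
gates appear in practice. Direction is "up" when the expressed fraction
after the split exceeds the fraction before. Results are ordered by
transition day.

## Electrophysiology features

`extract_features()` returns ten named parameters per cell.

Passive (from a 5 mV voltage-clamp step through series resistance `R_s`
into the parallel `R_in`–`C` membrane): the peak transient gives
`R_s = ΔV / I_peak`; the steady state gives the total access
`R_s + R_in = ΔV / I_ss`, and the reported input resistance is that total
minus `R_s`. Capacitance integrates the transient charge
`Q = ∫(I − I_ss) dt` and divides by ΔV; because the transient is filtered
through `R_s`, the raw `Q/ΔV` systematically underestimates `C` by
`(R_in / (R_s + R_in))^2`, so the reported value applies the inverse
correction (the raw value is kept as an attribute). Without the correction
a 10/90 MΩ divider would bias `C` by 19%, which the 2% round-trip
requirement on simulated sweeps cannot absorb.

Active: spike detection uses a dV/dt ≥ 20 V/s onset criterion with a 1 ms
refractory period (a conventional criterion; none is canonical). The F-I
curve (spike count over the 1.5 s step) is fit with a three-parameter
logistic `F = Fmax / (1 + exp(-(I - I0)/s))` by bounded least squares,
initialized from data quantiles; the firing threshold is the x-intercept of
the chord through the 20% and 80% amplitude points, which for an exact
logistic is `I0 - (5/3) ln(4) s` in closed form — the tests hold the fit to
that formula. dF/dI is the OLS slope over the window from 50 pA above the
first spiking step to 250 pA beyond that. Attenuation is the first/last AP
amplitude ratio on the maximal step (so values above 1 mean decline). Sag
is the late-window median minus the early-window minimum on the −150 pA
step, with the conventional windows (750–1000 ms, 1500–2250 ms) as
defaults; these windows exceed a 1.5 s step, so the sag step is rendered
longer and the windows are arguments. Single-AP shape metrics (amplitude =
peak − trough, half-width, base width, symmetry from the 20% crossings)
come from the peak-aligned average of all APs in the first trace containing
at least three; traces with fewer are excluded. Which ten quantities count
as "the ten parameters" is a documented choice — the Methods of such
studies enumerate more measurable quantities than ten — and base width and
trough amplitude are emitted as auxiliary columns rather than dropped.

## Synthetic data

`simulate_expression()` generates the study conditions the pipeline is
tested under: five PV types plus SST-OLM (default sizes 7/9/11/31/9/10,
matching a realistic cohort), ages uniform on integer postnatal days
P10–P77, per-gene log-normal baselines (mean log2 TPM 4, gene spread 1),
per-cell log2 noise (SD 0.5), and Bernoulli dropout (10%). Noise is
log-normal-on-TPM rather than negative-binomial-on-counts because the
pipeline consumes TPM and every threshold acts on TPM. DE genes scale one
type's mean by a planted fold; transition genes are on/off with planted
pre/post expression probabilities at a planted onset age, with "on" draws
clamped above the binarization cutoff. Ages are sampled on integer days
with replicates allowed, which deliberately exercises the within-age-tie
rules of the detector. What this generator does *not* emulate: UMI/count
noise, doublets, ambient RNA, batch structure, or genuinely graded (rather
than binary) developmental expression — so passing recovery tests shows the
statistics are correctly calibrated under their own assumptions, not that
real tissue is this clean.

`simulate_sweeps()` renders sweeps from the same RC model the extractor
inverts, with spikes placed at regular intervals at the logistic rate
(count = `round(F(I) · duration)`), a triangular AP template with optional
linear amplitude accommodation (making attenuation ground truth analytic),
a Gaussian sag bump of configured amplitude, and optional Gaussian voltage
noise (off by default; no empirical noise magnitudes exist to copy, so the
level is a knob, not a claim). It is not a conductance-based membrane
model.

## Numerical choices and problem sizes

Gini losses are compared with a 1e-12 tolerance so floating-point equality
ties are treated as ties. The Monte Carlo null uses 100,000 arrangements
per expressed count. The test suite exercises: the full simulate-vs-
enumerate grid for all n ≤ 12 and every 1 ≤ k < n at 100,000 draws; the
balanced-RF null baseline at 30+30 cells × 200 genes × 100 repeats;
transition recovery at 40 cells spanning P10–P40 with a planted P21 switch
among ≥ 50 null genes plus 20 all-null replicate datasets; and passive
ephys recovery over a grid of (R_s, R_in, C). These sizes were chosen so
the whole suite runs in minutes on one CPU while keeping Monte Carlo
standard errors well inside the tolerances being checked.

## Known limitations

* The rank-sum DE stand-in does not model count dispersion; it is a
  deliberate replacement for NB-GLM machinery, labeled in the output.
* The per-dataset spread of the balanced-RF null baseline (above) means a
  single unlucky dataset can sit a few points off 50% with no bug present.
* The detector models transitions as binary state switches; genuinely
  graded expression changes are better served by level-based methods and
  are out of scope.
* The ephys extractor assumes the protocol sidecar timing is trustworthy
  and performs no bridge-balance or capacitance-artifact compensation.
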
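---
title: "Methods: fragmentomic copy-number profiling of cell-free DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentomic copy-number profiling of cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedure implemented by `fragcnv`,
the default parameter values and why they were chosen, what the bundled
simulator does and does not emulate, and the limitations of the approach.

## 1. Signal model

Cell-free DNA (cfDNA) fragments are nucleosome-protected apoptotic
degradation products. Two consequences drive the pipeline:

- the fragment-length distribution is a nucleosome ladder — a dominant
  mononucleosome mode near 167 bp and progressively weaker multiples near
  334, 501, and 668 bp — with tumor-derived fragments shifted shorter;
- regional copy-number alteration in the tumor changes the *relative* density
  of tumor-informative fragments over the altered region, in proportion to
  the tumor fraction of the plasma sample.

For a sample with tumor fraction $t$ and window $b$ with accessibility
weight $w_b$ and tumor copy ratio $r_b$, the expected fragment density is

$$\mathbb{E}[\text{density}_b] \propto w_b \,\bigl((1 - t) + t\, r_b\bigr).$$

A loss ($r_b < 1$) depresses, and a gain ($r_b > 1$) inflates, counts in the
altered windows relative to each sample's own total. Everything downstream
works on those per-window counts.

## 2. Pipeline stages and parameter choices

### 2.1 Size gates and size classes

`gate_scheme()` partitions the library-molecule length axis at
100 / 400 / 585 / 825 / 5500 bp. These boundaries isolate the mono-, di-,
and trinucleosome ladder rungs plus a long tail; the
`preset = "electropherogram"` variant adds a 130 bp adapter offset so the
same gates can be read off an electrophoretic trace of adapter-ligated
libraries. Gate membership is half-open on the right, lengths outside
[100, 5500] are unclassified, and per-sample gate percentages use all
fragments as denominator so the four gates of a fully in-range sample sum
to 100. `compare_paired_gates()` tests per-gate percentage differences
between paired libraries with a Wilcoxon signed-rank test (at least six
pairs required — below that the test has no power at conventional levels).

The classifier uses a different, intra-mononucleosomal partition,
`size_classes()`: **short** 100–150 bp and **medium** 151–220 bp. Short
fragments are enriched for tumor-derived molecules; medium fragments cover
the mononucleosome mode. Longer fragments carry little tumor signal and are
excluded from counting (tallied in an `excluded` attribute for QC).

### 2.2 Region features

`make_bins()` tiles the target region with uniform windows, 5 kb by default
(the last window may be truncated). The packaged target,
`region_preset("chr18q")` = chr18:18,500,000–80,373,285 (12,375 windows at
5 kb), covers the 18q arm recurrently lost in colorectal cancer; any region
can be substituted. A fragment is assigned to the window containing its
midpoint $\lfloor(\text{start}+\text{end})/2\rfloor$ — midpoint assignment
makes each fragment count exactly once and is insensitive to fragment
length. The default feature is the combined short+medium count per window,
normalized to counts per million class-qualifying in-region fragments (CPM)
so samples with different sequencing depths are comparable; `separate` and
short/medium `ratio` layouts are available.

### 2.3 Region selection

`correlation_filter()` removes redundant windows before classification.
Windows are processed in consecutive batches of 1000 (a compute bound: the
full feature set would need a correlation matrix with ~10^8 entries); within
a batch, each window's score is its mean absolute Pearson correlation with
the other batch members, and windows scoring above 0.7 are removed in a
single pass. Constant windows get score 0 and are kept (they are harmless to
a shrinkage classifier and removing them would silently change the feature
space). The threshold 0.7 removes near-duplicates while keeping windows that
merely share the cohort-level depth trend; an iterative mode re-filters
until fixpoint. A rank-sum `differential_test()` post-filter is available
but off by default — with small cohorts it is noisy, and the classifier's
shrinkage already tolerates uninformative features.

### 2.4 Classification and evaluation

`fit_lda()` fits two-class linear discriminant analysis with a shrunken
pooled covariance

$$\hat\Sigma = (1-\alpha)\, S + \alpha\, \mathrm{diag}(S),$$

where $S$ is the maximum-likelihood pooled covariance (dividing by $n$, so
the fit is invariant to duplicating the training set at fixed $\alpha$) and
$\alpha$ defaults to the Schäfer–Strimmer estimate, which balances the
sampling variance of the off-diagonal entries against their magnitude. With
dozens of samples and thousands of windows, $p \gg n$: unshrunken LDA is
singular and the function refuses it explicitly. Scores are reported as
$\mathrm{posterior} = \mathrm{logit}^{-1}(x^\top\beta + \beta_0)$ with
$\beta = \hat\Sigma^{-1}(\mu_1-\mu_0)$ and the intercept centered at the
midpoint of the class means (adjusted by the log prior odds).

`evaluate_classifier()` reports the confusion matrix at a posterior
threshold (default 0.5), sensitivity and specificity as percentages rounded
to one decimal, a per-stage breakdown with stages I and IIA additionally
combined into an early-stage sensitivity, a per-location breakdown
(proximal/distal split at the splenic flexure), the full ROC curve, and the
rank (Mann–Whitney) AUC with ties counted 0.5 — equivalent to the normalized
Wilcoxon statistic and independent of any threshold.

### 2.5 GC-bias quantification

Library conversion chemistry biases which fragments survive into the
sequenced library. `gc_windows()` computes GC content in 150 bp windows
(fine enough to resolve local GC, wide enough for a stable fraction);
ambiguous bases are excluded from numerator and denominator, and
all-ambiguous windows are dropped with a message. `stratified_gc_sample()`
draws 3000 windows total, equally across ten 5%-wide GC gates spanning
[15%, 65%) (the observed range of the genome model), so the regression
design covers the GC axis evenly instead of mirroring the genome's GC
histogram. `coverage_vs_gc()` then regresses per-window fragment-midpoint
coverage on GC fraction by ordinary least squares and reports slope,
intercept, and Pearson r. A flat r under bisulfite chemistry relative to
native or enzymatically converted libraries quantifies the depletion of
GC-rich fragments.

## 3. What the simulator emulates — and what it does not

`simulate_cohort()` exists so that every pipeline property can be tested
end-to-end with a known ground truth. Its design choices:

- **Genome model.** A smoothed random-walk GC track rank-mapped to
  [0.15, 0.65], and per-window sampling weights log-linearly coupled to GC
  (coupling 1.5, log-normal noise sd 0.1). The coupling matters: real
  sequencing coverage correlates positively with GC, and without it no
  chemistry could show a positive coverage–GC regression to be flattened by
  bisulfite.
- **Lengths.** A Gaussian mixture at 167/334/501/668 bp with geometrically
  decaying weights (ratio 0.28) and sd 25; tumor-derived components are
  shifted −20 bp.
- **Copy number.** One altered block (default: 5% of windows at copy ratio
  3) mixed by tumor fraction as in Section 1. The classifier is never told
  where the block is.
- **Chemistry.** Fragment survival
  $\exp(-\lambda_{len}\max(0, \ell-250) - \lambda_{gc}\,g)$, with presets
  WGS (0, 0), WGES (2·10⁻⁴, 0.1), WGBS (4·10⁻³, 1.5). Two mechanisms make
  chemistry consequential for classification, not just for length profiles:
  a per-sample log-normal multiplier on the λs (sd 0 / 0.1 / 0.5) modeling
  batch-to-batch conversion variability, and conversion depth loss —
  `n_fragments` is interpreted as input molecules, so harsher chemistry
  yields fewer sequenced fragments and noisier counts.
- **Cohort design.** Defaults: 24+24 training and 12+12 test samples,
  20,000 input molecules per sample over a 10 Mb region at 5 kb (2000
  windows), tumor fraction 0.2, stages drawn from a fixed mix dominated by
  early stages, locations uniform over eight colorectal segments. These
  sizes are the package's own choice: large enough that signal recovery is
  reliable and chemistry orderings emerge, small enough that a full cohort
  simulates in seconds.

Not emulated: sequence-level reads, alignment artifacts, CpG-context-specific
conversion damage, subclonal copy-number heterogeneity, focal events,
non-tumor covariates (age, inflammation), or between-individual nucleosome
positioning differences.

## 4. Reproducibility

Every stochastic function takes an explicit `seed` and restores the caller's
RNG state, so pipeline runs are bit-reproducible and independent of call
order. `run_pipeline()` writes a self-describing run directory — features,
selection table, model coefficients, ROC, metrics JSON, GC regression JSON,
and a run log with a config hash and seed.

## 5. Limitations

- LDA assumes a shared covariance across classes; strongly heteroscedastic
  cohorts would favor quadratic or regularized logistic alternatives.
- The correlation filter is batch-local: correlated windows in different
  batches are never compared, which is a deliberate compute bound, not a
  statistical optimum.
- CPM normalization removes depth but not GC bias from the features; a
  GC-correction step on counts (e.g. LOESS by window GC) is out of scope.
- Sensitivity/specificity from a 12+12 test split carry wide binomial
  confidence intervals; single-run point estimates should not be
  over-interpreted, which is why the test suite asserts orderings across
  replicates rather than single values.
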
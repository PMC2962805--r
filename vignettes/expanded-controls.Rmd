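---
title: "Expanding a GWAS control group with external reference samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanding a GWAS control group with external reference samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(expandctrl)
```

## The problem

A case-control genome-wide association study is often limited by its
control count. Public repositories hold genome-wide genotypes for many
reference cohorts and disease collections, so in principle the control
group can be expanded for free. The catch is population structure: if the
external samples are not genetically matched to the study population,
allele-frequency differences between cohorts masquerade as disease
associations, and the naive expanded-control test becomes anticonservative
— its false-positive error rate can exceed its nominal level several-fold
at divergences as small as those between European subpopulations.

`expandctrl` implements a correction pipeline and the simulation machinery
to characterize it:

1. **IBS**: pairwise identity by state over all samples (cases,
   within-study controls, external cohorts) from a genome-wide panel,
   `IBS_ij = 1 - sum_k |G_ik - G_jk| / (2 N_ij)`, where `G in {0, 1, 2}`
   counts minor alleles and `N_ij` is the number of SNPs non-missing in
   both samples.
2. **MDS**: classical (Torgerson) multidimensional scaling of the
   distances `1 - IBS` yields axes of genetic variation, ordered by
   eigenvalue.
3. **Axis selection**: a forward search retains the axes associated with
   phenotype (1-df likelihood-ratio test, `P < 0.05`) among the leading
   `t_max` (default 3).
4. **Adjusted trend test**: a logistic regression
   `logit P(D_i) = a + b_k G_ik + sum_t c_t x_it z_t` with the retained
   axes as covariates; the likelihood-ratio test of `b_k = 0` is the
   structure-adjusted trend test, and `exp(b_k)` estimates the allelic
   odds ratio.

Three tests are compared throughout: `T_CC` (cases vs within-study
controls), `T_F` (cases vs the expanded control group, unadjusted), and
`T_Fmds` (expanded group, adjusted).

## The generative model

The simulator reproduces a specific study design: a source population
contributing cases and controls, plus `J` external cohorts whose allele
frequencies have drifted from the source. Divergence is parameterized by
`F_ST` through the Balding-Nichols model: a SNP with source frequency `q`
has cohort frequency drawn from `Beta(q(1-F)/F, (1-q)(1-F)/F)`, with mean
`q` and variance `F q (1-q)`. `F = 0` is treated as the exact point mass
at `q` (the Beta parameters are undefined there), and draws near 0 or 1
are kept as-is — strongly diverged cohorts can be near-monomorphic, and
the pipeline must tolerate that.

Disease risk follows a multiplicative model at a single test SNP:
penetrances `f0, f0 g, f0 g^2` for 0/1/2 risk alleles, with `f0` solved
from the prevalence `K` by HWE-averaging. Cases are drawn from
`P(G | D)`, controls from `P(G | not D)` — controls are explicitly
unaffected rather than population samples; at `K = 0.001` the difference
is negligible but the ascertainment is kept exact. External samples are
unphenotyped, so their test-SNP genotypes are plain HWE at the diverged
frequency regardless of the disease model.

Defaults mirror the study conditions the package characterizes: 100 cases,
100 controls, three external cohorts of 100; a 10,000-SNP structure panel
with source MAF uniform on [0.05, 0.5]; prevalence 0.1%; test-SNP
frequency 0.2. The test SNP is never part of the structure panel, so the
correction is not contaminated by the marker under test. The published
error-rate tables do not state the test-SNP frequency for the null runs;
the package defaults it to 0.2, matching the power runs, and it is
configurable.

```{r}
cfg <- sim_config(fst = 0.1, disease = disease_model(het_grr = 1))
d <- simulate_replicate(cfg, seed = 1)
d
```

## What one replicate looks like

```{r}
mds <- classical_mds(ibs_matrix(d$null_genotypes), t_max = 3)
res <- run_three_tests(d, mds = mds)
res[, c("test", "beta", "odds_ratio", "statistic", "p_value", "n_axes")]
attr(res, "selection")
```

With three external cohorts the structure occupies up to three axes;
selection retains only those correlated with phenotype. When none is
retained, the adjusted model is identical to the unadjusted one and
`T_Fmds` reproduces `T_F` exactly — by construction, not approximately.

## Error rate and power drivers

`estimate_error_rate()` and `estimate_power()` run independent replicates
(simulate, IBS, MDS, select, test) and summarize rejection rates at
`alpha = 0.05`, mean and 5-/95-percentile allelic odds-ratio estimates,
degenerate-replicate counts, and how often an axis beyond the third is
used. `fst_grid()` maps either over a divergence grid, reproducing the
layout of the published tables; `sensitivity_analysis()` re-runs the
pipeline under alternative axis-selection strategies (`P < 0.1`, all
leading axes, `t_max = 10`).

```{r, eval = FALSE}
fst_grid(sim_config(disease = disease_model(het_grr = 1)),
         fst_values = c(0, 0.01, 0.1), n_reps = 1000, base_seed = 1)
```

Replicate `i` of a run draws its seed from `(base_seed, i)` through an
integer hash, so runs are reproducible bit-for-bit, any execution order
gives identical summaries, and a single replicate can be re-run in
isolation. Replicates with a monomorphic test SNP are reported as
degenerate non-rejections (`P = 1`) and tallied, never redrawn — silent
redrawing would bias the null calibration.

## Numerical and design choices

**IBS kernel.** For complete matrices, genotypes are packed into two bit
planes per sample (`g >= 1` and `g == 2`); the allele-sharing distance of
a pair is then two XOR-and-popcount sweeps, since
`|g_i - g_j| = (A_i xor A_j) + (B_i xor B_j)` holds bitwise. This is exact
integer arithmetic and fast enough to run thousands of replicates of a
500-sample, 10,000-SNP (or 100,000-SNP) panel on one core. Matrices with
missing genotypes take a per-pair masked path with pairwise `N_ij`; a
pair sharing no non-missing SNP is an error naming the pair.

**MDS convention.** Torgerson scaling is applied to squared distances with
double centering; scores are eigenvectors scaled by the square root of
their eigenvalues (the principal-coordinate convention). The scaling is
cosmetic: every downstream likelihood-ratio statistic is invariant to
rescaling any axis. Axes with non-positive eigenvalues (non-Euclidean
noise) are dropped, never imaginary-scaled, so the result may have fewer
than `t_max` columns. Exact eigenvalue ties are broken by the
eigensolver's deterministic order, which is arbitrary but fixed.

**Logistic fitting.** IRLS (via `stats::glm.fit`) with a relative deviance
tolerance of 1e-10 and at most 100 iterations. Quasi-separation is flagged
when a non-intercept coefficient exceeds 15 on the standardized-covariate
scale (`|b| * sd(x) > 15`). The standardized scale is deliberate: MDS
scores have arbitrary units, and a raw-coefficient threshold would make
the flag — and hence axis selection — depend on an axis's scale, breaking
the rescaling invariance the pipeline otherwise has. Flagged fits are
never retained in axis selection and are excluded from odds-ratio
summaries; there is no penalized fallback, keeping the estimator the
plain MLE.

**Forward selection.** Interpreted conditionally: previously retained axes
stay in the null model when the next axis is tested. The marginal reading
(every axis against the intercept-only model) is available via
`method = "marginal"`. The choice matters only when leading axes are
correlated with each other and with phenotype; in the simulated designs
the two agree almost always.

**Dosage coding.** The trend test codes the minor allele as determined in
the combined (merged) sample, recomputed after pooling cohorts. Dominant,
recessive and heterozygote codings are available but not used in the
calibration runs.

**Analytic power.** `analytic_trend_power()` uses the 1-df non-central
chi-square approximation with non-centrality from the standardized
case-control difference in mean dosage under the exact genotype
distributions. It is validated against the package's own simulator (the
two agree within Monte-Carlo error at matched parameters); it is an
approximation, not a second implementation of the test.

## What the tests do and do not show

The test suite re-derives the published operating characteristics at
reduced replicate counts — 250 replicates for the error-rate and power
table cells, 100 for the paired 10k-vs-100k panel comparison, 1,000-2,000
for cheap panel-free checks — with tolerances of three binomial standard
errors at the replicate count actually run. The acceptance script
(`scripts/acceptance.R`) uses 1,000 replicates per condition.

One calibration subtlety: with 100 cases and 100 controls the trend
statistic's chi-square approximation leaves mild discreteness in the
null p-value distribution, which a Kolmogorov-Smirnov test at 2,000
replicates can detect even though rejection rates at conventional levels
are nominal. The suite therefore checks full-distribution uniformity on
the expanded-sample test (n = 500, where the approximation is accurate)
and multi-level tail calibration (1%, 5%, 10%) for the within-study test.

The simulator deliberately omits features of real data: no linkage
disequilibrium between panel SNPs (real panels must be LD-thinned first —
`ld_thin()` exists for that), no genotyping batch effects between cohorts,
no missingness in simulated data, no pleiotropy between the disease under
study and the diseases of external cohorts, and no imputation across
platforms. Passing calibration here shows the structure correction works
against Balding-Nichols-style drift; it does not certify robustness to
assay artifacts, which in real expanded-control analyses can mimic
structure and should be handled the same way (or by stricter QC).

## Known limitations

* Axes can capture extended-LD regions or batch effects rather than
  genome-wide ancestry; adjusting them away can mask true signals in
  those regions. Interpret leading axes before trusting the correction.
* With very large panels the correction resolves ever finer structure,
  and external samples contribute correspondingly less information — the
  trade-off seen when moving from a 10,000- to a 100,000-SNP panel at
  small divergence.
* The within-study design is assumed clean: the correction addresses
  mismatch between the source population and external cohorts, not
  confounding inside the source sample itself.
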
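---
title: "GWAS-preselected marker panels for genomic prediction: models and design"
author: "growsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GWAS-preselected marker panels for genomic prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genomic selection (GS) predicts breeding values from genome-wide markers.
In practice, raising marker density rarely raises prediction accuracy:
adding markers dilutes the signal of the causal variants and inflates the
effective number of parameters. One remedy is to *preselect* variants that
genome-wide association studies (GWAS) flag as trait-associated and to give
them a privileged role in the prediction model — either as the only markers
(a "SIG" panel) or as a separate variance component next to the remaining
chip ("two-kernel" GBLUP, "TK").

growsel implements this complete workflow for two-breed livestock
populations and quantitative growth traits (average daily gain, backfat
thickness, birth weight, body weight): phenotype standardisation, genotype
QC, three GWAS flavours (single-marker mixed model, BayesC window variance,
cross-breed meta-analysis), variant pooling, and cross-validated genomic
prediction, plus a two-breed simulator with known truth so that every stage
is testable without proprietary animal data.

# Phenotype standardisation

Test-station backfat (BFT, mm) and age are recorded when animals reach
roughly 115 kg and are standardised to a common 100-kg live weight:

$$\mathrm{BFT}_{100} = \mathrm{BFT}_{meas} \cdot
  \frac{A}{A + B\,(\mathrm{BW}_{meas} - 100)},\qquad
  \mathrm{AGE}_{100} = \mathrm{AGE}_{meas} - \frac{\mathrm{BW}_{meas} - 100}{CF},
  \qquad \mathrm{ADG}_{100} = \frac{100}{\mathrm{AGE}_{100}}$$

with $CF = c \cdot \mathrm{BW}_{meas}/\mathrm{AGE}_{meas}$ and sex-class
constants $A = 13.47$, $B = 0.1115$, $c = 1.826$ for sires and $A = 15.65$,
$B = 0.156$, $c = 1.715$ for dams. The mapping is the identity at exactly
100 kg and monotone decreasing in body weight; both properties are tested.
Units are enforced (mm, kg, days); ADG is emitted in kg/day. Animals of
unknown sex class are rejected rather than defaulted, and trait summaries
use the sample (n−1) standard deviation with CV% computed from unrounded
mean and SD.

The simulator's `simulateRawMeasurements()` inverts these formulas in
closed form (measured age $= \mathrm{AGE}_{100}/(1 - (\mathrm{BW}-100)/(c\,\mathrm{BW}))$),
so the adjustment stage always runs on realistic raw inputs and the
round-trip is exact to numerical precision.

# Genotype quality control

`qcFilter()` applies rules in a fixed order: (1) drop unmapped or
sex-chromosome SNPs; (2) drop individuals with *more than* 5% missing
genotypes; (3) drop SNPs with call rate *less than* 95%; (4) drop SNPs
with MAF *less than* 1%; (5) optionally drop SNPs failing an exact
Hardy–Weinberg test below 1e-6 (meant for dense, imputed panels). Boundary
semantics follow the printed words: "less than" removes, so values exactly
at a threshold survive. The exact HWE p-value sums the probabilities of all
heterozygote counts no more probable than the observed one, conditional on
the allele counts, using the stable mode-anchored recurrence; it is tested
against a full log-factorial enumeration oracle.

Missing dosages are mean-imputed (replaced by $2p_i$) only when a design
matrix or GRM is built — never persisted. Coordinates are 1-based as in
bim/VCF files; genomic windows are half-open $[\mathrm{start}, \mathrm{end})$.

# Genomic relationships and PCA

The genomic relationship matrix follows VanRaden's first method,

$$G = \frac{ZZ'}{2\sum_i p_i(1-p_i)},$$

with $Z$ the dosage matrix centred by $2p_i$. We read "$p_i$" as the
alt-allele frequency, not the folded MAF — centring by a folded frequency
would be wrong for $p > 0.5$. Frequencies come from the analysis sample
unless supplied. No diagonal blending is baked into the GRM itself; the
prediction code optionally blends $(1-w)G + wI$ (default $w = 0.01$) before
covariance solves, a standard numerical-stability device that is switched
off in the oracle-equivalence tests. Population-structure covariates are
the top-k eigenvectors of the post-QC GRM (the GCTA convention), not a raw
genotype SVD.

# Mixed-linear-model GWAS

Per SNP the model is $y = W\alpha + x\beta + u + \varepsilon$ with
$u \sim N(0, \lambda \tau^{-1} K)$ and $\varepsilon \sim N(0, \tau^{-1}I)$,
$K$ the chip GRM, and $W$ containing intercept, sex, measurement age and
the top five GRM eigenvectors. One eigendecomposition $K = UDU'$ rotates
the model to independent errors; the REML likelihood is profiled over
$\lambda$ on a 100-point grid of $\log_{10}\lambda \in [-5, 5]$ with Brent
refinement (tolerance 1e-6). By default each SNP reuses the null
$\hat\lambda$ (the EMMAX-style approximation, $O(n)$ per SNP); exact
per-SNP re-optimisation is available behind `mode = "exact"` and agrees
with the approximation to within 10% in $-\log_{10}p$ on simulated data.
Tests are two-sided Wald $\chi^2_1$. With $K = I$ the machinery collapses
to ordinary least squares exactly, which is one of the oracle tests.

Significance uses Bonferroni thresholds $0.05/M$ (genome-wide) and $1/M$
(suggestive). The rule is $1/M$ by construction; we do not reverse-engineer
any printed constant that disagrees with its stated panel size. Hits are
strict inequalities ($p <$ threshold). The genomic-control factor is
$\lambda_{GC} = \mathrm{median}(\chi^2)/\chi^2_{1,0.5}$.

# BayesC window-variance GWAS

The BayesC sampler places a point mass at zero with prior exclusion
probability $\pi = 0.999$ and a shared slab variance $\sigma^2_\beta$ on
included effects. Each Gibbs iteration updates fixed effects, then every
SNP in map order — the indicator from its Bernoulli full conditional with
the effect integrated out, then the effect — then $\sigma^2_\beta$ and
$\sigma^2_e$ from scaled-inverse-$\chi^2$ full conditionals (df = 4). The
slab scale derives from a genetic-variance guess via
$\sigma^2_\beta = \sigma^2_g / ((1-\pi)\, 2\sum p(1-p))$; when no guess is
supplied the package's own single-kernel REML provides it. $\pi$ is fixed,
not estimated. The update order is deterministic and the chain uses R's
RNG, so runs are exactly reproducible given a seed. Production-scale
defaults are 50,000 iterations, 40,000 burn-in, thinning 10; tests and the
demo pipeline shorten the chain (e.g. 3,000/1,500), which we verified is
long enough at those problem sizes for stable window rankings.

One subtlety the test suite documents: on pure-noise data the *posterior*
mean model size sits below the naive prior expectation $M(1-\pi)$. The
posterior inclusion probability is $q\,\mathrm{BF}/(1 + q\,\mathrm{BF})$
with $q = (1-\pi)/\pi$; although $E[\mathrm{BF}] = 1$ under the null, that
expectation is carried by a heavy right tail which the saturation at 1
truncates, so $E[\text{model size}] < M(1-\pi)$. The suite checks the
sampler against a direct Monte-Carlo integration of this expression (they
agree closely) and holds the $M(1-\pi)$ anchor only to order of magnitude.

Windows tile each chromosome in consecutive 1-Mb bins by physical
position. Per retained iteration $t$, the window's genomic value is
$g_w^{(t)} = X_w \beta_w^{(t)}$ and its share is
$\mathrm{Var}(g_w^{(t)})/\mathrm{Var}(\sum_w g_w^{(t)})$ across
individuals; `gv_percent` is 100 times the posterior mean of shares
(a ratio-of-posterior-means estimand is available as a switch — the
GenSel estimand is not published, so both are exposed). Because windows
covary, shares can exceed 100% in pathological cases; values are clamped
below at 0 only. Iterations with zero total genomic variance are skipped
and counted. Windows with more than 1% of genomic variance are significant
(strict inequality).

# Cross-breed meta-analysis

Per-breed summary statistics are first allele-harmonized: the reference
effect allele comes from the first study carrying the SNP, swapped-allele
records have their betas sign-flipped, and incompatible allele pairs are
dropped with a count (no strand flipping is attempted). Fixed-effect
inverse-variance pooling then gives
$\hat\beta = \sum w_i \beta_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$,
$w_i = 1/se_i^2$, with a two-sided normal test. SNPs present in one breed
only pass through unchanged (union behaviour, the default, matching a
union-set chip analysis); `commonOnly = TRUE` restricts to shared SNPs.
Thresholds reuse the chip Bonferroni pair. Only the fixed-effect model is
implemented: the inputs are effects and standard errors, so the
sample-size-weighted scheme adds nothing here, and heterogeneity
statistics are out of scope.

# Pooling and annotation

The selection panel is the union of chip mixed-model hits, dense-panel
hits, meta-analysis hits, and every chip SNP inside a significant BayesC
window, each SNP carrying provenance tags (CL/IL/META/CB). Dense-panel
hits absent from the chip are retained but flagged; they participate only
when the prediction genotypes contain them — no LD-proxy search is
attempted, because the two-kernel construction defines its second kernel
as "the remaining chip SNPs", which keeps panel membership unambiguous.
Whether meta-analysis hits belong in the panel is genuinely ambiguous in
the source protocol; they are included by default and excluded by setting
`includeMeta = FALSE` in the pipeline. Positional gene annotation assigns
the containing gene (distance 0) or the nearest gene within a 500-kb flank
via GenomicRanges; distances count base pairs to the gene boundary.
Pathway enrichment is out of scope.

# Genomic prediction

Single-kernel GBLUP is $y = W\alpha + g + \varepsilon$ with
$g \sim N(0, G\sigma^2_g)$; the two-kernel model adds independent
$g_1 \sim N(0, G_1\sigma^2_{g1})$ (preselected SNPs) and
$g_2 \sim N(0, G_2\sigma^2_{g2})$ (remaining chip SNPs), with
$\mathrm{GEBV} = \mathrm{GEBV}_1 + \mathrm{GEBV}_2$ exactly.

Variance components: single-kernel fits use the exact eigen-rotated
profile REML shared with the GWAS null model; multi-kernel fits use
average-information REML with EM fallback whenever an AI step would leave
the parameter space, a floor of $10^{-8}\mathrm{Var}(y)$ on each
component, and convergence at $\max|\Delta\log\theta| < 10^{-8}$ or 100
iterations. Non-convergence flags the result (with the trajectory
attached) instead of throwing. The two routes agree to 1e-4 relative on
single-kernel problems, which is a standing test.

Prediction uses the BLUP identity
$\hat g_k = \sigma^2_{gk}\, G_k[\cdot, \mathcal{T}]\, V^{-1} (y_\mathcal{T} - W_\mathcal{T}\hat\alpha)$
with $V = \sum_k \sigma^2_{gk} G_k[\mathcal{T},\mathcal{T}] + \sigma^2_e I$
over the training set $\mathcal{T}$, rather than Henderson's equations
with $G^{-1}$: the identity is algebraically equivalent and remains valid
when a kernel is singular, which is the normal situation for small
preselected panels. Equivalence with marker-level ridge/SNP-BLUP (Henderson
equations on marker effects) at a matched variance ratio is an oracle test
at relative error below 1e-6.

Accuracy is $\mathrm{GPA} = r(\mathrm{GEBV}, y^*)/\sqrt{h^2}$ where $y^*$
is the phenotype corrected by the *training-fold* fixed-effect estimates
and $h^2$ is the full-data single-kernel chip REML estimate, held fixed
across folds and models so that GPA differences reflect the correlation
only. (Dividing by $h^2$ rather than $\sqrt{h^2}$ would routinely exceed
1, contradicting any plausible reported accuracy, so the standard
definition is used.) Cross-validation is 20 replicates of random 5-fold
partitions by default, reporting the mean and SD over the 100 fold-level
accuracies.

Preselection inside cross-validation deserves care. The default `global`
policy fixes the panel from a full-data GWAS — this is what published
gains of this design reflect, but it leaks test information into
selection, so measured gains are optimistic for new animals. The `refit`
policy re-runs a user-supplied selector inside every training fold and is
the leakage-free protocol. Both are first-class options; the package's
demonstration of the accuracy gain uses `global` and says so.

# The simulator

`simulateGenotypes()` draws ancestral allele frequencies uniform on
[0.05, 0.95], diverges them per breed with the Balding–Nichols beta model
at a target $F_{st}$, and builds within-breed haplotypes as a first-order
Markov chain along each chromosome: a latent Gaussian AR(1) with
correlation `ldRho`, thresholded at the breed allele frequency. This gives
controllable adjacent LD with exact independence at `ldRho = 0`; the
realized genotype $r^2$ is below `ldRho` because thresholding attenuates
the latent correlation. A positive MAF floor guarantees polymorphic output
(rare monomorphic columns at small n are redrawn and counted).
`simulatePhenotypes()` samples sparse QTLs, rescales their effects jointly
so the breeding-value variance hits $h^2 \cdot \mathrm{traitSd}^2$, and
adds sex and age fixed effects; the truth record (QTL positions, effects,
true breeding values, realized $h^2$) feeds recovery tests. One global
seed is split into independent per-stage sub-seeds so each stage is
individually reproducible.

What the simulator does *not* emulate: coalescent LD structure and
long-range haplotypes, selection and pedigree dynamics, genotyping error,
imputation error (the "dense panel" is generated directly), and
chip ascertainment bias. Passing tests therefore demonstrate correctness
of the algorithms and qualitative behaviour (e.g. preselection gains on
sparse architectures), not pig-specific quantitative results. Where the
source protocol's populations had a 153:2704 male:female imbalance, the
simulator defaults to a balanced sex ratio, with the imbalance available
through `sexRatioMale` (≈ 0.054).

# Problem sizes and numerical choices

Desk-scale problem sizes were fixed once: calibration of the mixed-model
scan uses 500 individuals x 20,000 SNPs; BayesC behaviour is checked at
500 x 2,000 with 3,000 iterations; REML recovery at n = 2,000; the
preselection-gain study at n = 1,000, 3,000 chip SNPs, 20 QTLs,
$h^2 = 0.3$, 5 replicates of 5-fold CV; and the end-to-end demo pipeline
at 2 x 800 individuals and 5,000 chip SNPs with a 3,000-iteration BayesC
chain and 3 CV replicates. These sizes are large enough for the
statistical checks they support while keeping a full run on a single CPU
comfortable.

Other numerical decisions: eigenvalues in $[-10^{-8}, 0)$ are clamped to
zero with a count (GRMs are PSD up to round-off); the QC report always
reconciles removed + retained = input; collinear SNPs are emitted with
missing statistics and a flag rather than dropped silently; the BayesC
residual variance has a $10^{-10}$ floor so degenerate constant
phenotypes cannot divide by zero; and all threshold comparisons
(significance, windows, QC) are strict as documented above.

# Known limitations

- The mixed-model scan fits one variance ratio per trait (EMMAX-style) by
  default; strongly structured traits may prefer `mode = "exact"`.
- The meta-analysis assumes independent per-breed studies; overlapping
  samples would require covariance-aware pooling.
- `global` preselection inflates cross-validated gains by construction;
  use `refit` for honest forward prediction estimates.
- The simulator's Markov LD is short-range; methods whose behaviour
  depends on long-range LD (e.g. window methods at much larger windows)
  should be validated on real data.
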
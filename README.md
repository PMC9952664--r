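# growsel

GWAS-preselected marker panels for genomic selection in two-breed livestock
populations.

## What problem this solves

Genomic selection predicts breeding values from genome-wide SNPs, but adding
markers rarely adds accuracy: the signal of causal variants is diluted
across tens of thousands of neutral ones. A widely studied remedy is to
**preselect** variants that genome-wide association studies flag as
trait-associated and give them a privileged role in prediction — either as
the only markers of a GBLUP kernel (the *SIG* model) or as their own
variance component next to the rest of the chip (*two-kernel* GBLUP, *TK*).

growsel implements the full workflow for quantitative growth traits
(average daily gain, backfat thickness, birth weight, body weight) in
two-breed pig-style populations, for breeders and methods researchers who
want a tested, reproducible reference implementation:

1. **Phenotype standardisation** — backfat and age corrected to 100 kg live
   weight with sire/dam constants (A = 13.47, B = 0.1115, CF = 1.826·BW/age
   for sires; 15.65 / 0.156 / 1.715 for dams); ADG₁₀₀ = 100/AGE₁₀₀.
2. **Genotype QC** — call rate ≥ 95%, MAF ≥ 1%, individual missingness
   ≤ 5%, autosomes only, optional exact Hardy–Weinberg filter (p ≥ 1e-6)
   for dense panels; PLINK bed/bim/fam and VCF readers/writers.
3. **Mixed-linear-model GWAS** — per SNP, y = Wα + xβ + u + ε with
   u ~ N(0, λτ⁻¹K), solved by one eigendecomposition of the VanRaden GRM
   K = ZZ′/2Σpᵢ(1−pᵢ) and profile REML over λ; Wald χ²₁ tests; Bonferroni
   thresholds 0.05/M and 1/M.
4. **BayesC GWAS** — Gibbs sampler with π = 0.999 prior exclusion and a
   common slab variance (compiled inner loop), 1-Mb window partitioning of
   genomic variance, windows with %GV > 1% significant.
5. **Meta-analysis** — allele harmonization plus fixed-effect
   inverse-variance pooling across breeds (βᵢ weighted by 1/seᵢ²).
6. **Preselection** — union of hits from all methods with provenance tags,
   window-to-SNP expansion, nearest-gene annotation.
7. **Genomic prediction** — single- and two-kernel GBLUP with AI-REML
   (EM fallback) variance components, GEBV = GEBV₁ + GEBV₂, and
   replicated k-fold cross-validation scoring
   GPA = r(GEBV, y*)/√h² (20 × 5-fold by default).

A two-breed simulator (Balding–Nichols divergence, Markov-chain LD,
sparse-QTL architecture with known truth) makes every stage testable
end-to-end; `runPipeline()` drives the whole chain and emits a
Figure-style accuracy report plus a JSON manifest.

## Worked example

```r
library(growsel)

params <- simParams(nPerBreed = c(300, 300), nSnps = 1200, nChromosomes = 6,
                    nQtl = 15, h2 = 0.4, fst = 0.1, seed = 42)
geno <- simulateGenotypes(params)
sim  <- simulatePhenotypes(geno, params)
sim$truth
#> SimTruth: 15 QTLs, sigma_g2 = 1.6 , sigma_e2 = 2.4 , realized h2 = 0.399

qc  <- qcFilter(geno)
grm <- buildGRM(qc$genotypes)
grm
#> GRM: 600 individuals, 1194 SNPs, denominator 418.677 (freqs in-sample)
#>   mean diagonal 1.0517, mean off-diagonal -0.0018

pca  <- pcaCovariates(grm, k = 5)
W    <- cbind(1, sim$phenotypes$sex == "M", sim$phenotypes$age_days,
              pca$eigenvectors)
null <- fitMlmNull(sim$phenotypes$phenotype, W, grm)
null
#> MlmNullFit: lambda = 0.7935, sigmaE2 = 2.227, h2-like ratio = 0.442

assoc <- testSnps(null, qc$genotypes)
th    <- bonferroniThresholds(nrow(assoc))
hits  <- extractHits(assoc, th)
#> genome-wide threshold 4.19e-05; 5 significant SNPs

panel <- unique(c(hits$significant$snp_id, hits$suggestive$snp_id))
h2    <- remlVarComp(sim$phenotypes$phenotype, W[, 1:3], list(grm))$h2Hat
#> 0.435

crossValidate(qc$genotypes, sim$phenotypes$phenotype, W[, 1:3],
              model = "CHIP", nReps = 3, nFolds = 5, seed = 1, h2 = h2)
#> CvResult [CHIP, global]: 3 x 5-fold, GPA = 0.516 +/- 0.106 (h2 = 0.435)
crossValidate(qc$genotypes, sim$phenotypes$phenotype, W[, 1:3],
              model = "TK", panel = panel, nReps = 3, nFolds = 5,
              seed = 1, h2 = h2)
#> CvResult [TK, global]: 3 x 5-fold, GPA = 0.935 +/- 0.070 (h2 = 0.435)
```

Reading the output: the simulated trait realises h² = 0.399 against the
0.4 target; REML on the chip GRM estimates 0.435. With 15 true QTLs, plain
chip GBLUP reaches a cross-validated accuracy of about 0.52, while the
two-kernel model built on the GWAS-preselected panel reaches about 0.94 —
the accuracy gain that motivates preselection (note this uses the
full-data "global" selection policy, which is optimistic by construction;
see the vignette for the leakage-free `refit` alternative).

The end-to-end driver does all of the above per breed, including BayesC
windows and the cross-breed meta-analysis:

```r
res <- runPipeline(simParams(nPerBreed = c(300, 300), nSnps = 1200,
                             nChromosomes = 6, nQtl = 15, h2 = 0.4,
                             fst = 0.1, seed = 42),
                   nReps = 3, outDir = "pipeline_out")
res$report       # breed x model table of mean ± SD accuracy
```

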
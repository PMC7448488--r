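---
title: "Models and methods in gremlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gremlite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gremlite)
```

gremlite implements the quantitative backbone of a cross-cohort behavioural
GWAS: per-cohort mixed-linear-model association on a log-transformed
phenotype, fixed-effects meta-analysis, LD clumping and gene mapping, a
sum-of-chi-square gene/set association test, and — the headline analysis —
a two-component GREML partition of additive genetic variance between a
candidate gene set's windows and the rest of the genome, calibrated against
gene-length-matched random gene sets. This vignette records the models, the
numerical choices, and the reasoning behind the design decisions that were
genuinely open.

## The phenotype and the association model

The motivating phenotype is cattle flight time — the electronically recorded
time an animal takes to cover a short fixed distance after release — a
standard temperament measure. Raw times are positive and right-skewed, so
the pipeline takes the natural logarithm and standardizes to mean 0,
variance 1 *within each cohort* (`preprocess_phenotype()`), using the
unbiased (n−1) sample variance. Because the transform is affine within a
cohort, all variance *ratios* (heritability, the set fraction below) are
unchanged by the standardization; only the absolute component sizes rescale.

Within each cohort the association model is the standard mixed linear
model

$$ y = X\beta + Zg + \varepsilon, \qquad
   g \sim N(0, G\sigma_g^2), \quad \varepsilon \sim N(0, I\sigma_\varepsilon^2), $$

with fixed effects (intercept, log age, contemporary group) plus the
candidate-variant dosage, and a genomic relationship matrix (GRM)
$G = WW'/k$ built from standardized dosages
$w_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$ (VanRaden scaling; allele
frequencies estimated in the analysis sample, since no external reference
frequencies exist for these populations). `mlma_scan()` estimates the
variance components once under the null model and holds $V$ fixed across
variants, the usual approximation that reduces the scan to one factorization
plus one matrix product; the per-variant effect is the exact GLS estimate
$\hat b = x'Py / x'Px$ with $P$ the $V^{-1}$ projection orthogonal to the
fixed effects. The candidate variant is *not* removed from the GRM by
default (no leave-one-chromosome-out); a `loco = TRUE` toggle exists because
both conventions are common. The non-LOCO default slightly favours
conservatism (proximal contamination deflates, rather than inflates, test
statistics), which matches the genomic-control behaviour the workflow
expects (inflation factors at or just below 1).

## REML

`reml_fit()` maximizes the restricted likelihood of
$V = \sum_i \sigma_i^2 G_i + \sigma_\varepsilon^2 I$ by
average-information (AI) updates. Numerical choices:

* starting values: each component at $\mathrm{var}(y)/(c+1)$ for $c$
  genetic components;
* convergence: absolute change in restricted log-likelihood below `1e-8`,
  at most 100 iterations; a stagnation check (no parameter movement)
  also terminates;
* constraint handling: proposals are bent to a floor of
  $10^{-6}\,\mathrm{var}(y)$; a component *at* the floor whose score is
  negative is frozen out of that iteration's AI system (constrained
  AI-REML). Without the freeze, boundary components cause step-halving
  cycles that waste dozens of likelihood evaluations per iteration;
* step acceptance: an AI step is accepted at step sizes 1, 0.5 or 0.1 if it
  does not decrease the restricted log-likelihood; otherwise one EM step is
  taken (EM is monotone and always defined);
* standard errors: inverse of the AI matrix at the optimum; variance
  ratios by the delta method. A near-singular AI matrix (e.g. an
  identity-like GRM, which makes $\sigma_g^2$ and
  $\sigma_\varepsilon^2$ unidentifiable) flags the fit.

## Meta-analysis, clumping, gene mapping

`ivw_meta()` is a fixed-effects inverse-variance meta-analysis with
per-cohort allele harmonization (effects and frequencies flipped onto the
first-seen orientation; mismatched allele pairs dropped). Genomic-control
correction is available but **off by default**: the target workflow reports
per-cohort inflation factors of at most about 1, and the correction clamps
at $\lambda = 1$, so it would be a no-op on clean data; both modes are
implemented because the original METAL setting is not recorded.
`genomic_control_lambda()` uses the median chi-square over the theoretical
1-df median computed by `qchisq(0.5, 1)` rather than a hard-coded 0.455.
`bh_fdr()` reports Benjamini–Hochberg q-values and the realized FDR at the
chosen significance threshold (the workflow's convention: genome-wide
$P < 5\times10^{-8}$, which corresponded to FDR 0.01 in the motivating
study).

Clumping (`clump()`) is the standard greedy procedure (smallest-p lead,
5-Mb window, $r^2 \ge 0.1$ to the lead, PLINK-style squared Pearson
correlation of mean-imputed dosages in an LD reference panel), with a
deterministic (chromosome, position) tie-break. Candidate genes are
protein-coding genes within 200 kb of the clump's spanned window; the
variant-to-gene mapping used by the set analyses is a closed interval
$\pm$100 kb around gene start/end. Coordinates are 1-based inclusive
internally; BED input/output converts 0-based half-open coordinates in
exactly one code path (`read_annotation_bed()` / `write_annotation_bed()`),
which is unit-tested in both directions because it is the classic silent
off-by-one risk.

The gene/set association test (`set_based_test()`) is the fastBAT-style
sum of squared z-scores over the variants mapped to a window. Its null is
$\sum_i \lambda_i \chi^2_1$ with $\lambda_i$ the eigenvalues of the
variants' genotype correlation matrix; the tail probability is computed by
Imhof's inversion integral, integrated blockwise (blocks of about 50
oscillation periods, stopping when two consecutive blocks are negligible —
a single adaptive pass across the whole oscillatory range is unreliable),
with a Satterthwaite moment-matching fallback if quadrature fails; the
method used is recorded per gene. Eigenvalues below $10^{-8}\lambda_{max}$
are truncated. The default mapping flank for this test is 50 kb
(configurable); the enrichment analysis below always uses the explicit
100 kb convention.

## The two-GRM enrichment model and its permutation null

For a candidate gene set, variants are partitioned into the union of the
set's $\pm$100 kb windows ($k_1$ variants) and the genomic remainder
($k_2$, with $k_1 + k_2 = k$ exactly), and

$$ y = X\beta + Z_1 g_1 + Z_2 g_2 + \varepsilon, \qquad
   g_1 \sim N(0, G_1 \sigma_{g1}^2), \;
   g_2 \sim N(0, G_2 \sigma_{g2}^2) $$

is fitted by REML. The headline quantity is the set fraction of additive
genetic variance $f = \sigma_{g1}^2 / (\sigma_{g1}^2 + \sigma_{g2}^2)$
(the share of *phenotypic* variance is also reported). Because candidate
sets of brain-expressed genes are physically large, $f$ must be calibrated
against random gene sets matched on gene count *per gene-length decile*
(`matched_random_sets()`): deciles are computed by rank over all eligible
protein-coding autosomal genes, each random set reproduces the target's
per-decile counts exactly, target genes are excluded from sampling, and
sets may overlap across replicates. The exclusion has a knowable side
effect: when the candidate set is a large fraction of the eligible gene
pool, replicates are barred from whatever signal the target's own genes
carry and the empirical p becomes anti-conservative. For realistic ratios
(tens of candidate genes against a genome-wide pool) the effect is
negligible, and the null-calibration experiment in the test suite keeps
the ratio in that regime (10-gene sets against 300 genes). Decile-count matching (rather than
total-bp matching) mirrors how such sets are usually characterized; the
realized variant count $k_1$ of every replicate is logged so residual size
bias can be checked. The empirical p-value uses the add-one estimator
$p = (1 + \#\{f_{rep} \ge \hat f\})/(1 + m)$, which can never be zero and
is conservative at the margin. Replicates whose REML fit fails are dropped
and counted; a run losing more than 10% of replicates is flagged invalid.

Two implementation notes. First, every replicate reuses the whole-panel
GRM through the exact identity $kG = k_1 G_1 + k_2 G_2$, so only the (much
smaller) set GRM is rebuilt per replicate. Second, replicate fits warm-start
from the target fit's total genetic variance with a small set share, which
cuts the iteration count roughly in half.

## The synthetic-data generator

Real phenotype/genotype data of this kind are proprietary, so the package
ships a generator whose defaults emulate the study design the methods were
built for, with known truth at every stage:

* **Cohorts**: 3 cohorts of 600 animals. Cohort allele frequencies follow a
  Balding–Nichols $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ model around
  uniform ancestral frequencies with $F_{ST} = 0.1$ — a minimal model of
  the indicine-content divergence visible in the motivating cohorts'
  principal components; realistic demography is out of scope.
* **Genome**: 8,000 variants on 6 autosomes of 40 Mb (about one variant
  per 30 kb). LD comes from a first-order haplotype copying chain whose
  adjacent-site correlation is $\rho^{d/\ell}$ with $\rho = 0.8$ and
  $\ell = 25$ kb — enough local structure to exercise clumping and the
  set test's eigen-null at a fraction of the cost of coalescent
  simulation. The implied $r^2$ at 70 kb is about 0.12–0.29 across
  adjacent-variant spacings, bracketing the reported LD of tropically
  adapted cattle at that distance.
* **Genes**: 500 genes with log-normal lengths (meanlog $\log 2\times10^4$,
  sdlog 1.1 — median 20 kb with a heavy right tail). The focal set of 25
  genes is drawn with weight 10 on the top three length deciles, emulating
  the large physical size of brain-gene sets; its windows cover roughly 3%
  of variants.
* **Phenotype**: 20 causal variants inside the focal windows and 200
  outside; Gaussian effects rescaled *exactly* (not in expectation) so the
  within-window sum of $2p(1-p)b^2$ is $h^2 \times$ share and the rest of
  the genome carries the remainder, with $h^2 = 0.4$ and share 0.30.
  The exact rescaling makes parameter-recovery tests tight. With share 0
  the architecture is purely polygenic — causals are drawn without
  reference to the set, which is what a permutation-null calibration needs.
  Fixed effects (log-age slope 0.2, eight contemporary groups per cohort
  with SD 0.3) are added and the phenotype exponentiated, so the pipeline's
  log-transform step operates on data that genuinely need it.

What the generator does **not** emulate: realistic bovine demography and
recombination maps, sequence-density panels (28 M variants), imputation
error structure, X chromosomes, and the ordinal docility score of
validation cohorts (validation summary statistics are synthesized
directly). Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under a faithful miniature of the study design — not
that the biological conclusions of any particular dataset would reproduce.

## Problem sizes used by the test suite

The suite exercises parameter recovery at the emulated design scale
(3 × 600 animals, 8,000 variants; 20 phenotype replicates, each with a
100-replicate matched permutation test, fitted in one analysis cohort —
mirroring the original workflow, where the two-GRM model was fitted in the
largest cohort). Null calibration runs at reduced scale (one cohort of 120,
900 variants, 200 experiments × 50 replicates) because only the *rank* of
the target among matched replicates is under test there, which is
scale-free. Oracle-equivalence checks (naive-loop GRM, exhaustive clumping,
HWE enumeration for all totals up to 50, closed-form meta-analysis, a
$10^6$-draw Monte-Carlo null for the weighted chi-square, and per-variant
GLS refits) pin the numerics at small sizes where the references are exact.

## Degenerate inputs and edge policies

* All-missing variants: excluded with a warning at frequency computation.
* Monomorphic variants: HWE p-value 1; excluded from standardization
  (zero scale factor) with a warning.
* The imputation-quality filter is strict (`< 0.6` removed, `= 0.6`
  retained); the orthology identity filter is inclusive (`>= 60%`).
* A variant collinear with the covariates (or constant) gets `NA`
  association results with a warning rather than a spurious p-value.
* Validation uses strict `P < 0.05`; a variant at exactly 0.05 does not
  validate.
* The permutation sampling frame for validated-count nulls is the whole
  validation summary, unmatched on allele frequency (nothing in the
  motivating description suggests matching); a MAF-matched mode exists
  because null counts are MAF-sensitive.
* The MAF filter reading: variants with minor allele frequency *below*
  `1e-4` are removed. The threshold is configurable; this is the only
  reading consistent with tens of millions of retained sequence variants.

## Known limitations

* REML ratio estimates at a few hundred individuals are noisy and
  boundary-skewed: single-replicate set fractions can hit 0 or 1; inference
  should always go through the matched permutation null, never the point
  estimate alone.
* The sum-of-chi-square test assumes the LD reference matches the
  association sample; a mismatched reference miscalibrates the eigen-null.
* Fixed-effects meta-analysis without heterogeneity modelling is the
  method under study; between-cohort effect heterogeneity (visible in the
  motivating validation data as sign flips across breeds) is reported via
  the Direction string and the sign-concordance test, not modelled.
* The sign-test construction in the motivating study aggregates cohorts in
  a way that is not fully recoverable from its main text; the package
  reports both per-cohort and pooled exact binomial tests and does not
  attempt to match that specific number.
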
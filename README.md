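# gremlite

Mixed-model GWAS, fixed-effects meta-analysis, and gene-set heritability
partitioning for quantitative behavioural traits — a self-contained R
implementation of the workflow used to ask whether the genetic control of
temperament is shared across species (e.g. whether variants around bovine
orthologs of human psychiatric-disorder risk genes are associated with
cattle temperament).

It is aimed at quantitative geneticists who want the full chain —
variant QC, GRMs, AI-REML, mixed-linear-model association, METAL-style
meta-analysis, LD clumping, gene mapping, a fastBAT-style set test, two-GRM
variance partitioning with a gene-length-matched permutation null, and
replication testing — as ordinary R functions they can test, rerun, and
take apart, plus a synthetic multi-cohort generator with known truth for
every stage.

## The models

Per cohort, the association model is the standard mixed linear model

    y = Xb + Zg + e,   g ~ N(0, G sg2),   e ~ N(0, I se2)

with `y` the within-cohort standardized log phenotype, `X` the fixed
effects (intercept, log age, contemporary groups, candidate-variant
dosage), and `G = WW'/k` the VanRaden genomic relationship matrix over
standardized dosages `w = (x - 2p)/sqrt(2p(1-p))`. Cohort results combine
by inverse-variance fixed-effects meta-analysis; lead variants come from
greedy clumping (P < 5e-8, 5-Mb windows, r² ≥ 0.1).

The headline analysis partitions additive genetic variance between the
±100 kb windows of a candidate gene set (k₁ variants) and the genomic
remainder (k₂):

    y = Xb + Z1 g1 + Z2 g2 + e,   g1 ~ N(0, G1 sg1²),  g2 ~ N(0, G2 sg2²)

and reports the set fraction `f = sg1² / (sg1² + sg2²)`, calibrated
against random gene sets matched on gene count per gene-length decile.
Single-variant contributions are summarized as
`%Vg = 2 p (1-p) b² / Vg × 100`.

## Worked example

```r
library(gremlite)

# a complete synthetic study: 3 diverged cohorts, annotated genome,
# phenotype with 30% of genetic variance in the focal gene-set windows
cfg   <- sim_config(seed = 101)
panel <- simulate_genotypes(cfg)
ann   <- simulate_annotation(cfg)
ph    <- simulate_phenotypes(panel, ann$genes, ann$gene_set, cfg)

# analysis cohort, QC'd
i3  <- which(panel$cohort == "cohort3")
qc3 <- apply_filters(subset_panel(panel, individuals = i3))
ph3 <- ph$phenotypes[i3, ]
y   <- preprocess_phenotype(ph3$flight_time, ph3$cohort)
X   <- model.matrix(~ log(age) + factor(cg), data = ph3)

# two-GRM partition for the focal set, with a 20-replicate matched null
pt <- permutation_test(qc3$panel, y, X, ann$gene_set, ann$genes,
                       n_replicates = 20, seed = 7001)
pt
#> Permutation test of gene-set variance enrichment ( FOCAL )
#> observed set fraction: 0.2213 (k1 = 227 of 7969 variants)
#> matched-replicate mean fraction: 0.0297 over 20 replicates (0 dropped)
#> empirical p = 0.04762
```

The observed fraction (here 0.22; the simulated truth is 0.30, and REML
ratio estimates at n = 600 are noisy) sits far above the matched-set null
mean (0.03 — the share a random, equally length-matched set of genes
captures under a polygenic background), and the add-one empirical p-value
over 20 matched replicates is 1/21 ≈ 0.048. `plot(pt)` draws the
permutation histogram with the observed fraction marked.

The single-variant summary works directly from published table rows:

```r
pct_vg(freq = 0.56, b = -0.089, Vg = 0.259)
#> [1] 1.507131
```

i.e. that lead variant explains about 1.5% of the additive genetic
variance.

`run_pipeline(pipeline_config(...), out_dir)` chains the whole workflow —
QC → GRM → per-cohort scans → meta-analysis → clumping and gene mapping →
set tests → enrichment with permutation null → validation — writing
tab-separated reports and a JSON manifest; identical config and seed give
byte-identical outputs.

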
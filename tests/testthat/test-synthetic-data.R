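# Synthetic-data generator: determinism, divergence, LD, annotation bias,
# and the exact variance bookkeeping of the phenotype model.

test_that("sim_config validates its ranges", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(set_variance_share = 1.2), "set_variance_share")
  expect_error(sim_config(n_variants = 0), "positive")
  expect_error(sim_config(ancestral_maf_range = c(0.2, 0.6)), "maf_range")
})

test_that("identical config and seed give bit-identical studies", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$panel$X, s2$panel$X)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$effects, s2$truth$effects)
})

test_that("fst = 0 leaves no cohort divergence beyond sampling noise", {
  cfg0 <- sim_config(n_cohorts = 2, n_per_cohort = 800, n_chrom = 2,
                     n_variants = 600, fst = 0, ld_rho = 0, seed = 11)
  panel <- simulate_genotypes(cfg0)
  p_by <- sapply(unique(panel$cohort), function(co)
    colMeans(panel$X[panel$cohort == co, ]) / 2)
  expect_lt(mean(abs(p_by[, 1] - p_by[, 2])), 0.03)
})

test_that("Hudson FST on a diverged panel recovers the configured fst", {
  cfg <- sim_config(n_cohorts = 2, n_per_cohort = 1000, n_chrom = 2,
                    n_variants = 5000, fst = 0.1, ld_rho = 0, seed = 12)
  panel <- simulate_genotypes(cfg)
  i1 <- panel$cohort == "cohort1"
  p1 <- colMeans(panel$X[i1, ]) / 2
  p2 <- colMeans(panel$X[!i1, ]) / 2
  n1 <- sum(i1); n2 <- sum(!i1)
  # Hudson estimator, ratio of averages
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  fst_hat <- sum(num[keep]) / sum(den[keep])
  expect_lt(abs(fst_hat - 0.1), 0.02)
})

test_that("ld_rho = 0 gives uncorrelated adjacent variants; ld_rho > 0 does not", {
  cfg0 <- sim_config(n_cohorts = 1, n_per_cohort = 2000, n_chrom = 1,
                     n_variants = 400, ld_rho = 0, fst = 0, seed = 13)
  panel0 <- simulate_genotypes(cfg0)
  adj_cor <- function(panel) {
    X <- panel$X
    mean(sapply(seq_len(ncol(X) - 1), function(j)
      suppressWarnings(cor(X[, j], X[, j + 1]))), na.rm = TRUE)
  }
  expect_lt(abs(adj_cor(panel0)), 0.02)
  cfgL <- sim_config(n_cohorts = 1, n_per_cohort = 800, n_chrom = 1,
                     n_variants = 400, chrom_bp = 1.2e7,
                     ld_rho = 0.8, ld_decay_bp = 25000, fst = 0, seed = 13)
  expect_gt(adj_cor(simulate_genotypes(cfgL)), 0.2)
})

test_that("per-cohort MAF spectra diverge increasingly with fst", {
  ks_stat <- function(fst) {
    cfg <- sim_config(n_cohorts = 2, n_per_cohort = 400, n_chrom = 2,
                      n_variants = 2000, fst = fst, ld_rho = 0, seed = 14)
    panel <- simulate_genotypes(cfg)
    i1 <- panel$cohort == "cohort1"
    maf <- function(idx) {
      p <- colMeans(panel$X[idx, ]) / 2
      pmin(p, 1 - p)
    }
    suppressWarnings(stats::ks.test(maf(i1), maf(!i1))$statistic)
  }
  expect_gt(ks_stat(0.25), ks_stat(0.02))
})

test_that("positions strictly increase within chromosomes", {
  panel <- simulate_genotypes(small_cfg())
  for (ch in unique(panel$map$chrom)) {
    bp <- panel$map$bp[panel$map$chrom == ch]
    expect_true(all(diff(bp) > 0))
  }
})

test_that("gene-length deciles partition genes into equal groups", {
  len <- exp(rnorm(1000, 10, 1))
  dec <- gene_length_deciles(len)
  expect_equal(unname(table(dec)), rep(100L, 10), ignore_attr = TRUE)
})

test_that("focal gene set is biased toward the top length deciles", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 50, n_variants = 500,
                    n_genes = 400, n_set_genes = 40, seed = 15)
  ann <- simulate_annotation(cfg)
  dec <- gene_length_deciles(ann$genes$length)
  focal_dec <- dec[match(ann$gene_set$gene_ids, ann$genes$gene_id)]
  expect_gte(mean(focal_dec >= 8), 0.7)
  # unbiased draw stays near uniform
  cfg_u <- sim_config(n_cohorts = 1, n_per_cohort = 50, n_variants = 500,
                      n_genes = 400, n_set_genes = 40, set_decile_bias = 1,
                      seed = 15)
  ann_u <- simulate_annotation(cfg_u)
  dec_u <- dec[match(ann_u$gene_set$gene_ids, ann_u$genes$gene_id)]
  expect_lt(mean(dec_u >= 8), 0.6)
})

test_that("phenotype truth matches the configured variance architecture", {
  cfg <- small_cfg(h2 = 0.4, set_variance_share = 0.3)
  st <- simulate_study(cfg)
  fr <- compute_freq(st$panel)$freq
  idx <- match(st$truth$causal_variant_ids, st$panel$map$variant_id)
  v <- 2 * fr[idx] * (1 - fr[idx]) * st$truth$effects^2
  expect_lt(abs(sum(v) - 0.4) / 0.4, 0.01)
  in_set <- st$truth$causal_variant_ids %in% st$truth$set_variant_ids
  expect_lt(abs(sum(v[in_set]) / sum(v) - 0.3), 0.01)
  expect_true(all(st$phenotypes$flight_time > 0))
})

test_that("h2 = 0 yields no genetic effects", {
  cfg <- small_cfg(h2 = 0, set_variance_share = 0)
  st <- simulate_study(cfg)
  expect_length(st$truth$effects, 0)
  expect_equal(st$truth$sigma_g2, 0)
})

test_that("a lone causal variant at p = 0.5 gets effect sqrt(2 Vg)", {
  # one gene window holding one variant with p = 1/2; share = 1, h2 = 0.25
  # => 2 p (1-p) b^2 = 0.25 so |b| = sqrt(0.5)
  set.seed(1)
  X <- cbind(rep(c(0, 1, 2, 1), 25), rbinom(100, 2, 0.3))
  panel <- make_panel(X, bp = c(5000L, 900000L))
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 4000, end = 6000,
                      length = 2001, biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  gset <- list(label = "S", gene_ids = "G1")
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 100, h2 = 0.25,
                    set_variance_share = 1, n_causal_in_set = 1,
                    n_causal_background = 0, gene_flank_bp = 1000, seed = 2)
  ph <- simulate_phenotypes(panel, genes, gset, cfg)
  expect_equal(ph$truth$causal_variant_ids, "v01")
  expect_equal(abs(ph$truth$effects), sqrt(0.5), tolerance = 1e-12)
})

test_that("a positive set share with empty windows is rejected", {
  X <- matrix(rbinom(200, 2, 0.4), 50, 4)
  panel <- make_panel(X, bp = c(1e6, 2e6, 3e6, 4e6))
  genes <- data.frame(gene_id = "G1", chrom = "2", start = 10, end = 20,
                      length = 11, biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 50, seed = 3,
                    gene_flank_bp = 100)
  expect_error(
    simulate_phenotypes(panel, genes, list(label = "S", gene_ids = "G1"), cfg),
    "no usable variants")
})
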
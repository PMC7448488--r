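# Clumping, per-variant variance explained, gene-window mapping, orthology
# filtering, and the sum-of-chi-square set test.

sum_from_panel <- function(panel, p) {
  data.frame(MarkerName = panel$map$variant_id, `P-value` = p,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("distant significant variants form separate clumps", {
  X <- sapply(rep(0.4, 2), function(pp) rbinom(100, 2, pp))
  panel <- make_panel(X, bp = c(1e6, 11e6))
  cl <- clump(sum_from_panel(panel, c(1e-10, 1e-9)), panel,
              p_thresh = 5e-8, window_bp = 5e6, r2_thresh = 0.1)
  expect_length(cl, 2)
})

test_that("linked nearby variants join the smaller-p lead", {
  set.seed(41)
  x1 <- rbinom(300, 2, 0.4)
  x2 <- ifelse(runif(300) < 0.95, x1, rbinom(300, 2, 0.4))
  panel <- make_panel(cbind(x1, x2), bp = c(100000L, 101000L))
  cl <- clump(sum_from_panel(panel, c(1e-9, 1e-10)), panel)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members[1], "v02")  # the 1e-10 variant leads
  expect_setequal(cl[[1]]$members, c("v01", "v02"))
})

test_that("greedy clumping matches the brute-force reference", {
  set.seed(42)
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 200, n_chrom = 2,
                    chrom_bp = 6e6, n_variants = 300, ld_rho = 0.9,
                    ld_decay_bp = 60000, seed = 43)
  panel <- simulate_genotypes(cfg)
  p <- runif(300)^4  # plenty of significant variants
  summary <- sum_from_panel(panel, p)
  cl <- clump(summary, panel, p_thresh = 0.01, window_bp = 1e6,
              r2_thresh = 0.2)
  oracle <- clump_oracle(summary, panel, 0.01, 1e6, 0.2)
  got <- lapply(cl, function(x) sort(x$members))
  expect_equal(length(got), length(oracle))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(oracle, paste, "", collapse = ","))
  # membership partitions the significant variants
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_false(any(duplicated(all_members)))
  expect_setequal(all_members, summary$MarkerName[p < 0.01])
})

test_that("percent variance explained reproduces the published worked rows", {
  expect_equal(pct_vg(0.56, -0.089, 0.259), 1.50, tolerance = 0.03 / 1.50)
  expect_equal(pct_vg(0.48, -0.107, 0.259), 2.19, tolerance = 0.03 / 2.19)
  expect_equal(pct_vg(0.222, -0.082, 0.259), 0.90, tolerance = 0.02 / 0.90)
  expect_equal(pct_vg(0.344, -0.072, 0.259), 0.90, tolerance = 0.02 / 0.90)
})

test_that("pct_vg is scale invariant and validates inputs", {
  expect_equal(pct_vg(0.3, 0.2, 0.5), pct_vg(0.3, 0.4, 2))
  expect_equal(pct_vg(0.3, 0, 0.5), 0)
  expect_error(pct_vg(0.3, 0.1, 0), "Vg")
  expect_error(pct_vg(1, 0.1, 0.5), "freq")
})

test_that("candidate genes are collected within the clump flank", {
  genes <- data.frame(
    gene_id = c("NEAR", "FAR", "INSIDE"),
    chrom = "1",
    start = c(1196000, 1250000, 995000),
    end = c(1199000, 1260000, 1005000),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  clumps <- list(list(lead = data.frame(bp = 1000000),
                      members = "v1", chrom = "1",
                      bp_min = 1000000, bp_max = 1000000))
  hits <- map_genes_to_clumps(clumps, genes, flank_bp = 2e5)
  expect_setequal(hits$gene_id, c("NEAR", "INSIDE"))
  expect_equal(hits$distance_bp[hits$gene_id == "NEAR"], 196000)
  expect_equal(hits$distance_bp[hits$gene_id == "INSIDE"], 0)
})

test_that("variant-to-gene windows use closed intervals on both edges", {
  genes <- data.frame(gene_id = "G", chrom = "1", start = 500000,
                      end = 600000, stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = c("at_edge", "inside", "just_out", "other_chr"),
    chrom = c("1", "1", "1", "2"),
    bp = c(400000, 550000, 399999, 550000), stringsAsFactors = FALSE)
  inc <- map_variants_to_gene_windows(variants, genes, flank_bp = 1e5)
  expect_setequal(inc$variant_id, c("at_edge", "inside"))
})

test_that("window incidence matches hand enumeration on a small fixture", {
  set.seed(44)
  genes <- data.frame(gene_id = sprintf("G%d", 1:5), chrom = c("1", "1", "1", "2", "2"),
                      start = c(100, 5000, 9000, 200, 7000) * 1000,
                      end = c(300, 5400, 9900, 800, 7100) * 1000,
                      stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = sprintf("v%d", 1:20),
                         chrom = sample(c("1", "2"), 20, TRUE),
                         bp = sample.int(1e7, 20), stringsAsFactors = FALSE)
  inc <- map_variants_to_gene_windows(variants, genes, flank_bp = 1e5)
  manual <- expand.grid(v = 1:20, g = 1:5)
  hit <- mapply(function(v, g)
    variants$chrom[v] == genes$chrom[g] &&
      variants$bp[v] >= genes$start[g] - 1e5 &&
      variants$bp[v] <= genes$end[g] + 1e5,
    manual$v, manual$g)
  expect_equal(nrow(inc), sum(hit))
  key <- paste(inc$variant_id, inc$gene_id)
  key_manual <- paste(variants$variant_id[manual$v[hit]],
                      genes$gene_id[manual$g[hit]])
  expect_setequal(key, key_manual)
})

test_that("orthology filtering applies identity, biotype, autosome and DDD rules", {
  tbl <- data.frame(
    gene_id = sprintf("G%d", 1:6),
    chrom = c("1", "2", "X", "3", "4", "5"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lncRNA", "protein_coding", "protein_coding"),
    percent_identity = c(60.0, 59.9, 95, 95, 80, 85),
    status = c("confirmed", "confirmed", "confirmed", "confirmed",
               "probable", "confirmed"),
    consequence = c("loss of function", "loss of function",
                    "loss of function", "loss of function",
                    "loss of function", "altered function"),
    phenotype_class = rep("Brain/Cognition", 6),
    stringsAsFactors = FALSE)
  asd <- orthology_filter(tbl, "ASD")
  expect_setequal(asd$gene_ids, c("G1", "G5", "G6"))  # >= 60 kept, X/lnc dropped
  ddd <- orthology_filter(tbl, "DDD")
  expect_equal(ddd$gene_ids, "G1")  # probable status and non-LoF dropped
  expect_error(orthology_filter(tbl[, -4], "ASD"), "percent_identity")
})

test_that("single-variant set test equals the variant's own p-value", {
  rp <- random_panel(200, 3, seed = 45)
  genes <- data.frame(gene_id = "G", chrom = "1", start = 900, end = 1100,
                      stringsAsFactors = FALSE)
  summary <- data.frame(MarkerName = rp$map$variant_id,
                        Effect = c(0.3, 0.1, -0.2), StdErr = 0.1,
                        stringsAsFactors = FALSE)
  res <- set_based_test(summary, rp, genes, flank_bp = 10)
  expect_equal(res$n_variants, 1)
  expect_equal(res$p, pchisq(9, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("weighted chi-square tail handles equal weights and far tails", {
  expect_equal(weighted_chisq_pvalue(9, rep(1, 4))$p,
               pchisq(9, 4, lower.tail = FALSE), tolerance = 1e-12)
  r <- weighted_chisq_pvalue(0, c(0.5, 1, 2))
  expect_equal(r$p, 1, tolerance = 1e-8)
  r2 <- weighted_chisq_pvalue(80, c(0.5, 1, 2))
  expect_lt(r2$p, 1e-10)
})

test_that("weighted chi-square matches a quick Monte-Carlo null", {
  lam <- c(2, 0.7, 0.3)
  set.seed(46)
  draws <- matrix(rchisq(3e5, 1), ncol = 3)
  Tnull <- drop(draws %*% lam)
  for (q in c(3, 8, 15)) {
    mc <- mean(Tnull > q)
    p <- weighted_chisq_pvalue(q, lam)$p
    expect_lt(abs(p - mc), 4 * sqrt(mc * (1 - mc) / 1e5))
  }
})

test_that("empty and degenerate windows are reported as such", {
  rp <- random_panel(100, 4, seed = 47)
  genes <- data.frame(gene_id = c("EMPTY", "OK"), chrom = c("2", "1"),
                      start = c(1000, 1000), end = c(2000, 4000),
                      stringsAsFactors = FALSE)
  summary <- data.frame(MarkerName = rp$map$variant_id,
                        Effect = rnorm(4), StdErr = 0.1,
                        stringsAsFactors = FALSE)
  res <- set_based_test(summary, rp, genes, flank_bp = 100)
  expect_equal(res$method[res$gene_id == "EMPTY"], "empty")
  expect_true(is.na(res$p[res$gene_id == "EMPTY"]))
  expect_equal(res$method[res$gene_id == "OK"], "imhof")
})
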
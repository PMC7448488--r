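# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny hand-controlled panel: dosage matrix supplied directly.
make_panel <- function(X, chrom = NULL, bp = NULL, A1 = "A", A2 = "C",
                       impute_r2 = NULL, cohort = NULL) {
  m <- ncol(X)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  map <- data.frame(variant_id = sprintf("v%02d", seq_len(m)),
                    chrom = as.character(chrom), bp = bp,
                    A1 = A1, A2 = A2, stringsAsFactors = FALSE)
  if (!is.null(impute_r2)) map$impute_r2 <- impute_r2
  genotype_panel(X, map, ids = sprintf("i%03d", seq_len(nrow(X))),
                 cohort = cohort)
}

# A random polymorphic panel (independent variants, HWE).
random_panel <- function(n, m, seed = 1, maf_range = c(0.1, 0.5),
                         cohort = NULL) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  X <- sapply(p, function(pp) rbinom(n, 2, pp))
  make_panel(X, cohort = cohort)
}

# A small simulated study shared by several expensive-ish tests.
small_cfg <- function(...) {
  sim_config(n_cohorts = 2, n_per_cohort = 150, n_chrom = 3,
             chrom_bp = 1.2e7, n_variants = 1200, n_genes = 150,
             n_set_genes = 12, seed = 20240901, ...)
}
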
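#' Simulation configuration for synthetic multi-cohort data
#'
#' Defines the study design emulated by the generator: several diverged
#' cohorts genotyped on a shared variant panel, a heavy-tailed gene
#' annotation with a focal (length-biased) gene set, and a phenotype with a
#' polygenic background plus a configurable concentration of additive
#' genetic variance inside the focal set's windows.
#'
#' Cohort allele frequencies follow a Balding-Nichols model around the
#' ancestral frequency with divergence parameter `fst`; linkage
#' disequilibrium is induced by a first-order haplotype copying chain whose
#' correlation between adjacent sites is `ld_rho^(distance/ld_decay_bp)`.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_per_cohort Individuals per cohort (recycled to `n_cohorts`).
#' @param n_chrom Number of autosomes in the simulated genome.
#' @param chrom_bp Physical length of each chromosome in base pairs.
#' @param n_variants Total number of variants across the genome.
#' @param ancestral_maf_range Range (low, high) in (0, 0.5] from which
#'   ancestral allele frequencies are drawn uniformly.
#' @param fst Balding-Nichols divergence parameter in \[0, 1).
#' @param ld_decay_bp Length scale of LD decay in base pairs.
#' @param ld_rho Adjacent-site haplotype correlation at zero distance,
#'   in \[0, 1).
#' @param n_genes Number of annotated genes.
#' @param gene_length_log_mean,gene_length_log_sd Log-normal parameters of
#'   gene length in base pairs (heavy-tailed, like brain-expressed genes).
#' @param n_set_genes Number of genes in the focal gene set.
#' @param set_decile_bias Sampling-weight multiplier applied to genes in the
#'   top three length deciles when drawing the focal set; `1` gives an
#'   unbiased draw.
#' @param h2 Narrow-sense heritability of the latent (log-scale) phenotype,
#'   in \[0, 1).
#' @param set_variance_share Fraction of additive genetic variance carried by
#'   causal variants inside the focal set's +/-100 kb windows, in \[0, 1\].
#' @param n_causal_in_set,n_causal_background Numbers of causal variants
#'   drawn inside and outside the focal windows.
#' @param gene_flank_bp Window flank (bp) defining "inside the set" for the
#'   variance split; the pipeline's enrichment stage uses the same flank.
#' @param b_log_age Fixed effect of log(age) on the latent phenotype.
#' @param n_contemp_groups Contemporary groups per cohort.
#' @param cg_sd Standard deviation of contemporary-group effects.
#' @param seed Master seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cohorts = 3,
                       n_per_cohort = 600,
                       n_chrom = 6,
                       chrom_bp = 4e7,
                       n_variants = 8000,
                       ancestral_maf_range = c(0.05, 0.5),
                       fst = 0.1,
                       ld_decay_bp = 25000,
                       ld_rho = 0.8,
                       n_genes = 500,
                       gene_length_log_mean = log(2e4),
                       gene_length_log_sd = 1.1,
                       n_set_genes = 25,
                       set_decile_bias = 10,
                       h2 = 0.4,
                       set_variance_share = 0.30,
                       n_causal_in_set = 20,
                       n_causal_background = 200,
                       gene_flank_bp = 1e5,
                       b_log_age = 0.2,
                       n_contemp_groups = 8,
                       cg_sd = 0.3,
                       seed = 1) {
  n_per_cohort <- rep_len(as.integer(n_per_cohort), n_cohorts)
  cfg <- list(n_cohorts = as.integer(n_cohorts), n_per_cohort = n_per_cohort,
              n_chrom = as.integer(n_chrom), chrom_bp = chrom_bp,
              n_variants = as.integer(n_variants),
              ancestral_maf_range = ancestral_maf_range, fst = fst,
              ld_decay_bp = ld_decay_bp, ld_rho = ld_rho,
              n_genes = as.integer(n_genes),
              gene_length_log_mean = gene_length_log_mean,
              gene_length_log_sd = gene_length_log_sd,
              n_set_genes = as.integer(n_set_genes),
              set_decile_bias = set_decile_bias,
              h2 = h2, set_variance_share = set_variance_share,
              n_causal_in_set = as.integer(n_causal_in_set),
              n_causal_background = as.integer(n_causal_background),
              gene_flank_bp = gene_flank_bp,
              b_log_age = b_log_age,
              n_contemp_groups = as.integer(n_contemp_groups),
              cg_sd = cg_sd, seed = as.integer(seed))
  counts <- c(cfg$n_cohorts, cfg$n_per_cohort, cfg$n_chrom, cfg$n_variants,
              cfg$n_genes, cfg$n_set_genes, cfg$n_contemp_groups)
  if (any(counts <= 0)) stop("all counts in sim_config must be positive")
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must lie in [0, 1)")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (cfg$h2 < 0 || cfg$h2 >= 1) stop("h2 must lie in [0, 1)")
  if (cfg$set_variance_share < 0 || cfg$set_variance_share > 1)
    stop("set_variance_share must lie in [0, 1]")
  if (length(cfg$ancestral_maf_range) != 2 ||
      cfg$ancestral_maf_range[1] <= 0 || cfg$ancestral_maf_range[2] > 0.5 ||
      diff(cfg$ancestral_maf_range) < 0)
    stop("ancestral_maf_range must be an increasing pair in (0, 0.5]")
  if (cfg$n_set_genes > cfg$n_genes)
    stop("n_set_genes cannot exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multi-cohort genotypes
#'
#' Draws per-cohort allele frequencies from a Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` distribution around uniform ancestral
#' frequencies, then generates haplotypes along each chromosome with a
#' first-order copying chain: the latent uniform at a site is retained from
#' the previous site with probability `ld_rho^(distance/ld_decay_bp)` and
#' refreshed otherwise, which yields approximately that correlation between
#' adjacent variants while preserving marginal frequencies. Dosages are the
#' sum of two independent haplotypes.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_panel()] with strictly increasing positions per
#'   chromosome and cohort labels per individual.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "genotypes"), {
    m_per <- table(factor(sort(rep_len(seq_len(cfg$n_chrom), cfg$n_variants)),
                          levels = seq_len(cfg$n_chrom)))
    chrom <- rep(seq_len(cfg$n_chrom), m_per)
    bp <- unlist(lapply(as.integer(m_per), function(m)
      sort(sample.int(cfg$chrom_bp - 1, m))), use.names = FALSE)
    m <- cfg$n_variants
    p0 <- stats::runif(m, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
    # per-cohort frequencies
    pc <- matrix(0, cfg$n_cohorts, m)
    for (c_i in seq_len(cfg$n_cohorts)) {
      if (cfg$fst == 0) {
        pc[c_i, ] <- p0
      } else {
        a <- p0 * (1 - cfg$fst) / cfg$fst
        b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
        pc[c_i, ] <- stats::rbeta(m, a, b)
      }
    }
    # copy probability from the previous variant (0 at chromosome starts)
    d <- c(Inf, diff(bp))
    d[c(1, which(diff(chrom) != 0) + 1)] <- Inf
    r <- ifelse(is.finite(d) & cfg$ld_rho > 0,
                cfg$ld_rho^(d / cfg$ld_decay_bp), 0)
    n_tot <- sum(cfg$n_per_cohort)
    X <- matrix(0L, n_tot, m)
    row0 <- 0
    for (c_i in seq_len(cfg$n_cohorts)) {
      nh <- 2L * cfg$n_per_cohort[c_i]
      u <- stats::runif(nh)
      H <- matrix(FALSE, nh, m)
      for (j in seq_len(m)) {
        if (r[j] > 0) {
          keep <- stats::runif(nh) < r[j]
          fresh <- stats::runif(nh)
          u <- ifelse(keep, u, fresh)
        } else {
          u <- stats::runif(nh)
        }
        H[, j] <- u < pc[c_i, j]
      }
      odd <- seq(1, nh, by = 2)
      X[row0 + seq_len(cfg$n_per_cohort[c_i]), ] <-
        H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
      row0 <- row0 + cfg$n_per_cohort[c_i]
    }
    map <- data.frame(variant_id = sprintf("%d:%d", chrom, bp),
                      chrom = as.character(chrom), bp = bp,
                      A1 = "A", A2 = "C",
                      impute_r2 = round(stats::runif(m, 0.6, 1), 4),
                      stringsAsFactors = FALSE)
    cohort <- rep(sprintf("cohort%d", seq_len(cfg$n_cohorts)), cfg$n_per_cohort)
    ids <- sprintf("%s_ind%04d", cohort,
                   unlist(lapply(cfg$n_per_cohort, seq_len), use.names = FALSE))
    genotype_panel(X, map, ids = ids, cohort = cohort)
  })
}

#' Simulate a gene annotation and a length-biased focal gene set
#'
#' Gene lengths are log-normal (heavy right tail); genes are placed without
#' overlap on the simulated autosomes. The focal set is drawn with sampling
#' weights `set_decile_bias` for genes in the top three length deciles and 1
#' elsewhere, emulating candidate sets of physically large genes.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (data.frame: `gene_id`, `chrom`, `start`,
#'   `end`, `length`, `biotype`; 1-based inclusive coordinates) and
#'   `gene_set` (a list with `label` and `gene_ids`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "annotation"), {
    len <- pmin(round(stats::rlnorm(cfg$n_genes, cfg$gene_length_log_mean,
                                    cfg$gene_length_log_sd)) + 1,
                floor(cfg$chrom_bp / 5))
    chrom <- sample.int(cfg$n_chrom, cfg$n_genes, replace = TRUE)
    start <- integer(cfg$n_genes)
    # place genes without overlap, redrawing clashing starts
    for (c_i in seq_len(cfg$n_chrom)) {
      idx <- which(chrom == c_i)
      if (!length(idx)) next
      if (sum(len[idx]) > 0.8 * cfg$chrom_bp)
        stop("genes do not fit on chromosome ", c_i, " without overlap")
      placed_s <- integer(0); placed_e <- integer(0)
      for (g in idx) {
        ok <- FALSE
        for (try in 1:200) {
          s <- sample.int(cfg$chrom_bp - len[g], 1)
          e <- s + len[g] - 1
          if (!any(s <= placed_e & e >= placed_s)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place gene without overlap on chromosome ", c_i)
        start[g] <- s
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
      }
    }
    genes <- data.frame(gene_id = sprintf("GENE%04d", seq_len(cfg$n_genes)),
                        chrom = as.character(chrom), start = start,
                        end = start + len - 1, length = len,
                        biotype = "protein_coding", stringsAsFactors = FALSE)
    genes <- genes[order(chrom_order(genes$chrom), genes$start), ]
    rownames(genes) <- NULL
    dec <- gene_length_deciles(genes$length)
    w <- ifelse(dec >= 8, cfg$set_decile_bias, 1)
    focal <- sample(genes$gene_id, cfg$n_set_genes, prob = w)
    list(genes = genes,
         gene_set = list(label = "FOCAL", gene_ids = sort(focal)))
  })
}

#' Gene-length decile indices
#'
#' Assigns each gene a decile (1 = shortest tenth, 10 = longest tenth) by
#' rank, so ties are broken deterministically and the groups are as equal as
#' the sample size allows.
#'
#' @param lengths Numeric vector of gene lengths.
#' @return Integer vector of deciles in 1..10.
#' @export
gene_length_deciles <- function(lengths) {
  n <- length(lengths)
  r <- rank(lengths, ties.method = "first")
  as.integer(ceiling(10 * r / n))
}

#' Simulate phenotypes with known variance architecture
#'
#' Causal variants are drawn inside and outside the focal set's windows;
#' Gaussian effects are rescaled exactly (not in expectation) so that the
#' realized sum of `2 p (1-p) b^2` equals `h2 * set_variance_share` inside
#' the windows and `h2 * (1 - set_variance_share)` outside, with residual
#' variance `1 - h2` on the latent scale. When the set share is zero the
#' architecture is purely polygenic: causal variants are drawn from the
#' whole genome without reference to the focal set. Fixed effects (intercept,
#' `b_log_age * log(age)`, contemporary groups nested in cohort) are added
#' and the phenotype is exponentiated, so the pipeline's log-transform and
#' within-cohort standardization are exercised downstream.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param genes,gene_set Annotation from [simulate_annotation()].
#' @param cfg The same [sim_config()].
#' @return A list with `phenotypes` (data.frame: `id`, `cohort`,
#'   `flight_time` on the positive raw scale, `age`, `cg`) and `truth`
#'   (class `sim_truth`: causal IDs and effects, `sigma_g2`, `sigma_e2`,
#'   realized within-set variance fraction, cohort labels, and the set /
#'   background variant ID partition used).
#' @export
simulate_phenotypes <- function(panel, genes, gene_set, cfg) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "phenotypes"), {
    n <- nrow(panel$X)
    set_genes <- genes[genes$gene_id %in% gene_set$gene_ids, , drop = FALSE]
    inc <- map_variants_to_gene_windows(panel$map, set_genes,
                                        flank_bp = cfg$gene_flank_bp)
    set_ids <- unique(inc$variant_id)
    freq <- compute_freq(panel)$freq
    poly <- !is.na(freq) & freq > 0.01 & freq < 0.99
    in_set <- panel$map$variant_id %in% set_ids
    target_set <- cfg$h2 * cfg$set_variance_share
    target_bg <- cfg$h2 * (1 - cfg$set_variance_share)
    if (target_set > 0 && !any(in_set & poly))
      stop("set_variance_share > 0 but no usable variants in set windows")
    pick <- function(pool, k) {
      if (!length(pool) || k <= 0) return(integer(0))
      pool[sample.int(length(pool), min(k, length(pool)))]
    }
    idx_set <- if (target_set > 0)
      pick(which(in_set & poly), cfg$n_causal_in_set) else integer(0)
    # with a zero set share the architecture is purely polygenic: background
    # causals are drawn from the whole genome, so the focal set carries no
    # special signal and is exchangeable with matched random sets
    bg_pool <- if (target_set > 0) which(!in_set & poly) else which(poly)
    idx_bg <- if (target_bg > 0)
      pick(bg_pool, cfg$n_causal_background) else integer(0)
    scale_effects <- function(idx, target) {
      if (!length(idx) || target <= 0) return(numeric(length(idx)))
      b <- stats::rnorm(length(idx))
      v <- sum(2 * freq[idx] * (1 - freq[idx]) * b^2)
      b * sqrt(target / v)
    }
    b_set <- scale_effects(idx_set, target_set)
    b_bg <- scale_effects(idx_bg, target_bg)
    idx <- c(idx_set, idx_bg)
    b <- c(b_set, b_bg)
    g <- if (length(idx)) {
      sub <- subset_panel(panel, variants = idx)
      # subsetting returns columns in genome order; realign the effects
      b_cols <- b[match(sub$map$variant_id, panel$map$variant_id[idx])]
      as.vector(impute_dosages(sub) %*% b_cols)
    } else numeric(n)
    e <- stats::rnorm(n, sd = sqrt(1 - cfg$h2))
    age <- round(stats::runif(n, 320, 600))
    cg <- paste0(panel$cohort, "_cg",
                 sample.int(cfg$n_contemp_groups, n, replace = TRUE))
    cg_eff <- stats::rnorm(length(unique(cg)), sd = cfg$cg_sd)
    names(cg_eff) <- unique(cg)
    eta <- 1.2 + cfg$b_log_age * (log(age) - mean(log(age))) +
      cg_eff[cg] + g + e
    realized_set <- sum(2 * freq[idx_set] * (1 - freq[idx_set]) * b_set^2)
    realized_bg <- sum(2 * freq[idx_bg] * (1 - freq[idx_bg]) * b_bg^2)
    truth <- structure(list(
      causal_variant_ids = panel$map$variant_id[idx],
      effects = unname(b),
      sigma_g2 = realized_set + realized_bg,
      sigma_e2 = 1 - cfg$h2,
      set_variance_fraction = if (realized_set + realized_bg > 0)
        realized_set / (realized_set + realized_bg) else 0,
      set_variant_ids = set_ids,
      cohort = panel$cohort), class = "sim_truth")
    phenotypes <- data.frame(id = panel$ids, cohort = panel$cohort,
                             flight_time = exp(eta), age = age, cg = cg,
                             stringsAsFactors = FALSE)
    list(phenotypes = phenotypes, truth = truth)
  })
}

#' Simulate a complete cohort study
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_annotation()] and [simulate_phenotypes()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `panel`, `genes`, `gene_set`, `phenotypes`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  ph <- simulate_phenotypes(panel, ann$genes, ann$gene_set, cfg)
  list(panel = panel, genes = ann$genes, gene_set = ann$gene_set,
       phenotypes = ph$phenotypes, truth = ph$truth)
}
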
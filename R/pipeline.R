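#' Pipeline configuration
#'
#' Collects the input paths, QC thresholds, analysis thresholds and master
#' seed for an end-to-end run. Every numeric default is the value the
#' workflow is designed around: genome-wide significance 5e-8, 5-Mb / r2 =
#' 0.1 clumping, 100-kb gene windows for set mapping and enrichment, 200-kb
#' candidate-gene flank, 50-kb set-test flank, validation alpha 0.05, 250
#' enrichment permutations, 10,000 validation permutation replicates, and
#' the QC defaults of [qc_thresholds()].
#'
#' @param genotypes PLINK prefix or VCF path.
#' @param phenotypes Tab-separated phenotype/covariate table with columns
#'   `id`, `cohort`, `flight_time`, `age`, `cg`.
#' @param annotation Gene annotation path (`.bed` or `.gff3`).
#' @param gene_sets Gene-set file path.
#' @param validation Optional named character vector of validation
#'   summary-statistic paths (one per validation cohort).
#' @param qc A [qc_thresholds()].
#' @param thresholds Named list of analysis thresholds; any subset may be
#'   overridden.
#' @param analysis_cohort Cohort used for the enrichment (two-GRM) fits;
#'   default the largest.
#' @param gc_correct Apply genomic control to cohorts entering the
#'   meta-analysis.
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, phenotypes = NULL,
                            annotation = NULL, gene_sets = NULL,
                            validation = NULL,
                            qc = qc_thresholds(),
                            thresholds = list(),
                            analysis_cohort = NULL,
                            gc_correct = FALSE,
                            seed = 1) {
  th_default <- list(gwas_p = 5e-8, clump_window_bp = 5e6, clump_r2 = 0.1,
                     gene_flank_bp = 1e5, candidate_flank_bp = 2e5,
                     settest_flank_bp = 5e4, validation_alpha = 0.05,
                     enrichment_replicates = 250,
                     validation_replicates = 10000)
  unknown <- setdiff(names(thresholds), names(th_default))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  th <- utils::modifyList(th_default, thresholds)
  cfg <- list(paths = list(genotypes = genotypes, phenotypes = phenotypes,
                           annotation = annotation, gene_sets = gene_sets,
                           validation = validation),
              qc = unclass(qc), thresholds = th,
              analysis_cohort = analysis_cohort,
              gc_correct = isTRUE(gc_correct),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, p))` equals
#' `cfg`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(genotypes = raw$paths$genotypes,
                  phenotypes = raw$paths$phenotypes,
                  annotation = raw$paths$annotation,
                  gene_sets = raw$paths$gene_sets,
                  validation = if (!is.null(raw$paths$validation))
                    unlist(raw$paths$validation) else NULL,
                  qc = do.call(qc_thresholds, raw$qc),
                  thresholds = raw$thresholds,
                  analysis_cohort = raw$analysis_cohort,
                  gc_correct = isTRUE(raw$gc_correct),
                  seed = raw$seed)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages, mirroring a multi-cohort sequence GWAS workflow: per-cohort
#' variant QC and phenotype preprocessing; per-cohort GRM, null REML
#' (heritability) and mixed-model association scan; fixed-effects
#' meta-analysis with genomic-control reporting and FDR; LD clumping and
#' candidate-gene mapping; gene/set sum-of-chi-square tests; two-GRM
#' gene-set variance partition with a matched permutation null in the
#' analysis cohort; and, when validation summary statistics are supplied,
#' validation counting, permutation null and sign-concordance tests.
#' Every report file is stamped with the configuration hash and seed in a
#' JSON manifest; a stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for report files.
#' @return Invisibly, a list of in-memory stage results (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("genotypes", "phenotypes", "annotation", "gene_sets")) {
    if (is.null(config$paths[[p]]))
      stop("pipeline config is missing required path: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(config_hash = object_hash(unclass(config)),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    log_msg("[%s] starting", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- load ------------------------------------------------------------
  inputs <- stage("load", {
    panel <- read_genotypes(config$paths$genotypes)
    ph <- utils::read.table(config$paths$phenotypes, header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    ann_path <- config$paths$annotation
    genes <- if (grepl("\\.gff3?$", ann_path)) read_annotation_gff3(ann_path)
    else read_annotation_bed(ann_path)
    sets <- read_gene_sets(config$paths$gene_sets)
    ph <- ph[match(panel$ids, ph$id), , drop = FALSE]
    if (anyNA(ph$id)) stop("phenotype table does not cover all genotyped ids")
    list(panel = panel, ph = ph, genes = genes, sets = sets)
  })
  cohorts <- unique(inputs$panel$cohort)

  # -- per-cohort QC, GRM, REML, association ---------------------------
  qc_th <- do.call(qc_thresholds, config$qc)
  per_cohort <- stage("gwas", {
    lapply(cohorts, function(co) {
      sub <- subset_panel(inputs$panel,
                          individuals = which(inputs$panel$cohort == co))
      qc <- apply_filters(sub, qc_th)
      ph <- inputs$ph[inputs$ph$cohort == co, , drop = FALSE]
      y <- preprocess_phenotype(ph$flight_time, ph$cohort)
      X <- stats::model.matrix(~ log(age) + factor(cg), data = ph)
      grm <- build_grm(qc$panel)
      vc <- suppressWarnings(reml_fit(y, X, list(poly = grm)))
      assoc <- mlma_scan(qc$panel, y, X, grm = grm, vc = vc)
      lambda <- genomic_control_lambda(p = assoc$p)
      utils::write.table(qc$report,
                         file.path(out_dir, sprintf("qc_%s.tsv", co)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_assoc(assoc, file.path(out_dir, sprintf("gwas_%s.tsv", co)))
      list(cohort = co, qc = qc, y = y, X = X, grm = grm, vc = vc,
           assoc = assoc, lambda = lambda,
           h2 = unname(vc$fractions["poly"]),
           h2_se = unname(vc$fractions_se["poly"]))
    })
  })
  names(per_cohort) <- cohorts
  manifest$stages$gwas <- lapply(per_cohort, function(pc)
    list(n = length(pc$y), variants_in = ncol(inputs$panel$X),
         variants_out = ncol(pc$qc$panel$X),
         h2 = pc$h2, h2_se = pc$h2_se, lambda_gc = pc$lambda))

  # -- meta-analysis ---------------------------------------------------
  meta <- stage("meta", {
    cohort_stats <- lapply(per_cohort, function(pc)
      read_sumstats(file.path(out_dir, sprintf("gwas_%s.tsv", pc$cohort))))
    m <- ivw_meta(harmonize_alleles(cohort_stats),
                  gc_correct = config$gc_correct)
    write_sumstats(m[, c("MarkerName", "Allele1", "Allele2", "Freq1",
                         "FreqSE", "MinFreq", "MaxFreq", "Effect", "StdErr",
                         "P-value", "Direction")],
                   file.path(out_dir, "meta.tsv"))
    m
  })
  fdr <- bh_fdr(meta[["P-value"]], threshold = th$gwas_p)
  manifest$stages$meta <- list(n_variants = nrow(meta),
                               lambda_gc = genomic_control_lambda(
                                 p = meta[["P-value"]]),
                               n_significant = fdr$n_significant,
                               fdr_at_threshold = fdr$fdr_at_threshold)

  # -- clumping and candidate genes ------------------------------------
  # LD reference: combined QC-passing genotypes of all cohorts
  ld_ids <- Reduce(union, lapply(per_cohort, function(pc)
    pc$qc$panel$map$variant_id))
  ld_panel <- subset_panel(inputs$panel,
                           variants = intersect(inputs$panel$map$variant_id,
                                                ld_ids))
  clumps <- stage("clump", {
    # meta rows carry chrom/bp through the LD panel lookup
    clump(meta, ld_panel, p_thresh = th$gwas_p,
          window_bp = th$clump_window_bp, r2_thresh = th$clump_r2)
  })
  genes_hit <- map_genes_to_clumps(clumps, inputs$genes,
                                   flank_bp = th$candidate_flank_bp)
  stage("clump-report", {
    # %Vg uses the additive genetic variance of the analysis cohort (set
    # after this block; the largest cohort by default), as in the table
    # convention the report mirrors
    sizes <- vapply(per_cohort, function(pc) length(pc$y), numeric(1))
    ac0 <- per_cohort[[if (is.null(config$analysis_cohort))
      cohorts[which.max(sizes)] else config$analysis_cohort]]
    vg_ref <- ac0$vc$sigma2[[1]]
    rep_df <- if (length(clumps)) do.call(rbind, lapply(seq_along(clumps),
      function(ci) {
        cl <- clumps[[ci]]
        cand <- genes_hit[genes_hit$clump == ci, , drop = FALSE]
        lead_row <- ld_panel$map[
          match(cl$members[1], ld_panel$map$variant_id), , drop = FALSE]
        freq <- cl$lead$Freq1
        genic <- any(inputs$genes$chrom == cl$chrom &
                       inputs$genes$start <= lead_row$bp &
                       inputs$genes$end >= lead_row$bp)
        data.frame(clump = ci, Chr = cl$chrom, bp = lead_row$bp,
                   lead = cl$members[1],
                   A1 = lead_row$A1, A2 = lead_row$A2,
                   n_members = length(cl$members),
                   Freq1 = freq, Effect = cl$lead$Effect,
                   P = cl$lead[["P-value"]],
                   pct_vg = if (is.finite(freq) && freq > 0 && freq < 1)
                     pct_vg(freq, cl$lead$Effect, vg_ref) else NA_real_,
                   Direction = cl$lead$Direction,
                   variant_type = if (isTRUE(genic)) "genic" else "intergenic",
                   candidate_genes = paste(
                     sprintf("%s (%d)", cand$gene_id, cand$distance_bp),
                     collapse = "; "),
                   stringsAsFactors = FALSE)
      }))
    else data.frame()
    utils::write.table(rep_df, file.path(out_dir, "clumps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  manifest$stages$clump <- list(n_clumps = length(clumps),
                                n_candidate_genes =
                                  length(unique(genes_hit$gene_id)))

  # -- gene/set-based association --------------------------------------
  settest <- stage("settest", {
    st <- set_based_test(meta, ld_panel, inputs$genes,
                         flank_bp = th$settest_flank_bp)
    utils::write.table(st, file.path(out_dir, "set_test.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    st
  })
  manifest$stages$settest <- list(n_genes = nrow(settest),
                                  n_tested = sum(settest$method != "empty"))

  # -- gene-set enrichment (two-GRM) in the analysis cohort -------------
  analysis_cohort <- config$analysis_cohort
  if (is.null(analysis_cohort)) {
    sizes <- vapply(per_cohort, function(pc) length(pc$y), numeric(1))
    analysis_cohort <- cohorts[which.max(sizes)]
  }
  ac <- per_cohort[[analysis_cohort]]
  enrich <- stage("enrich", {
    lapply(inputs$sets, function(gs)
      permutation_test(ac$qc$panel, ac$y, ac$X, gs, inputs$genes,
                       flank_bp = th$gene_flank_bp,
                       n_replicates = th$enrichment_replicates,
                       seed = derive_seed(config$seed, "enrich")))
  })
  stage("enrich-report", {
    for (lb in names(enrich)) {
      utils::write.table(permutation_report(enrich[[lb]]),
                         file.path(out_dir, sprintf("enrichment_%s.tsv", lb)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  manifest$stages$enrich <- lapply(enrich, function(e)
    list(k1 = e$target$k1, k2 = e$target$k2,
         fraction = e$target$fraction,
         mean_replicate_fraction = e$mean_replicate_fraction,
         empirical_p = e$empirical_p, valid = e$valid))

  # -- replication ------------------------------------------------------
  results <- list(per_cohort = per_cohort, meta = meta, clumps = clumps,
                  candidate_genes = genes_hit, settest = settest,
                  enrichment = enrich, analysis_cohort = analysis_cohort)
  if (!is.null(config$paths$validation)) {
    validation <- stage("validate", {
      val_stats <- lapply(config$paths$validation, read_sumstats)
      sig <- meta[meta[["P-value"]] < th$gwas_p, , drop = FALSE]
      counts <- count_validated(sig, val_stats, alpha = th$validation_alpha)
      perm <- permutation_null_counts(
        val_stats, set_sizes = counts$n_present,
        observed = counts$n_validated,
        n_replicates = th$validation_replicates,
        alpha = th$validation_alpha,
        seed = derive_seed(config$seed, "validate"))
      conc <- sign_concordance_test(sig, val_stats, relation = "same",
                                    alpha = th$validation_alpha)
      rep_df <- merge(counts, perm$per_cohort[, c("cohort", "null_mean",
                                                  "empirical_p")],
                      by = "cohort", sort = TRUE)
      utils::write.table(rep_df, file.path(out_dir, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(conc$z_data, file.path(out_dir, "validation_z.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(counts = counts, perm = perm, concordance = conc)
    })
    manifest$stages$validate <- list(
      n_discovery = sum(meta[["P-value"]] < th$gwas_p),
      union_validated = length(attr(validation$counts, "union_validated")),
      pooled_empirical_p = validation$perm$pooled_empirical_p,
      sign_test_p = validation$concordance$pooled$p)
    results$validation <- validation
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline complete; outputs in %s", out_dir)
  invisible(results)
}
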
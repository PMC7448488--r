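#' Read genotypes from PLINK bed/bim/fam or VCF
#'
#' Dispatches on the file name: `.vcf` / `.vcf.gz` files are parsed with
#' the vcfR package (GT fields become A1 = ALT dosages, `./.` becomes
#' missing); anything else is treated as a PLINK prefix or `.bed` path.
#'
#' @param path VCF file, PLINK `.bed` file, or PLINK prefix.
#' @param cohort Optional per-individual cohort labels (defaults to the fam
#'   family ID for PLINK input, a single cohort for VCF).
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, cohort = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf_panel(path, cohort)
  else read_plink(sub("\\.bed$", "", path), cohort)
}

#' Read a PLINK bed/bim/fam triplet
#'
#' Implements the standard SNP-major 2-bit encoding: per variant,
#' `ceil(n/4)` bytes; within a byte, individuals occupy bit pairs from the
#' least significant end with 00 = two A1 copies, 10 = one, 11 = zero,
#' 01 = missing. An optional tab-separated sidecar `<prefix>.r2.txt`
#' (columns `variant_id`, `impute_r2`) attaches imputation quality.
#'
#' @param prefix Path prefix of the `.bed` / `.bim` / `.fam` files.
#' @param cohort Optional cohort labels; defaults to the fam family ID.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix, cohort = NULL) {
  bed_path <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "variant_id", "cm", "bp", "A1", "A2")
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_variant <- ceiling(n / 4)
  expected <- 3 + bytes_per_variant * m
  actual <- file.size(bed_path)
  raw <- readBin(bed_path, "raw", n = expected)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes at offset 0): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major PLINK bed files are supported: ", bed_path)
  if (is.na(actual) || actual != expected)
    stop("bed size (", actual, " bytes) does not match bim/fam dimensions (",
         expected, " bytes expected): ", bed_path)
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit fields of every byte
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  lut <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  G <- matrix(lut[codes + 1L], nrow = 4 * bytes_per_variant, ncol = m)
  G <- G[seq_len(n), , drop = FALSE]
  map <- bim[, c("variant_id", "chrom", "bp", "A1", "A2")]
  map$chrom <- as.character(map$chrom)
  r2_path <- paste0(prefix, ".r2.txt")
  if (file.exists(r2_path)) {
    r2 <- utils::read.table(r2_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    map$impute_r2 <- r2$impute_r2[match(map$variant_id, r2$variant_id)]
  }
  if (is.null(cohort)) cohort <- as.character(fam[[1]])
  genotype_panel(G, map, ids = as.character(fam[[2]]), cohort = cohort)
}

#' Write a panel as PLINK bed/bim/fam
#'
#' SNP-major encoding as in [read_plink()]. Cohort labels go in the fam
#' family-ID column; an `impute_r2` column, when present, is written to the
#' `<prefix>.r2.txt` sidecar.
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths written.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$X); m <- ncol(panel$X)
  utils::write.table(data.frame(panel$cohort, panel$ids, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(panel$map$chrom, panel$map$variant_id, 0,
                                panel$map$bp, panel$map$A1, panel$map$A2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(panel$X) & panel$X == 2] <- 0L
  code[!is.na(panel$X) & panel$X == 1] <- 2L
  code[!is.na(panel$X) & panel$X == 0] <- 3L
  pad <- (-n) %% 4
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  bytes <- code[seq(1, nrow(code), 4), , drop = FALSE] +
    4L * code[seq(2, nrow(code), 4), , drop = FALSE] +
    16L * code[seq(3, nrow(code), 4), , drop = FALSE] +
    64L * code[seq(4, nrow(code), 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if ("impute_r2" %in% names(panel$map)) {
    r2_path <- paste0(prefix, ".r2.txt")
    utils::write.table(data.frame(variant_id = panel$map$variant_id,
                                  impute_r2 = panel$map$impute_r2),
                       r2_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, r2_path)
  }
  invisible(paths)
}

# VCF reading through vcfR; ALT is the counted (A1) allele.
read_vcf_panel <- function(path, cohort = NULL) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("malformed VCF: ", path, " (", conditionMessage(e), ")"))
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  count_alt <- function(s) {
    out <- rep(NA_integer_, length(s))
    known <- !is.na(s) & !grepl("\\.", s)
    alleles <- strsplit(s[known], "[/|]")
    out[known] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
    out
  }
  G <- t(apply(gt, 1, count_alt))
  ids <- colnames(gt)
  id_col <- fix[, "ID"]
  no_id <- is.na(id_col) | id_col == "."
  id_col[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  map <- data.frame(variant_id = id_col, chrom = fix[, "CHROM"],
                    bp = as.integer(fix[, "POS"]),
                    A1 = fix[, "ALT"], A2 = fix[, "REF"],
                    stringsAsFactors = FALSE)
  if (is.null(cohort)) cohort <- rep("cohort1", length(ids))
  genotype_panel(t(G), map, ids = ids, cohort = cohort)
}

#' Read / write gene annotation as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive.
#' The conversion (`start + 1` on read, `start - 1` on write; `end`
#' unchanged) is the single place this translation happens. Column 4 is the
#' gene ID; an optional 5th column carries the biotype (default
#' `protein_coding`).
#'
#' @param path File path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `length`,
#'   `biotype`.
#' @export
read_annotation_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED annotation needs at least 4 columns")
  out <- data.frame(gene_id = as.character(df[[4]]),
                    chrom = as.character(df[[1]]),
                    start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out$biotype <- if (ncol(df) >= 5) as.character(df[[5]]) else "protein_coding"
  if (any(out$length <= 0)) stop("non-positive gene length after conversion")
  out
}

#' @rdname read_annotation_bed
#' @param genes Internal annotation data.frame (1-based inclusive).
#' @export
write_annotation_bed <- function(genes, path) {
  utils::write.table(data.frame(genes$chrom, genes$start - 1L, genes$end,
                                genes$gene_id, genes$biotype),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write gene annotation as GFF3 gene records
#'
#' GFF3 is 1-based inclusive, matching the internal convention. Only rows
#' of type `gene` are read; `ID` and `biotype` attributes supply the gene
#' ID and biotype.
#'
#' @param path File path.
#' @return As [read_annotation_bed()].
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) stop("malformed GFF3 (expected 9 columns): ", path)
  f <- do.call(rbind, f)
  gene_rows <- f[, 3] == "gene"
  f <- f[gene_rows, , drop = FALSE]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  out <- data.frame(gene_id = attr_get(f[, 9], "ID"),
                    chrom = f[, 1],
                    start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  bt <- attr_get(f[, 9], "biotype")
  out$biotype <- ifelse(is.na(bt), "protein_coding", bt)
  out
}

#' @rdname read_annotation_gff3
#' @param genes Internal annotation data.frame.
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tgremlite\tgene\t%d\t%d\t.\t+\t.\tID=%s;biotype=%s",
                     genes$chrom, genes$start, genes$end, genes$gene_id,
                     genes$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write gene sets as two-column text
#'
#' Tab-separated with header `set_label`, `gene_id`; one row per (set,
#' gene) membership.
#'
#' @param path File path.
#' @return A named list of gene sets (each a list with `label`,
#'   `gene_ids`).
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("set_label", "gene_id") %in% names(df)))
    stop("gene-set file needs columns set_label and gene_id")
  sets <- lapply(split(df$gene_id, df$set_label), function(g)
    list(label = NULL, gene_ids = sort(unique(g))))
  for (lb in names(sets)) sets[[lb]]$label <- lb
  sets
}

#' @rdname read_gene_sets
#' @param sets A gene set or list of gene sets.
#' @export
write_gene_sets <- function(sets, path) {
  if (!is.null(sets$gene_ids)) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(set_label = s$label, gene_id = s$gene_ids,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study to disk in pipeline input formats
#'
#' Emits PLINK bed/bim/fam (+ imputation-quality sidecar), a tab-separated
#' phenotype/covariate table, BED gene annotation, and a gene-set file.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param prefix File name stem.
#' @return Invisibly, a named list of paths (`genotypes` prefix,
#'   `phenotypes`, `annotation`, `gene_sets`).
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno_prefix <- file.path(dir, prefix)
  write_plink(study$panel, geno_prefix)
  ph_path <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  utils::write.table(study$phenotypes, ph_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann_path <- file.path(dir, paste0(prefix, "_genes.bed"))
  write_annotation_bed(study$genes, ann_path)
  set_path <- file.path(dir, paste0(prefix, "_gene_sets.tsv"))
  write_gene_sets(study$gene_set, set_path)
  invisible(list(genotypes = geno_prefix, phenotypes = ph_path,
                 annotation = ann_path, gene_sets = set_path))
}
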
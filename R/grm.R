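#' Standardize genotypes for relationship-matrix construction
#'
#' Centers and scales dosages variant-wise: `w_ij = (x_ij - 2 p_j) /
#' sqrt(2 p_j (1 - p_j))`. Frequencies are estimated from the panel unless
#' supplied. Missing dosages are mean-imputed, which corresponds to `w = 0`
#' after centering. Monomorphic variants (`p` of 0 or 1) are excluded with a
#' warning since their scale factor is zero.
#'
#' @param panel A [genotype_panel()].
#' @param freqs Optional numeric vector of A1 frequencies (one per variant,
#'   in panel column order).
#' @return Numeric matrix `W` (individuals x retained variants) with a
#'   `variant_id` attribute naming the retained columns.
#' @export
standardize_genotypes <- function(panel, freqs = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(freqs)) freqs <- suppressWarnings(compute_freq(panel))$freq
  stopifnot(length(freqs) == ncol(panel$X))
  ok <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!all(ok))
    warning(sum(!ok), " monomorphic or untyped variant(s) excluded from ",
            "standardization")
  X <- impute_dosages(panel)[, ok, drop = FALSE]
  p <- freqs[ok]
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  attr(W, "variant_id") <- panel$map$variant_id[ok]
  W
}

#' Build a genomic relationship matrix
#'
#' VanRaden-style GRM `G = W W' / k` over the (optionally subset) variants,
#' where `W` is the standardized genotype matrix and `k` the number of
#' variants used. For panels wider than `chunk` variants the cross-product
#' accumulates chunk-wise, keeping memory at O(n^2 + n*chunk).
#'
#' @param panel A [genotype_panel()].
#' @param variant_subset Optional variant IDs (or column indices) to use.
#' @param freqs Optional A1 frequencies for the full panel (before
#'   subsetting); estimated in-sample when `NULL`.
#' @param chunk Number of variants per accumulation block.
#' @return An object of class `grm`: list with `G` (n x n symmetric matrix),
#'   `k` (variants used), `ids`, `variant_ids`.
#' @export
build_grm <- function(panel, variant_subset = NULL, freqs = NULL,
                      chunk = 2000L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(variant_subset)) {
    if (!length(variant_subset)) stop("empty variant subset")
    vi <- if (is.character(variant_subset))
      match(variant_subset, panel$map$variant_id) else variant_subset
    if (anyNA(vi)) stop("unknown variant IDs in subset")
    vi <- sort(vi)  # panel columns stay in genome order after subsetting
    if (!is.null(freqs)) freqs <- freqs[vi]
    panel <- subset_panel(panel, variants = vi)
  }
  n <- nrow(panel$X)
  m <- ncol(panel$X)
  if (is.null(freqs)) freqs <- suppressWarnings(compute_freq(panel))$freq
  G <- matrix(0, n, n)
  used <- character(0)
  for (j0 in seq(1, m, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1, m)
    W <- standardize_genotypes(subset_panel(panel, variants = jj),
                               freqs = freqs[jj])
    used <- c(used, attr(W, "variant_id"))
    if (ncol(W)) G <- G + tcrossprod(W)
  }
  k <- length(used)
  if (k == 0) stop("no polymorphic variants available for the GRM")
  G <- G / k
  dimnames(G) <- list(panel$ids, panel$ids)
  structure(list(G = G, k = k, ids = panel$ids, variant_ids = used),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM over", length(x$ids), "individuals from", x$k, "variants\n")
  cat("mean diagonal:", round(mean(diag(x$G)), 4),
      " mean off-diagonal:", round(mean(x$G[upper.tri(x$G)]), 4), "\n")
  invisible(x)
}

#' Write a GRM in GCTA text interchange format
#'
#' Writes `<prefix>.grm.gz` (gzipped, tab-separated lower triangle:
#' index i, index j, variant count k, relationship) and `<prefix>.grm.id`
#' (family and individual ID columns).
#'
#' @param grm A [build_grm()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len), use.names = FALSE)
  df <- data.frame(i = i, j = j, k = grm$k,
                   value = grm$G[cbind(i, j)])
  gz <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     gz, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(gz)
  utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".grm.gz"), paste0(prefix, ".grm.id")))
}

#' Read a GRM written by [write_grm()] (GCTA text convention)
#'
#' @param prefix Path prefix of the `.grm.gz` / `.grm.id` pair.
#' @return A `grm` object (without `variant_ids`).
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  n <- length(ids)
  G <- matrix(0, n, n)
  G[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  G[cbind(tri[[2]], tri[[1]])] <- tri[[4]]
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, k = tri[[3]][1], ids = ids, variant_ids = NULL),
            class = "grm")
}

#' Combine set and complement GRMs by the partition identity
#'
#' For a variant partition S, S-bar of the full panel,
#' `k * G_all = k1 * G_S + k2 * G_Sbar` holds exactly. This helper solves
#' for the complement GRM given the full and set GRMs, avoiding a second
#' O(n^2 k2) pass when the complement is large.
#'
#' @param grm_all GRM over all k variants.
#' @param grm_set GRM over the k1 set variants.
#' @return A `grm` for the complement (k2 = k - k1 variants).
#' @export
complement_grm <- function(grm_all, grm_set) {
  stopifnot(inherits(grm_all, "grm"), inherits(grm_set, "grm"),
            identical(grm_all$ids, grm_set$ids))
  k2 <- grm_all$k - grm_set$k
  if (k2 <= 0) stop("set GRM uses at least as many variants as the full GRM")
  G2 <- (grm_all$k * grm_all$G - grm_set$k * grm_set$G) / k2
  vids <- if (!is.null(grm_all$variant_ids) && !is.null(grm_set$variant_ids))
    setdiff(grm_all$variant_ids, grm_set$variant_ids) else NULL
  structure(list(G = G2, k = k2, ids = grm_all$ids, variant_ids = vids),
            class = "grm")
}
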
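#' Genotype panel container
#'
#' Bundles an individuals-by-variants dosage matrix with per-variant and
#' per-individual metadata. Dosages count copies of allele A1 and must lie in
#' \{0, 1, 2\} or be `NA` (missing).
#'
#' @param X Integer or numeric matrix, individuals in rows, variants in
#'   columns. Values in \{0, 1, 2, NA\}.
#' @param map `data.frame` with one row per variant and columns
#'   `variant_id`, `chrom`, `bp`, `A1`, `A2`, and optionally `impute_r2`
#'   (imputation quality).
#' @param ids Character vector of individual identifiers (unique).
#' @param cohort Character vector of per-individual cohort labels.
#'
#' @return An object of class `genotype_panel`: a list with elements `X`,
#'   `map`, `ids`, `cohort`.
#' @export
genotype_panel <- function(X, map, ids = rownames(X), cohort = NULL) {
  X <- as.matrix(X)
  if (is.null(ids)) ids <- sprintf("id%d", seq_len(nrow(X)))
  if (is.null(cohort)) cohort <- rep("cohort1", nrow(X))
  stopifnot(is.data.frame(map),
            all(c("variant_id", "chrom", "bp", "A1", "A2") %in% names(map)),
            nrow(map) == ncol(X),
            length(ids) == nrow(X),
            length(cohort) == nrow(X))
  if (anyDuplicated(map$variant_id))
    stop("duplicated variant IDs in map")
  if (anyDuplicated(ids))
    stop("duplicated individual IDs")
  vals <- X[!is.na(X)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  # positions must be sorted within chromosome
  ord <- order(chrom_order(map$chrom), map$bp)
  if (is.unsorted(ord) && any(ord != seq_along(ord))) {
    X <- X[, ord, drop = FALSE]
    map <- map[ord, , drop = FALSE]
    rownames(map) <- NULL
  }
  by_chr <- split(map$bp, map$chrom)
  if (any(vapply(by_chr, function(b) any(diff(b) <= 0), logical(1))))
    stop("variant positions must be strictly increasing within chromosome")
  map$variant_id <- as.character(map$variant_id)
  dimnames(X) <- list(ids, map$variant_id)
  structure(list(X = X, map = map, ids = as.character(ids),
                 cohort = as.character(cohort)),
            class = "genotype_panel")
}

# stable ordering key for chromosome labels (numeric first, then lexical)
chrom_order <- function(chrom) {
  ch <- as.character(chrom)
  num <- suppressWarnings(as.numeric(ch))
  key <- ifelse(is.na(num), 1e6 + as.numeric(factor(ch)), num)
  key
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$X), "individuals x", ncol(x$X), "variants\n")
  cat("Chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  tb <- table(x$cohort)
  cat("Cohorts:", paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
                        collapse = ", "), "\n")
  nm <- sum(is.na(x$X))
  if (nm > 0) cat("Missing dosages:", nm, "\n")
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel A `genotype_panel`.
#' @param variants Variant IDs or column indices to keep (default all).
#' @param individuals Individual IDs or row indices to keep (default all).
#' @return A `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, variants = NULL, individuals = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  vi <- if (is.null(variants)) seq_len(ncol(panel$X)) else
    if (is.character(variants)) match(variants, panel$map$variant_id) else variants
  if (anyNA(vi)) stop("unknown variant IDs in subset")
  ii <- if (is.null(individuals)) seq_len(nrow(panel$X)) else
    if (is.character(individuals)) match(individuals, panel$ids) else individuals
  if (anyNA(ii)) stop("unknown individual IDs in subset")
  map <- panel$map[vi, , drop = FALSE]
  rownames(map) <- NULL
  genotype_panel(panel$X[ii, vi, drop = FALSE], map,
                 ids = panel$ids[ii], cohort = panel$cohort[ii])
}

# Mean-impute missing dosages (per variant, 2 * allele frequency).
# Returns a plain numeric matrix; monomorphic all-missing columns become 0.
impute_dosages <- function(panel) {
  X <- panel$X
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}
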
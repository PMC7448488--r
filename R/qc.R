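#' Per-variant allele frequency
#'
#' A1 allele frequency from dosages: sum of dosages over twice the number of
#' non-missing genotypes. Variants with no typed genotype get `NA` and a
#' warning; downstream filters exclude them.
#'
#' @param panel A [genotype_panel()].
#' @return data.frame with `variant_id`, `freq` (A1 frequency), `maf`,
#'   `n_typed`.
#' @export
compute_freq <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_typed <- colSums(!is.na(panel$X))
  p <- colSums(panel$X, na.rm = TRUE) / (2 * n_typed)
  if (any(n_typed == 0)) {
    warning(sum(n_typed == 0),
            " variant(s) with all genotypes missing; frequency set to NA")
    p[n_typed == 0] <- NA_real_
  }
  data.frame(variant_id = panel$map$variant_id, freq = unname(p),
             maf = unname(pmin(p, 1 - p)), n_typed = unname(n_typed),
             stringsAsFactors = FALSE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the allele counts, the p-value is the sum
#' of probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Probabilities are computed by
#' the standard recurrence over heterozygote counts, which is numerically
#' stable far into the tail (the QC threshold of 1e-10 lives where a
#' chi-square approximation is unreliable).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return The exact p-value; 1 for monomorphic variants.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1, n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start from the mid-range het count and apply the ratio recurrence
  # P(h+2)/P(h) = (rare-h)(2n-rare-h) / ((h+2)(h+1))
  mid <- hets[which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))]
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid < length(hets)) for (i in i_mid:(length(hets) - 1)) {
    h <- hets[i]
    probs[i + 1] <- probs[i] * (rare - h) * (2 * n - rare - h) /
      ((h + 2) * (h + 1))
  }
  if (i_mid > 1) for (i in i_mid:2) {
    h <- hets[i]
    probs[i - 1] <- probs[i] * h * (h - 1) /
      ((rare - h + 2) * (2 * n - rare - h + 2))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("impossible heterozygote count for the allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' HWE exact p-values for every variant in a panel
#'
#' @param panel A [genotype_panel()].
#' @return Numeric vector of p-values (1 for monomorphic or all-missing).
#' @export
hwe_test_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  vapply(seq_len(ncol(panel$X)), function(j) {
    x <- panel$X[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))
}

#' Variant QC thresholds
#'
#' Defaults follow standard sequence-GWAS practice for cattle: remove
#' variants with MAF below 1e-4, HWE exact p below 1e-10, imputation quality
#' below 0.6, and any non-autosomal variant.
#'
#' @param maf_min Minimum minor allele frequency (variants with MAF <
#'   `maf_min` are removed).
#' @param hwe_p_min Minimum HWE exact-test p-value.
#' @param impute_r2_min Minimum imputation r-squared; applied only when the
#'   panel carries an `impute_r2` column. The filter is strict (`< 0.6`
#'   removed, `= 0.6` retained).
#' @param autosomes_only Drop X/Y/MT variants.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 1e-4, hwe_p_min = 1e-10,
                          impute_r2_min = 0.6, autosomes_only = TRUE) {
  th <- list(maf_min = maf_min, hwe_p_min = hwe_p_min,
             impute_r2_min = impute_r2_min,
             autosomes_only = isTRUE(autosomes_only))
  if (any(unlist(th[1:3]) < 0) || any(unlist(th[1:3]) > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

NON_AUTOSOMES <- c("X", "Y", "MT", "M", "chrX", "chrY", "chrM", "chrMT")

#' Apply variant QC filters
#'
#' Each filter is a pure predicate on the unfiltered panel, so the surviving
#' set does not depend on filter order; the report counts removals in the
#' fixed order MAF, HWE, imputation r2, non-autosomal (a variant is counted
#' against the first filter that rejects it). Variants with all genotypes
#' missing are removed with the MAF filter.
#'
#' @param panel A [genotype_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return list with `panel` (filtered) and `report` (data.frame: one row
#'   per filter with the threshold and number removed, plus a final
#'   `retained` row).
#' @export
apply_filters <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  fr <- suppressWarnings(compute_freq(panel))
  fail_maf <- is.na(fr$maf) | fr$maf < thresholds$maf_min
  hwe_p <- hwe_test_panel(panel)
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_r2 <- if ("impute_r2" %in% names(panel$map))
    !is.na(panel$map$impute_r2) & panel$map$impute_r2 < thresholds$impute_r2_min
  else rep(FALSE, ncol(panel$X))
  fail_auto <- if (thresholds$autosomes_only)
    panel$map$chrom %in% NON_AUTOSOMES else rep(FALSE, ncol(panel$X))
  keep <- !(fail_maf | fail_hwe | fail_r2 | fail_auto)
  first_fail <- function(this, earlier) sum(this & !earlier)
  report <- data.frame(
    filter = c("maf", "hwe", "impute_r2", "non_autosomal", "retained"),
    threshold = c(thresholds$maf_min, thresholds$hwe_p_min,
                  thresholds$impute_r2_min, NA, NA),
    n = c(sum(fail_maf),
          first_fail(fail_hwe, fail_maf),
          first_fail(fail_r2, fail_maf | fail_hwe),
          first_fail(fail_auto, fail_maf | fail_hwe | fail_r2),
          sum(keep)),
    stringsAsFactors = FALSE)
  if (!any(keep)) {
    seq_fail <- c("maf", "hwe", "impute_r2", "non_autosomal")
    cum <- cbind(fail_maf, fail_maf | fail_hwe,
                 fail_maf | fail_hwe | fail_r2,
                 fail_maf | fail_hwe | fail_r2 | fail_auto)
    culprit <- seq_fail[which(colSums(cum) == ncol(panel$X))[1]]
    stop("QC removed every variant; last responsible filter: ", culprit)
  }
  list(panel = subset_panel(panel, variants = which(keep)), report = report)
}

#' Log-transform and standardize a positive phenotype within cohorts
#'
#' Takes the natural logarithm and z-scores within each cohort using the
#' unbiased (n-1) sample standard deviation, so each cohort has mean 0 and
#' variance 1 after preprocessing.
#'
#' @param raw Positive raw phenotype values.
#' @param cohort Cohort label per record.
#' @return Numeric vector of standardized log-phenotypes.
#' @export
preprocess_phenotype <- function(raw, cohort) {
  if (any(!is.finite(raw) | raw <= 0)) {
    bad <- which(!is.finite(raw) | raw <= 0)
    stop("non-positive phenotype value at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ly <- log(raw)
  out <- numeric(length(ly))
  for (co in unique(cohort)) {
    i <- cohort == co
    s <- stats::sd(ly[i])
    if (!is.finite(s) || s == 0)
      stop("degenerate phenotype (zero variance) in cohort ", co)
    out[i] <- (ly[i] - mean(ly[i])) / s
  }
  out
}
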
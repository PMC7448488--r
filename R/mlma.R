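#' Mixed-linear-model association scan
#'
#' Per-variant association test under the null-model variance structure:
#' variance components are estimated once by REML without any candidate
#' variant, then each variant's allele-substitution effect is the
#' generalized-least-squares estimate after projecting out the fixed
#' effects, `b = x'Py / x'Px` with `P` the projected inverse of
#' `V = sigma_g^2 G + sigma_e^2 I`, its sampling variance `1 / x'Px`, and a
#' Wald p-value from chi-square with 1 df. The additive coding means two
#' copies of A1 have twice the effect of one. `V` is held fixed across
#' variants, the standard approximation that makes the scan a single
#' factorization plus one matrix product.
#'
#' Missing dosages are mean-imputed per variant. Variants whose dosage is
#' constant, or collinear with the covariates after projection, get `NA`
#' results with a warning.
#'
#' @param panel A QC'd [genotype_panel()].
#' @param y Standardized phenotype vector.
#' @param X Fixed-effect design matrix (default intercept).
#' @param grm A [build_grm()] result; by default built from the whole panel.
#'   With `loco = TRUE` a leave-one-chromosome-out GRM is used per
#'   chromosome (derived by the exact partition identity).
#' @param vc Optional pre-fitted null [reml_fit()] (one genetic component);
#'   fitted here when `NULL`.
#' @param loco Leave-one-chromosome-out GRM toggle (off by default,
#'   matching the usual single-GRM mixed-model scan).
#'
#' @return An object of classes `assoc_result` and `data.frame`: one row
#'   per variant with `variant_id`, `chrom`, `bp`, `A1`, `A2`, `freq`
#'   (A1 frequency), `beta`, `se`, `p`, `n`.
#' @export
mlma_scan <- function(panel, y, X = NULL, grm = NULL, vc = NULL,
                      loco = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$X)
  stopifnot(length(y) == n)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(grm)) grm <- build_grm(panel)
  freqs <- suppressWarnings(compute_freq(panel))
  Xg <- impute_dosages(panel)
  if (!loco) {
    if (is.null(vc)) vc <- reml_fit(y, X, list(poly = grm))
    res <- .mlma_chunk(Xg, y, X, grm$G, vc$sigma2[[1]], vc$sigma2[["residual"]])
  } else {
    res <- matrix(NA_real_, ncol(Xg), 2)
    for (chr in unique(panel$map$chrom)) {
      jj <- which(panel$map$chrom == chr)
      g_chr <- build_grm(panel, variant_subset = jj)
      g_loco <- complement_grm(grm, g_chr)
      vc_chr <- reml_fit(y, X, list(poly = g_loco))
      res[jj, ] <- .mlma_chunk(Xg[, jj, drop = FALSE], y, X, g_loco$G,
                               vc_chr$sigma2[[1]],
                               vc_chr$sigma2[["residual"]])
    }
  }
  beta <- res[, 1]
  se <- res[, 2]
  bad <- !is.finite(se)
  if (any(bad))
    warning(sum(bad), " variant(s) constant or collinear with covariates; ",
            "results set to NA")
  chisq <- (beta / se)^2
  out <- data.frame(variant_id = panel$map$variant_id,
                    chrom = panel$map$chrom, bp = panel$map$bp,
                    A1 = panel$map$A1, A2 = panel$map$A2,
                    freq = freqs$freq, beta = beta, se = se,
                    p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                    n = freqs$n_typed, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

# GLS effect and SE for each column of Xg under fixed V
.mlma_chunk <- function(Xg, y, X, G, s2g, s2e) {
  n <- length(y)
  V <- s2g * unname(G) + diag(s2e, n)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  Py <- drop(P %*% y)
  xtPy <- drop(crossprod(Xg, Py))
  xtPx <- colSums(Xg * (P %*% Xg))
  ok <- xtPx > 1e-10 * n
  beta <- se <- rep(NA_real_, length(xtPx))
  beta[ok] <- xtPy[ok] / xtPx[ok]
  se[ok] <- 1 / sqrt(xtPx[ok])
  cbind(beta, se)
}

#' Write an association scan in the shared summary-statistic dialect
#'
#' Columns: MarkerName, Allele1, Allele2, Freq1, Effect, StdErr, P-value, N
#' (tab-separated).
#'
#' @param assoc An [mlma_scan()] result.
#' @param path Output file.
#' @export
write_assoc <- function(assoc, path) {
  df <- data.frame(MarkerName = assoc$variant_id,
                   Allele1 = assoc$A1, Allele2 = assoc$A2,
                   Freq1 = assoc$freq, Effect = assoc$beta,
                   StdErr = assoc$se, `P-value` = assoc$p, N = assoc$n,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
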
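#' Read / write summary statistics in the shared column dialect
#'
#' The meta-analysis interchange format is tab-separated with header
#' `MarkerName, Allele1, Allele2, Freq1, FreqSE, MinFreq, MaxFreq, Effect,
#' StdErr, P-value, Direction`; per-cohort files may carry the subset
#' `MarkerName, Allele1, Allele2, Freq1, Effect, StdErr, P-value, N`.
#'
#' @param path File path.
#' @return data.frame with the columns present in the file (names kept
#'   verbatim, including `P-value`).
#' @export
read_sumstats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_sumstats
#' @param stats data.frame of summary statistics.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# normalize one cohort's stats to internal column names
.norm_stats <- function(df) {
  need <- c("MarkerName", "Allele1", "Allele2", "Effect", "StdErr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary statistics missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(marker = as.character(df$MarkerName),
                    a1 = toupper(as.character(df$Allele1)),
                    a2 = toupper(as.character(df$Allele2)),
                    beta = as.numeric(df$Effect),
                    se = as.numeric(df$StdErr),
                    stringsAsFactors = FALSE)
  out$freq <- if ("Freq1" %in% names(df)) as.numeric(df$Freq1) else
    rep(NA_real_, nrow(out))
  out$p <- if ("P-value" %in% names(df)) as.numeric(df[["P-value"]]) else
    2 * stats::pnorm(-abs(out$beta / out$se))
  out$n <- if ("N" %in% names(df)) as.numeric(df$N) else
    rep(NA_real_, nrow(out))
  out
}

#' Align per-cohort summary statistics onto shared effect alleles
#'
#' The first cohort reporting a marker defines its reference A1/A2. Cohorts
#' reporting the swapped pair have their effect negated and frequency
#' flipped; markers whose allele pair does not match either orientation are
#' dropped from that cohort with a message (counted in the attribute
#' `n_dropped`).
#'
#' @param cohort_stats Named list of per-cohort summary-statistic
#'   data.frames in the shared dialect.
#' @return A list of aligned per-cohort data.frames (internal columns
#'   `marker, a1, a2, beta, se, freq, p, n`) with attribute `n_dropped`.
#' @export
harmonize_alleles <- function(cohort_stats) {
  stopifnot(is.list(cohort_stats), length(cohort_stats) >= 1)
  norm <- lapply(cohort_stats, .norm_stats)
  # reference orientation: first appearance of each marker
  all_mk <- unlist(lapply(norm, `[[`, "marker"), use.names = FALSE)
  all_a1 <- unlist(lapply(norm, `[[`, "a1"), use.names = FALSE)
  all_a2 <- unlist(lapply(norm, `[[`, "a2"), use.names = FALSE)
  first <- !duplicated(all_mk)
  ref <- data.frame(marker = all_mk[first], a1 = all_a1[first],
                    a2 = all_a2[first], stringsAsFactors = FALSE)
  n_dropped <- 0L
  aligned <- lapply(norm, function(df) {
    i <- match(df$marker, ref$marker)
    same <- df$a1 == ref$a1[i] & df$a2 == ref$a2[i]
    swap <- df$a1 == ref$a2[i] & df$a2 == ref$a1[i]
    bad <- !(same | swap)
    if (any(bad)) {
      n_dropped <<- n_dropped + sum(bad)
      log_msg("harmonize_alleles: dropping %d marker(s) with mismatched alleles",
              sum(bad))
    }
    df$beta[swap] <- -df$beta[swap]
    df$freq[swap] <- 1 - df$freq[swap]
    df$a1[swap] <- ref$a1[i][swap]
    df$a2[swap] <- ref$a2[i][swap]
    df[!bad, , drop = FALSE]
  })
  attr(aligned, "n_dropped") <- n_dropped
  aligned
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Combines aligned per-cohort effects with weights `1/se^2`: the meta
#' effect is the weighted mean, the meta standard error `1/sqrt(sum w)`,
#' and the p-value two-sided normal. The `Direction` string holds one
#' character per cohort: `+` / `-` for the sign of that cohort's aligned
#' effect, `?` when the marker is absent there. `Freq1` is the
#' weight-averaged allele frequency; `FreqSE`, `MinFreq`, `MaxFreq`
#' summarize its spread across cohorts.
#'
#' @param aligned Output of [harmonize_alleles()] (or a compatible list).
#' @param gc_correct Apply genomic control to each input cohort first:
#'   every cohort's standard errors are inflated by `sqrt(max(lambda, 1))`
#'   computed from its own p-values, so deflated cohorts are left
#'   untouched.
#' @return An object of classes `variant_summary` and `data.frame` with the
#'   full interchange columns plus `z` and `n_cohorts`; attribute
#'   `lambda_gc` carries the per-cohort lambdas when `gc_correct` is used.
#' @export
ivw_meta <- function(aligned, gc_correct = FALSE) {
  stopifnot(is.list(aligned), length(aligned) >= 1)
  if (!is.data.frame(aligned[[1]]) || !"marker" %in% names(aligned[[1]]))
    aligned <- harmonize_alleles(aligned)
  lambdas <- NULL
  if (gc_correct) {
    lambdas <- vapply(aligned, function(df)
      genomic_control_lambda(p = df$p), numeric(1))
    aligned <- Map(function(df, lam) {
      infl <- sqrt(max(lam, 1))
      df$se <- df$se * infl
      df$p <- 2 * stats::pnorm(-abs(df$beta / df$se))
      df
    }, aligned, lambdas)
  }
  markers <- unique(unlist(lapply(aligned, `[[`, "marker"), use.names = FALSE))
  k <- length(aligned)
  B <- SE <- FR <- matrix(NA_real_, length(markers), k)
  ref_a1 <- ref_a2 <- rep(NA_character_, length(markers))
  for (c_i in seq_len(k)) {
    df <- aligned[[c_i]]
    i <- match(df$marker, markers)
    B[i, c_i] <- df$beta
    SE[i, c_i] <- df$se
    FR[i, c_i] <- df$freq
    new <- is.na(ref_a1[i])
    ref_a1[i][new] <- df$a1[new]
    ref_a2[i][new] <- df$a2[new]
  }
  W <- 1 / SE^2
  W[!is.finite(W)] <- NA
  sw <- rowSums(W, na.rm = TRUE)
  if (any(sw == 0)) {
    drop_i <- sw == 0
    markers <- markers[!drop_i]
    B <- B[!drop_i, , drop = FALSE]; SE <- SE[!drop_i, , drop = FALSE]
    W <- W[!drop_i, , drop = FALSE]; FR <- FR[!drop_i, , drop = FALSE]
    ref_a1 <- ref_a1[!drop_i]; ref_a2 <- ref_a2[!drop_i]
    sw <- sw[!drop_i]
  }
  beta <- rowSums(W * B, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  fsw <- rowSums(W * !is.na(FR), na.rm = TRUE)
  freq <- rowSums(W * FR, na.rm = TRUE) / fsw
  freq_se <- sqrt(pmax(0, rowSums(W * (FR - freq)^2, na.rm = TRUE) / fsw))
  direction <- apply(B, 1, function(b)
    paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")), collapse = ""))
  out <- data.frame(MarkerName = markers, Allele1 = ref_a1, Allele2 = ref_a2,
                    Freq1 = freq, FreqSE = freq_se,
                    MinFreq = suppressWarnings(apply(FR, 1, min, na.rm = TRUE)),
                    MaxFreq = suppressWarnings(apply(FR, 1, max, na.rm = TRUE)),
                    Effect = beta, StdErr = se, `P-value` = p,
                    Direction = direction, z = z,
                    n_cohorts = rowSums(!is.na(B)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "lambda_gc") <- lambdas
  class(out) <- c("variant_summary", "data.frame")
  out
}

#' Genomic-control inflation factor
#'
#' `lambda_gc` is the median association chi-square divided by the median
#' of the chi-square distribution with 1 df (computed from the inverse CDF
#' at 0.5, about 0.4549).
#'
#' @param p P-values (converted to 1-df chi-squares), or
#' @param chisq chi-square statistics directly.
#' @return The inflation factor.
#' @export
genomic_control_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    stopifnot(!is.null(p), length(p) >= 1)
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values and the FDR at a p-value threshold
#'
#' Adjusts with `stats::p.adjust(method = "BH")` and reports the q-value of
#' the largest p-value at or below the chosen significance threshold, so the
#' correspondence between a fixed p threshold and its realized FDR can be
#' stated for any run.
#'
#' @param p P-values in (0, 1].
#' @param threshold Significance threshold on the p scale.
#' @return list with `q` (BH q-values in input order), `fdr_at_threshold`
#'   (NA when nothing passes), and `n_significant`.
#' @export
bh_fdr <- function(p, threshold = 5e-8) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  sel <- !is.na(p) & p <= threshold
  list(q = q,
       fdr_at_threshold = if (any(sel)) max(q[sel]) else NA_real_,
       n_significant = sum(sel))
}
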
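#' Count discovery variants validated in independent cohorts
#'
#' A discovery variant is validated in a cohort when it is present there,
#' polymorphic (frequency strictly between 0 and 1), allele-consistent with
#' the discovery orientation, and has validation p strictly below `alpha`.
#' Variants whose allele pair matches neither orientation are excluded from
#' that cohort's denominator with a message.
#'
#' @param discovery Discovery summary (rows to validate) with `MarkerName`,
#'   `Allele1`, `Allele2` and `Effect`.
#' @param validation Named list of per-cohort validation summaries in the
#'   shared dialect.
#' @param alpha Validation significance threshold (strict `<`).
#' @return data.frame with one row per cohort (`cohort`, `n_present`,
#'   `n_polymorphic`, `n_validated`) and attribute `union_validated`
#'   (variant IDs validated in at least one cohort).
#' @export
count_validated <- function(discovery, validation, alpha = 0.05) {
  disc <- .norm_stats(discovery)
  cohorts <- names(validation)
  if (is.null(cohorts)) cohorts <- sprintf("cohort%d", seq_along(validation))
  union_hits <- character(0)
  rows <- lapply(seq_along(validation), function(c_i) {
    val <- .norm_stats(validation[[c_i]])
    i <- match(disc$marker, val$marker)
    present <- !is.na(i)
    same <- present & disc$a1 == val$a1[i] & disc$a2 == val$a2[i]
    swap <- present & disc$a1 == val$a2[i] & disc$a2 == val$a1[i]
    mismatch <- present & !(same | swap)
    if (any(mismatch))
      log_msg("count_validated: %d allele-mismatched variant(s) excluded in %s",
              sum(mismatch), cohorts[c_i])
    ok <- same | swap
    poly <- ok & val$freq[i] > 0 & val$freq[i] < 1
    validated <- poly & val$p[i] < alpha
    union_hits <<- union(union_hits, disc$marker[validated])
    data.frame(cohort = cohorts[c_i], n_present = sum(ok),
               n_polymorphic = sum(poly), n_validated = sum(validated),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "union_validated") <- union_hits
  out
}

#' Permutation null for the number of validated variants
#'
#' For each cohort, draws `set_size` variants uniformly without replacement
#' from the cohort's full validation summary (its own QC-passing sampling
#' frame) and counts how many have p below `alpha`; the pooled null is the
#' per-replicate sum across cohorts. Empirical p-values use the add-one
#' correction. A minor-allele-frequency-matched mode restricts each draw to
#' variants within `maf_tol` of the observed set's frequencies.
#'
#' @param validation Named list of per-cohort validation summaries.
#' @param set_sizes Number of variants drawn per cohort (recycled).
#' @param observed Observed validated counts per cohort (for empirical p;
#'   optional).
#' @param n_replicates Replicates per cohort.
#' @param alpha Significance threshold (strict `<`).
#' @param seed Integer seed.
#' @param maf_match Optional list of discovery frequencies per cohort to
#'   match on (default unmatched).
#' @param maf_tol Half-width of the frequency matching band.
#' @return list with `per_cohort` (data.frame: cohort, set_size, null_mean,
#'   observed, empirical_p), `pooled_null` (replicate sums),
#'   `pooled_observed`, `pooled_empirical_p`, `n_replicates`.
#' @export
permutation_null_counts <- function(validation, set_sizes, observed = NULL,
                                    n_replicates = 10000, alpha = 0.05,
                                    seed = 1, maf_match = NULL,
                                    maf_tol = 0.05) {
  cohorts <- names(validation)
  if (is.null(cohorts)) cohorts <- sprintf("cohort%d", seq_along(validation))
  set_sizes <- rep_len(set_sizes, length(validation))
  nulls <- with_seed(seed, lapply(seq_along(validation), function(c_i) {
    val <- .norm_stats(validation[[c_i]])
    frame_hit <- val$p < alpha
    maf <- pmin(val$freq, 1 - val$freq)
    if (!is.null(maf_match)) {
      tgt <- pmin(maf_match[[c_i]], 1 - maf_match[[c_i]])
      band <- range(tgt) + c(-maf_tol, maf_tol)
      keep <- !is.na(maf) & maf >= band[1] & maf <= band[2]
      frame_hit <- frame_hit[keep]
    }
    M <- length(frame_hit)
    s <- set_sizes[c_i]
    if (M < s)
      stop("sampling frame for ", cohorts[c_i], " has ", M,
           " variants but set size is ", s)
    vapply(seq_len(n_replicates), function(r)
      sum(frame_hit[sample.int(M, s)]), numeric(1))
  }))
  null_mean <- vapply(nulls, mean, numeric(1))
  per_cohort <- data.frame(cohort = cohorts, set_size = set_sizes,
                           null_mean = null_mean,
                           stringsAsFactors = FALSE)
  pooled_null <- Reduce(`+`, nulls)
  out <- list(per_cohort = per_cohort, pooled_null = pooled_null,
              n_replicates = n_replicates)
  if (!is.null(observed)) {
    observed <- rep_len(observed, length(validation))
    per_cohort$observed <- observed
    per_cohort$empirical_p <- vapply(seq_along(nulls), function(c_i)
      (1 + sum(nulls[[c_i]] >= observed[c_i])) / (1 + n_replicates),
      numeric(1))
    out$per_cohort <- per_cohort
    out$pooled_observed <- sum(observed)
    out$pooled_empirical_p <-
      (1 + sum(pooled_null >= sum(observed))) / (1 + n_replicates)
  }
  out
}

#' Sign test of direction concordance between discovery and validation
#'
#' Among validated variants (validation p below `alpha` after allele
#' alignment), counts those whose validation effect sign matches the
#' expected relation to the discovery sign (`"same"` or `"opposite"`), and
#' tests the concordant count against 0.5 with an exact two-sided binomial
#' test, per cohort and pooled. Per-variant z-statistics for both studies
#' are returned for plotting.
#'
#' @param discovery Discovery summary with `MarkerName`, `Allele1`,
#'   `Allele2`, `Effect`, `StdErr`.
#' @param validation Named list of validation summaries.
#' @param relation `"same"` or `"opposite"` expected sign relation.
#' @param alpha Validation threshold defining the tested subset.
#' @return list with `per_cohort` (cohort, n_validated, n_concordant, p),
#'   `pooled` (n_validated, n_concordant, p; `NA` with a reason when no
#'   variant is validated), and `z_data` (cohort, marker, z_discovery,
#'   z_validation, concordant).
#' @export
sign_concordance_test <- function(discovery, validation,
                                  relation = c("same", "opposite"),
                                  alpha = 0.05) {
  relation <- match.arg(relation)
  disc <- .norm_stats(discovery)
  cohorts <- names(validation)
  if (is.null(cohorts)) cohorts <- sprintf("cohort%d", seq_along(validation))
  z_rows <- list()
  per <- lapply(seq_along(validation), function(c_i) {
    val <- .norm_stats(validation[[c_i]])
    i <- match(disc$marker, val$marker)
    present <- !is.na(i)
    same <- present & disc$a1 == val$a1[i] & disc$a2 == val$a2[i]
    swap <- present & disc$a1 == val$a2[i] & disc$a2 == val$a1[i]
    beta_v <- ifelse(swap, -val$beta[i], val$beta[i])
    se_v <- val$se[i]
    p_v <- val$p[i]
    validated <- (same | swap) & !is.na(p_v) & p_v < alpha &
      !is.na(val$freq[i]) & val$freq[i] > 0 & val$freq[i] < 1
    validated[is.na(validated)] <- FALSE
    expected_sign <- if (relation == "same") sign(disc$beta) else
      -sign(disc$beta)
    conc <- validated & sign(beta_v) == expected_sign
    z_rows[[c_i]] <<- data.frame(
      cohort = rep(cohorts[c_i], sum(validated)),
      marker = disc$marker[validated],
      z_discovery = (disc$beta / disc$se)[validated],
      z_validation = (beta_v / se_v)[validated],
      concordant = conc[validated],
      stringsAsFactors = FALSE)
    n_val <- sum(validated, na.rm = TRUE)
    n_conc <- sum(conc, na.rm = TRUE)
    data.frame(cohort = cohorts[c_i], n_validated = n_val,
               n_concordant = n_conc,
               p = if (n_val > 0)
                 stats::binom.test(n_conc, n_val, 0.5)$p.value else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  z_data <- do.call(rbind, z_rows)
  n_val <- sum(per$n_validated)
  n_conc <- sum(per$n_concordant)
  pooled <- if (n_val > 0)
    list(n_validated = n_val, n_concordant = n_conc,
         p = stats::binom.test(n_conc, n_val, 0.5)$p.value)
  else
    list(n_validated = 0L, n_concordant = 0L, p = NA_real_,
         reason = "no validated variants; sign test skipped")
  list(per_cohort = per, pooled = pooled, z_data = z_data)
}
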
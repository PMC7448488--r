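# Validation counting, permutation null for validated counts, and the
# sign-concordance test.

mk_val <- function(marker, p, beta = 0.1, freq = 0.3, a1 = "A", a2 = "C") {
  data.frame(MarkerName = marker, Allele1 = a1, Allele2 = a2, Freq1 = freq,
             Effect = beta, StdErr = 0.05, `P-value` = p,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("validated counts respect presence, polymorphism and the strict threshold", {
  disc <- mk_val(sprintf("m%d", 1:10), p = rep(1e-9, 10))
  val <- mk_val(sprintf("m%d", 1:8),
                p = c(0.01, 0.04, 0.049, 0.05, 0.2, 0.6, 0.9, 0.001),
                freq = c(rep(0.3, 7), 0))   # m8 monomorphic
  counts <- count_validated(disc, list(v1 = val), alpha = 0.05)
  expect_equal(counts$n_present, 8)      # m9, m10 absent
  expect_equal(counts$n_polymorphic, 7)  # m8 monomorphic
  expect_equal(counts$n_validated, 3)    # 0.05 is NOT validated (strict <)
  expect_setequal(attr(counts, "union_validated"), c("m1", "m2", "m3"))
})

test_that("allele-mismatched variants leave the denominator", {
  disc <- mk_val(c("m1", "m2"), p = 1e-9)
  val <- mk_val(c("m1", "m2"), p = 0.01, a1 = c("A", "A"), a2 = c("C", "G"))
  expect_message(counts <- count_validated(disc, list(val)), "mismatch")
  expect_equal(counts$n_present, 1)
})

test_that("union count across cohorts is bounded by the per-cohort sum", {
  disc <- mk_val(sprintf("m%d", 1:6), p = 1e-9)
  v1 <- mk_val(sprintf("m%d", 1:6), p = c(0.01, 0.01, 0.5, 0.5, 0.5, 0.5))
  v2 <- mk_val(sprintf("m%d", 1:6), p = c(0.01, 0.5, 0.01, 0.5, 0.5, 0.5))
  counts <- count_validated(disc, list(a = v1, b = v2))
  expect_equal(length(attr(counts, "union_validated")), 3)
  expect_lte(length(attr(counts, "union_validated")),
             sum(counts$n_validated))
  # order of cohorts does not change the result
  counts_r <- count_validated(disc, list(b = v2, a = v1))
  expect_setequal(attr(counts_r, "union_validated"),
                  attr(counts, "union_validated"))
})

test_that("permutation null mean matches the sub-threshold frame fraction", {
  set.seed(61)
  # frame with exactly 20% of p-values below alpha
  frame <- mk_val(sprintf("f%d", 1:500),
                  p = c(runif(100, 0, 0.049), runif(400, 0.051, 1)))
  perm <- permutation_null_counts(list(c1 = frame), set_sizes = 10,
                                  n_replicates = 10000, alpha = 0.05,
                                  seed = 62)
  expect_lt(abs(perm$per_cohort$null_mean - 2), 3 * sqrt(10 * 0.2 * 0.8 / 10000) + 0.05)
  # uniform p-values: null mean near alpha * set_size
  frame_u <- mk_val(sprintf("u%d", 1:2000), p = (1:2000 - 0.5) / 2000)
  perm_u <- permutation_null_counts(list(c1 = frame_u), set_sizes = 100,
                                    n_replicates = 2000, alpha = 0.05,
                                    seed = 63)
  expect_lt(abs(perm_u$per_cohort$null_mean - 5), 0.3)
})

test_that("an observation beyond the null maximum reaches the add-one floor", {
  frame <- mk_val(sprintf("f%d", 1:300), p = runif(300, 0.2, 1))
  perm <- permutation_null_counts(list(c1 = frame), set_sizes = 20,
                                  observed = 15, n_replicates = 500,
                                  alpha = 0.05, seed = 64)
  expect_equal(perm$per_cohort$empirical_p, 1 / 501)
  expect_equal(perm$pooled_empirical_p, 1 / 501)
  expect_error(
    permutation_null_counts(list(c1 = frame[1:10, ]), set_sizes = 20,
                            n_replicates = 10, seed = 1), "frame")
})

test_that("sign test matches the exact binomial, including the worked cases", {
  # 5/5 concordant
  disc <- mk_val(sprintf("m%d", 1:5), p = 1e-9, beta = 0.2)
  val <- mk_val(sprintf("m%d", 1:5), p = 0.01, beta = 0.3)
  r <- sign_concordance_test(disc, list(v = val), relation = "same")
  expect_equal(r$pooled$p, 0.0625, tolerance = 1e-12)
  expect_equal(r$pooled$n_concordant, 5)
  # 3/6 concordant: p = 1
  disc6 <- mk_val(sprintf("m%d", 1:6), p = 1e-9, beta = 0.2)
  val6 <- mk_val(sprintf("m%d", 1:6), p = 0.01,
                 beta = c(0.3, 0.3, 0.3, -0.3, -0.3, -0.3))
  r6 <- sign_concordance_test(disc6, list(v = val6), relation = "same")
  expect_equal(r6$pooled$p, 1)
  # 30/73: compare with direct tail summation of Binomial(73, 1/2)
  disc73 <- mk_val(sprintf("m%d", 1:73), p = 1e-9, beta = 0.2)
  beta_v <- c(rep(0.3, 30), rep(-0.3, 43))
  val73 <- mk_val(sprintf("m%d", 1:73), p = 0.01, beta = beta_v)
  r73 <- sign_concordance_test(disc73, list(v = val73), relation = "same")
  dens <- dbinom(0:73, 73, 0.5)
  p_exact <- sum(dens[dens <= dbinom(30, 73, 0.5) * (1 + 1e-7)])
  expect_equal(r73$pooled$p, p_exact, tolerance = 1e-9)
})

test_that("opposite-relation concordance flips the expectation", {
  disc <- mk_val(sprintf("m%d", 1:4), p = 1e-9, beta = 0.2)
  val <- mk_val(sprintf("m%d", 1:4), p = 0.01, beta = -0.3)
  r <- sign_concordance_test(disc, list(v = val), relation = "opposite")
  expect_equal(r$pooled$n_concordant, 4)
  # swapped alleles in validation flip the working sign
  val_sw <- mk_val(sprintf("m%d", 1:4), p = 0.01, beta = 0.3,
                   a1 = "C", a2 = "A")
  r_sw <- sign_concordance_test(disc, list(v = val_sw), relation = "opposite")
  expect_equal(r_sw$pooled$n_concordant, 4)
})

test_that("zero validated variants skips the sign test with a reason", {
  disc <- mk_val("m1", p = 1e-9)
  val <- mk_val("m1", p = 0.9)
  r <- sign_concordance_test(disc, list(v = val))
  expect_true(is.na(r$pooled$p))
  expect_match(r$pooled$reason, "skipped")
})

test_that("permutation empirical p is calibrated under a uniform frame", {
  set.seed(65)
  ps <- replicate(200, {
    frame <- mk_val(sprintf("f%d", 1:400), p = runif(400))
    # the observed set is exchangeable with the null draws
    obs <- sum(runif(15) < 0.05)
    perm <- permutation_null_counts(list(c1 = frame), set_sizes = 15,
                                    observed = obs, n_replicates = 60,
                                    alpha = 0.05,
                                    seed = sample.int(1e6, 1))
    perm$per_cohort$empirical_p
  })
  # p is discrete (ties on small counts), so check calibration on coarse
  # bands: it must be conservative-to-uniform, never anti-conservative
  for (a in c(0.1, 0.3, 0.5)) {
    expect_lt(mean(ps <= a), a + 0.1)
  }
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.75)
})
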
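# REML variance components and the mixed-model association scan.

test_that("pure-noise phenotype gives a heritability indistinguishable from zero", {
  rp <- random_panel(250, 600, seed = 21)
  g <- build_grm(rp)
  set.seed(22)
  y <- rnorm(250)
  fit <- suppressWarnings(reml_fit(y, grms = list(poly = g)))
  expect_true(fit$converged)
  h2 <- fit$fractions["poly"]
  expect_lt(h2, 2 * fit$fractions_se["poly"] + 0.05)
})

test_that("an identity-like GRM flags the confounded model", {
  n <- 80
  g <- structure(list(G = diag(n), k = 100, ids = sprintf("i%d", 1:n),
                      variant_ids = NULL), class = "grm")
  set.seed(23)
  expect_warning(fit <- reml_fit(rnorm(n), grms = list(id = g)),
                 "singular|confounded")
  expect_true(fit$singular_ai)
})

test_that("rank-deficient fixed effects fail naming the collinear column", {
  rp <- random_panel(50, 100, seed = 24)
  g <- build_grm(rp)
  X <- cbind("(Intercept)" = 1, a = rnorm(50))
  X <- cbind(X, dup = X[, "a"])
  expect_error(reml_fit(rnorm(50), X, list(g)), "dup")
})

test_that("single-GRM REML recovers a simulated heritability", {
  # moderate scale; the acceptance suite runs the full parameter-recovery
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 500, n_chrom = 3,
                    chrom_bp = 2e7, n_variants = 2500, n_genes = 200,
                    n_set_genes = 10, h2 = 0.4, set_variance_share = 0,
                    n_causal_background = 150, seed = 25)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  g <- suppressWarnings(build_grm(panel))
  h2s <- sapply(1:8, function(r) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + r
    ph <- simulate_phenotypes(panel, ann$genes, ann$gene_set, cfg2)
    y <- preprocess_phenotype(ph$phenotypes$flight_time, ph$phenotypes$cohort)
    X <- stats::model.matrix(~ log(age) + factor(cg), data = ph$phenotypes)
    fit <- suppressWarnings(reml_fit(y, X, list(poly = g)))
    fit$fractions["poly"]
  })
  expect_lt(abs(mean(h2s) - 0.4), 2 * sd(h2s) / sqrt(8) + 0.02)
})

test_that("restricted log-likelihood is reproducible and finite", {
  rp <- random_panel(60, 150, seed = 26)
  g <- build_grm(rp)
  set.seed(27)
  y <- rnorm(60)
  f1 <- suppressWarnings(reml_fit(y, grms = list(g)))
  f2 <- suppressWarnings(reml_fit(y, grms = list(g)))
  expect_identical(f1$sigma2, f2$sigma2)
  expect_true(is.finite(f1$logLik))
})

test_that("reml_fit S3 methods behave like a fitted model object", {
  rp <- random_panel(80, 200, seed = 28)
  g <- build_grm(rp)
  set.seed(29)
  X <- cbind(1, rnorm(80))
  colnames(X) <- c("(Intercept)", "covar")
  y <- drop(X %*% c(1, 0.5)) + rnorm(80)
  fit <- suppressWarnings(reml_fit(y, X, list(poly = g)))
  expect_named(coef(fit), c("(Intercept)", "covar"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_equal(length(residuals(fit)), 80)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(80, 3))
  expect_output(print(summary(fit)), "Fixed effects")
})

test_that("with no genetic variance the scan reduces to per-variant OLS", {
  rp <- random_panel(120, 30, seed = 30)
  set.seed(31)
  X <- cbind(1, rnorm(120))
  y <- rnorm(120)
  vc <- list(sigma2 = c(poly = 0, residual = 1))
  g <- build_grm(rp)
  res <- mlma_scan(rp, y, X, grm = g, vc = vc)
  for (j in c(1, 7, 30)) {
    sm <- summary(lm(y ~ X[, 2] + rp$X[, j]))
    ols <- sm$coefficients
    expect_equal(res$beta[j], ols[3, 1], tolerance = 1e-8)
    # the scan uses the known residual variance (1), lm its estimate
    expect_equal(res$se[j], ols[3, 2] / sm$sigma, tolerance = 1e-6)
  }
})

test_that("scan effects equal a per-variant full GLS refit", {
  cfg <- small_cfg()
  st <- simulate_study(cfg)
  qc <- suppressWarnings(apply_filters(st$panel))
  y <- preprocess_phenotype(st$phenotypes$flight_time, st$phenotypes$cohort)
  X <- stats::model.matrix(~ cohort + log(age), data = st$phenotypes)
  g <- build_grm(qc$panel)
  vc <- suppressWarnings(reml_fit(y, X, list(poly = g)))
  res <- mlma_scan(qc$panel, y, X, grm = g, vc = vc)
  V <- vc$sigma2[["poly"]] * g$G + diag(vc$sigma2[["residual"]], length(y))
  L <- t(chol(V))
  yw <- forwardsolve(L, y)
  Xw <- forwardsolve(L, X)
  set.seed(32)
  for (j in sample(ncol(qc$panel$X), 10)) {
    x <- qc$panel$X[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    xw <- forwardsolve(L, x)
    fit <- lm(yw ~ 0 + Xw + xw)
    expect_equal(unname(res$beta[j]), unname(coef(fit)["xw"]),
                 tolerance = 1e-8)
  }
})

test_that("the leave-one-chromosome-out toggle produces a complete scan", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 150, n_chrom = 2,
                    chrom_bp = 5e6, n_variants = 300, n_genes = 40,
                    n_set_genes = 5, seed = 33)
  st <- simulate_study(cfg)
  qc <- suppressWarnings(apply_filters(st$panel))
  y <- preprocess_phenotype(st$phenotypes$flight_time, st$phenotypes$cohort)
  res <- suppressWarnings(mlma_scan(qc$panel, y, loco = TRUE))
  expect_equal(nrow(res), ncol(qc$panel$X))
  expect_true(all(is.finite(res$p) | is.na(res$p)))
  # LOCO removes the candidate's own tagging from the GRM, so the two
  # scans agree in direction but not exactly in magnitude
  res0 <- suppressWarnings(mlma_scan(qc$panel, y))
  ok <- is.finite(res$beta) & is.finite(res0$beta) & abs(res0$beta) > 0.05
  expect_gt(mean(sign(res$beta[ok]) == sign(res0$beta[ok])), 0.9)
})

test_that("constant variants give missing association results", {
  X <- cbind(rep(1L, 40), rbinom(40, 2, 0.4))
  rp <- make_panel(X)
  y <- rnorm(40)
  vc <- list(sigma2 = c(poly = 0, residual = 1))
  expect_warning(res <- mlma_scan(rp, y, grm = build_grm(rp), vc = vc),
                 "constant")
  expect_true(is.na(res$p[1]))
  expect_false(is.na(res$p[2]))
})
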
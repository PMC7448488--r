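#' Average-information REML for one or more genomic variance components
#'
#' Fits the linear mixed model `y = X beta + sum_i u_i + e` with
#' `u_i ~ N(0, G_i sigma_i^2)` and `e ~ N(0, I sigma_e^2)` by maximizing the
#' restricted likelihood of `V = sum_i sigma_i^2 G_i + sigma_e^2 I`.
#' Updates use the average-information (AI) algorithm with step-halving and
#' an EM fallback whenever an AI step would decrease the restricted
#' log-likelihood; negative proposals are bent to a small positive floor.
#' Standard errors of the variance components come from the inverse AI
#' matrix at the optimum, and standard errors of variance ratios from the
#' delta method.
#'
#' @param y Numeric response vector (no missing values).
#' @param X Fixed-effect design matrix (default: intercept only). Must have
#'   full column rank.
#' @param grms A single [build_grm()] result or a list of them, all over the
#'   same individuals as `y`.
#' @param start Optional starting values for `c(sigma_1^2, ...,
#'   sigma_e^2)`; by default each component starts at `var(y) / (n_comp +
#'   1)`.
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param max_iter Maximum number of iterations.
#' @param floor_frac Lower bound for each component, as a fraction of the
#'   phenotypic variance.
#' @param verbose Print the likelihood trajectory.
#'
#' @return An object of class `reml_fit`: variance-component estimates
#'   (`sigma2`, named, residual last) with standard errors (`sigma2_se`),
#'   variance ratios (`fractions`: each component over the total, plus
#'   `h2_g1_of_genetic` = first over the genetic total when two or more
#'   genetic components are fitted) with delta-method SEs, GLS fixed-effect
#'   estimates (`beta`, `beta_se`), the restricted log-likelihood, iteration
#'   count, convergence flag, and the inverse AI matrix.
#' @export
reml_fit <- function(y, X = NULL, grms, start = NULL, tol = 1e-8,
                     max_iter = 100L, floor_frac = 1e-6, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must not contain missing values")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1,
            all(vapply(grms, inherits, logical(1), "grm")))
  Gs <- lapply(grms, function(g) {
    stopifnot(nrow(g$G) == n)
    unname(g$G)
  })
  nc <- length(Gs)
  comp_names <- names(grms)
  if (is.null(comp_names) || any(!nzchar(comp_names)))
    comp_names <- paste0("g", seq_len(nc))
  comp_names <- c(comp_names, "residual")
  vp <- stats::var(y)
  floor_val <- floor_frac * vp
  theta <- if (is.null(start)) rep(vp / (nc + 1), nc + 1) else as.numeric(start)
  stopifnot(length(theta) == nc + 1)
  theta <- pmax(theta, floor_val)

  eval_point <- function(theta) {
    V <- diag(theta[nc + 1], n)
    for (i in seq_len(nc)) V <- V + theta[i] * Gs[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtViX_inv <- chol2inv(chx)
    P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll, Vi = Vi, ViX = ViX,
         XtViX_inv = XtViX_inv)
  }

  derivs <- function(st, theta) {
    # score and AI matrix; component nc+1 is the residual (G = I)
    r <- vector("list", nc + 1)
    for (i in seq_len(nc)) r[[i]] <- Gs[[i]] %*% st$Py
    r[[nc + 1]] <- st$Py
    Pr <- lapply(r, function(ri) st$P %*% ri)
    score <- numeric(nc + 1)
    tr_P <- sum(diag(st$P))
    for (i in seq_len(nc))
      score[i] <- -0.5 * (sum(st$P * Gs[[i]]) - sum(st$Py * r[[i]]))
    score[nc + 1] <- -0.5 * (tr_P - sum(st$Py * st$Py))
    AI <- matrix(0, nc + 1, nc + 1)
    for (i in seq_len(nc + 1)) for (j in i:(nc + 1)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(r[[i]] * Pr[[j]])
    }
    list(score = score, AI = AI, r = r)
  }

  st <- eval_point(theta)
  if (is.null(st)) stop("variance matrix not positive definite at start")
  converged <- FALSE
  iter <- 0L
  AIm <- NULL
  singular_ai <- FALSE
  # best point seen: near a variance floor the log-likelihood surface is
  # flat and its evaluation noise can exceed the tolerance, so the loop
  # also stops once several iterations fail to improve on the best value
  ll_best <- st$ll
  theta_best <- theta
  st_best <- st
  plateau <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- derivs(st, theta)
    AIm <- d$AI
    # components pinned at the floor whose score pushes further down are
    # frozen out of this iteration's update (constrained AI-REML)
    frozen <- theta <= floor_val * (1 + 1e-8) & d$score < 0
    delta <- rep(0, nc + 1)
    free <- !frozen
    if (any(free)) {
      A_free <- AIm[free, free, drop = FALSE]
      if (rcond(A_free) < 1e-12) {
        singular_ai <- TRUE
      } else {
        delta[free] <- solve(A_free, d$score[free])
      }
    }
    accepted <- FALSE
    st_new <- NULL
    if (any(delta != 0)) {
      for (step in c(1, 0.5, 0.1)) {
        prop <- pmax(theta + step * delta, floor_val)
        cand <- eval_point(prop)
        if (!is.null(cand) && cand$ll >= st$ll - 1e-10) {
          accepted <- TRUE
          st_new <- cand
          break
        }
      }
    }
    if (!accepted) {
      # EM fallback: sigma_i^2 <- sigma_i^2 + sigma_i^4 (y'P G_i P y - tr(P G_i)) / n
      prop <- theta
      for (i in seq_len(nc))
        prop[i] <- theta[i] + theta[i]^2 *
          (sum(st$Py * d$r[[i]]) - sum(st$P * Gs[[i]])) / n
      prop[nc + 1] <- theta[nc + 1] + theta[nc + 1]^2 *
        (sum(st$Py^2) - sum(diag(st$P))) / n
      prop <- pmax(prop, floor_val)
      st_new <- eval_point(prop)
      if (is.null(st_new)) break
    }
    dll <- st_new$ll - st$ll
    moved <- max(abs(prop - theta)) / max(vp, 1e-12)
    theta <- prop
    st <- st_new
    if (st$ll > ll_best + tol) {
      ll_best <- st$ll
      theta_best <- theta
      st_best <- st
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
    }
    if (verbose)
      log_msg("iter %d  logL %.6f  (%s)", iter, st$ll,
              if (accepted) "AI" else "EM")
    if (abs(dll) < tol || moved < 1e-12 || plateau >= 5L) {
      converged <- TRUE
      break
    }
  }
  if (ll_best > st$ll) {
    theta <- theta_best
    st <- st_best
  }
  d <- derivs(st, theta)
  AIm <- d$AI
  ai_inv <- if (rcond(AIm) > 1e-12) solve(AIm) else
    matrix(NA_real_, nc + 1, nc + 1)
  if (any(!is.finite(ai_inv))) singular_ai <- TRUE
  sigma2 <- theta
  names(sigma2) <- comp_names
  sigma2_se <- sqrt(pmax(diag(ai_inv), 0))
  names(sigma2_se) <- comp_names
  # variance ratios: each component over the full total
  tot <- sum(sigma2)
  fractions <- sigma2[seq_len(nc)] / tot
  frac_se <- vapply(seq_len(nc), function(i) {
    gr <- rep(-sigma2[i] / tot^2, nc + 1)
    gr[i] <- (tot - sigma2[i]) / tot^2
    sqrt(max(0, drop(t(gr) %*% ai_inv %*% gr)))
  }, numeric(1))
  names(fractions) <- names(frac_se) <- comp_names[seq_len(nc)]
  extra <- NULL
  if (nc >= 2) {
    gtot <- sum(sigma2[1:2])
    f12 <- sigma2[1] / gtot
    gr <- numeric(nc + 1)
    gr[1] <- sigma2[2] / gtot^2
    gr[2] <- -sigma2[1] / gtot^2
    extra <- c(value = unname(f12),
               se = sqrt(max(0, drop(t(gr) %*% ai_inv %*% gr))))
  }
  beta <- drop(st$XtViX_inv %*% crossprod(st$ViX, y))
  names(beta) <- colnames(X)
  beta_vcov <- st$XtViX_inv
  dimnames(beta_vcov) <- list(colnames(X), colnames(X))
  fit <- structure(list(
    sigma2 = sigma2, sigma2_se = sigma2_se,
    fractions = fractions, fractions_se = frac_se,
    genetic_fraction_g1 = extra,
    beta = beta, beta_se = sqrt(diag(beta_vcov)), beta_vcov = beta_vcov,
    logLik = st$ll, iterations = iter, converged = converged,
    singular_ai = singular_ai, ai_inv = ai_inv, n = n,
    n_components = nc, y = y, X = X, grms = grms,
    call = match.call()), class = "reml_fit")
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")
  if (singular_ai)
    warning("average-information matrix near singular; components may be ",
            "confounded (e.g. an identity-like GRM)")
  fit
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("REML fit:", x$n_components, "genomic component(s) + residual, n =",
      x$n, "\n")
  tab <- cbind(estimate = x$sigma2, se = x$sigma2_se)
  print(round(tab, digits))
  fr <- cbind(fraction = x$fractions, se = x$fractions_se)
  rownames(fr) <- paste0(names(x$fractions), "/total")
  print(round(fr, digits))
  cat("logLik:", format(x$logLik, digits = 8),
      " iterations:", x$iterations,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  z <- object$beta / object$beta_se
  coef_tab <- cbind(Estimate = object$beta, `Std. Error` = object$beta_se,
                    `z value` = z,
                    `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = coef_tab)
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
vcov.reml_fit <- function(object, ...) object$beta_vcov

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$sigma2) + length(object$beta),
            class = "logLik")
}

# V implied by the fitted components
fitted_V <- function(object) {
  n <- object$n
  V <- diag(object$sigma2[["residual"]], n)
  for (i in seq_len(object$n_components))
    V <- V + object$sigma2[[i]] * unname(object$grms[[i]]$G)
  V
}

#' @export
fitted.reml_fit <- function(object, ...) {
  # conditional fit X beta + BLUP of the summed genetic effects
  xb <- drop(object$X %*% object$beta)
  V <- fitted_V(object)
  r <- object$y - xb
  w <- solve(V, r)
  g <- numeric(object$n)
  for (i in seq_len(object$n_components))
    g <- g + object$sigma2[[i]] * drop(unname(object$grms[[i]]$G) %*% w)
  xb + g
}

#' @export
residuals.reml_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
simulate.reml_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- fitted_V(object)
  ch <- chol(V)
  xb <- drop(object$X %*% object$beta)
  out <- as.data.frame(
    xb + t(ch) %*% matrix(stats::rnorm(object$n * nsim), object$n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
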
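#' Greedy LD clumping of meta-analysis results
#'
#' Standard greedy clumping: take the unassigned variant with the smallest
#' p-value below `p_thresh` as a lead; assign to its clump every unassigned
#' significant variant on the same chromosome within `window_bp` of the
#' lead whose squared dosage correlation with the lead (in the LD reference
#' panel, missing dosages mean-imputed) is at least `r2_thresh`; repeat.
#' Ties on p are broken by (chromosome, position). Significant variants
#' absent from the LD panel are treated as unlinked (they can lead their
#' own clump but never join another) and are counted in the attribute
#' `n_unlinked`.
#'
#' @param summary A meta-analysis result ([ivw_meta()]) or any data.frame
#'   with `MarkerName` and `P-value` columns.
#' @param ld_panel [genotype_panel()] used as LD reference.
#' @param p_thresh Significance threshold for clumped variants.
#' @param window_bp Half-window around the lead in base pairs.
#' @param r2_thresh Minimum squared correlation with the lead.
#' @return A list of clumps, each a list with `lead` (one-row data.frame of
#'   the lead's summary), `members` (variant IDs including the lead),
#'   `chrom`, `bp_min`, `bp_max`.
#' @export
clump <- function(summary, ld_panel, p_thresh = 5e-8, window_bp = 5e6,
                  r2_thresh = 0.1) {
  stopifnot(inherits(ld_panel, "genotype_panel"))
  mk <- as.character(summary$MarkerName)
  p <- as.numeric(summary[["P-value"]])
  sig <- which(!is.na(p) & p < p_thresh)
  if (!length(sig)) return(structure(list(), n_unlinked = 0L))
  idx_panel <- match(mk[sig], ld_panel$map$variant_id)
  chrom <- ld_panel$map$chrom[idx_panel]
  bp <- ld_panel$map$bp[idx_panel]
  # fall back to coordinates from the summary table if present
  if ("chrom" %in% names(summary)) chrom[is.na(idx_panel)] <-
      as.character(summary$chrom[sig][is.na(idx_panel)])
  if ("bp" %in% names(summary)) bp[is.na(idx_panel)] <-
      summary$bp[sig][is.na(idx_panel)]
  n_unlinked <- sum(is.na(idx_panel))
  if (n_unlinked)
    log_msg("clump: %d significant variant(s) absent from the LD panel, treated as unlinked",
            n_unlinked)
  Xd <- impute_dosages(ld_panel)
  ord <- order(p[sig], chrom_order(chrom), bp)
  remaining <- ord
  clumps <- list()
  assigned <- rep(FALSE, length(sig))
  for (lead_i in ord) {
    if (assigned[lead_i]) next
    assigned[lead_i] <- TRUE
    members <- lead_i
    if (!is.na(idx_panel[lead_i])) {
      cand <- which(!assigned & chrom == chrom[lead_i] &
                      abs(bp - bp[lead_i]) <= window_bp &
                      !is.na(idx_panel))
      if (length(cand)) {
        x_lead <- Xd[, idx_panel[lead_i]]
        r <- suppressWarnings(
          stats::cor(x_lead, Xd[, idx_panel[cand], drop = FALSE]))
        r2 <- drop(r)^2
        take <- cand[!is.na(r2) & r2 >= r2_thresh]
        assigned[take] <- TRUE
        members <- c(members, take)
      }
    }
    clumps[[length(clumps) + 1]] <- list(
      lead = summary[sig[lead_i], , drop = FALSE],
      members = mk[sig[members]],
      chrom = chrom[lead_i],
      bp_min = min(bp[members], na.rm = TRUE),
      bp_max = max(bp[members], na.rm = TRUE))
  }
  structure(clumps, n_unlinked = n_unlinked)
}

#' Percent of additive genetic variance explained by one variant
#'
#' `%Vg = 2 p (1 - p) b^2 / Vg * 100` for allele frequency `p`,
#' allele-substitution effect `b` and additive genetic variance `Vg`.
#' Vectorized over `freq` and `b`.
#'
#' @param freq A1 allele frequency in (0, 1).
#' @param b Allele-substitution effect for A1.
#' @param Vg Additive genetic variance (> 0).
#' @return Percent of `Vg` explained.
#' @export
pct_vg <- function(freq, b, Vg) {
  if (any(Vg <= 0)) stop("Vg must be positive")
  if (any(freq <= 0 | freq >= 1)) stop("freq must lie in (0, 1)")
  2 * freq * (1 - freq) * b^2 / Vg * 100
}

#' Map candidate genes to clumps by physical distance
#'
#' Reports protein-coding genes whose body intersects the clump's spanned
#' window extended by `flank_bp` on both sides; the distance is from the
#' lead variant position to the nearest gene edge (0 when the lead falls
#' inside the gene). Coordinates are 1-based inclusive.
#'
#' @param clumps Output of [clump()].
#' @param annotation Gene data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `biotype`).
#' @param flank_bp Flank added around the clump window.
#' @return data.frame with one row per (clump, gene): `clump`, `lead`,
#'   `gene_id`, `distance_bp`.
#' @export
map_genes_to_clumps <- function(clumps, annotation, flank_bp = 2e5) {
  ann <- annotation[annotation$biotype == "protein_coding", , drop = FALSE]
  rows <- list()
  for (ci in seq_along(clumps)) {
    cl <- clumps[[ci]]
    lead_bp <- cl$lead$bp
    if (is.null(lead_bp) || !length(lead_bp) || is.na(lead_bp)) {
      # locate the lead inside the clump span if the summary lacks bp
      lead_bp <- cl$bp_min
    }
    hit <- ann$chrom == cl$chrom &
      ann$start <= cl$bp_max + flank_bp &
      ann$end >= cl$bp_min - flank_bp
    if (!any(hit)) next
    g <- ann[hit, , drop = FALSE]
    dist <- ifelse(lead_bp >= g$start & lead_bp <= g$end, 0,
                   pmin(abs(lead_bp - g$start), abs(lead_bp - g$end)))
    rows[[length(rows) + 1]] <- data.frame(
      clump = ci, lead = cl$members[1], gene_id = g$gene_id,
      distance_bp = dist, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(clump = integer(0), lead = character(0),
                      gene_id = character(0), distance_bp = numeric(0)))
  do.call(rbind, rows)
}

#' Map variants to gene windows
#'
#' A variant belongs to a gene's window iff
#' `start - flank_bp <= bp <= end + flank_bp` (closed interval, 1-based
#' coordinates); a variant may map to several genes.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `bp` (a panel
#'   `map` works directly).
#' @param genes Gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param flank_bp Window flank in base pairs.
#' @return data.frame of incidences: `variant_id`, `gene_id`.
#' @export
map_variants_to_gene_windows <- function(variants, genes, flank_bp = 1e5) {
  rows <- vector("list", nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    hit <- variants$chrom == g$chrom &
      variants$bp >= g$start - flank_bp &
      variants$bp <= g$end + flank_bp
    if (any(hit))
      rows[[gi]] <- data.frame(variant_id = variants$variant_id[hit],
                               gene_id = g$gene_id,
                               stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(variant_id = character(0), gene_id = character(0)))
  do.call(rbind, rows)
}

#' Filter an ortholog table into a candidate gene set
#'
#' Retains genes at least `min_identity` percent identical to their human
#' counterpart, protein-coding, and autosomal. For developmental-delay
#' (DDD-style) sets, three further string filters apply: status
#' `"confirmed"`, mutation consequence containing `"loss of function"`, and
#' phenotype class containing `"Brain/Cognition"`.
#'
#' @param ortholog_table data.frame with columns `gene_id`, `chrom`,
#'   `biotype`, `percent_identity`, and for DDD additionally `status`,
#'   `consequence`, `phenotype_class`.
#' @param label Set label (e.g. `"ASD"`, `"SCZ"`, `"NEU"`, `"DDD"`); the
#'   extra filters trigger on `"DDD"`.
#' @param min_identity Identity threshold in percent (inclusive).
#' @return A gene set: list with `label` and sorted unique `gene_ids`.
#' @export
orthology_filter <- function(ortholog_table, label, min_identity = 60) {
  need <- c("gene_id", "chrom", "biotype", "percent_identity")
  if (identical(toupper(label), "DDD"))
    need <- c(need, "status", "consequence", "phenotype_class")
  miss <- setdiff(need, names(ortholog_table))
  if (length(miss))
    stop("ortholog table missing column(s): ", paste(miss, collapse = ", "))
  t <- ortholog_table
  keep <- t$percent_identity >= min_identity &
    t$biotype == "protein_coding" &
    !(t$chrom %in% NON_AUTOSOMES)
  if (identical(toupper(label), "DDD"))
    keep <- keep & tolower(t$status) == "confirmed" &
      grepl("loss of function", t$consequence, ignore.case = TRUE) &
      grepl("brain/cognition", t$phenotype_class, ignore.case = TRUE)
  list(label = label, gene_ids = sort(unique(t$gene_id[keep & !is.na(keep)])))
}

#' Sum-of-chi-square gene / set association test
#'
#' For the variants mapped to a gene (or arbitrary window set), the test
#' statistic is the sum of squared GWAS z-scores, `T = sum z_j^2`. Under
#' the null `T` is distributed as a weighted sum of 1-df chi-squares whose
#' weights are the eigenvalues of the variants' genotype correlation matrix
#' in the LD reference panel; the tail probability is computed by Imhof
#' numerical inversion with a Satterthwaite moment-matching fallback. The
#' method actually used is recorded per gene.
#'
#' @param summary Meta-analysis (or GWAS) summary with `MarkerName`,
#'   `Effect`, `StdErr` (z is `Effect/StdErr`).
#' @param ld_panel [genotype_panel()] LD reference.
#' @param genes Gene annotation data.frame; one test per row.
#' @param flank_bp Gene-window flank for variant mapping.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `n_variants`,
#'   `chisq`, `p`, `method` (`imhof`, `satterthwaite`, `chisq1`, or
#'   `empty`).
#' @export
set_based_test <- function(summary, ld_panel, genes, flank_bp = 5e4) {
  stopifnot(inherits(ld_panel, "genotype_panel"))
  z_all <- summary$Effect / summary$StdErr
  names(z_all) <- as.character(summary$MarkerName)
  Xd <- impute_dosages(ld_panel)
  inc <- map_variants_to_gene_windows(ld_panel$map, genes, flank_bp)
  out <- genes[, intersect(c("gene_id", "chrom", "start", "end"),
                           names(genes)), drop = FALSE]
  out$n_variants <- 0L
  out$chisq <- NA_real_
  out$p <- NA_real_
  out$method <- "empty"
  for (gi in seq_len(nrow(genes))) {
    vids <- inc$variant_id[inc$gene_id == genes$gene_id[gi]]
    vids <- vids[vids %in% names(z_all)]
    z <- z_all[vids]
    z <- z[is.finite(z)]
    if (!length(z)) next
    T_obs <- sum(z^2)
    out$n_variants[gi] <- length(z)
    out$chisq[gi] <- T_obs
    if (length(z) == 1) {
      out$p[gi] <- stats::pchisq(T_obs, 1, lower.tail = FALSE)
      out$method[gi] <- "chisq1"
      next
    }
    R <- stats::cor(Xd[, match(names(z), ld_panel$map$variant_id),
                       drop = FALSE])
    lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    res <- weighted_chisq_pvalue(T_obs, lam)
    out$p[gi] <- res$p
    out$method[gi] <- res$method
  }
  rownames(out) <- NULL
  out
}

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_i lambda_i chi2_1 > q)` by Imhof's inversion integral
#' (adaptive quadrature); if the integration fails or returns a value
#' outside \[0, 1\], falls back to Satterthwaite moment matching (a scaled
#' chi-square with matched mean and variance). Eigenvalues below
#' `1e-8 * max(lambda)` are truncated for numerical stability.
#'
#' @param q Observed statistic.
#' @param lambda Weights (eigenvalues), not all zero.
#' @return list with `p` and `method` (`"imhof"` or `"satterthwaite"`).
#' @export
weighted_chisq_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-8 * max(lambda)]
  stopifnot(length(lambda) >= 1, q >= 0)
  if (max(lambda) / min(lambda) < 1 + 1e-10) {
    # equal weights: plain chi-square
    return(list(p = stats::pchisq(q / lambda[1], df = length(lambda),
                                  lower.tail = FALSE),
                method = "imhof"))
  }
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    # analytic limit as u -> 0
    out[u < 1e-12] <- 0.5 * (sum(lambda) - q)
    out
  }
  # Integrate blockwise: the integrand oscillates with asymptotic period
  # 4*pi/q and its envelope decays like u^-(1 + m/2), so successive blocks
  # of ~50 periods shrink geometrically; stop once two consecutive blocks
  # are negligible.
  block_len <- 50 * 4 * pi / max(q, sum(lambda) * 1e-3, 1e-6)
  p <- tryCatch({
    total <- 0
    small <- 0L
    a <- 0
    for (blk in 1:400) {
      int <- stats::integrate(integrand, a, a + block_len,
                              rel.tol = 1e-8, abs.tol = 1e-11,
                              subdivisions = 2000L)
      total <- total + int$value
      a <- a + block_len
      small <- if (abs(int$value) < 1e-10) small + 1L else 0L
      if (small >= 2L) break
    }
    0.5 + total / pi
  }, error = function(e) NA_real_)
  if (is.finite(p) && p > -1e-8 && p < 1 + 1e-8)
    return(list(p = min(max(p, 1e-300), 1), method = "imhof"))
  # moment matching: mean sum(lambda), variance 2 sum(lambda^2)
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  scale <- s2 / s1
  df <- s1^2 / s2
  list(p = stats::pchisq(q / scale, df = df, lower.tail = FALSE),
       method = "satterthwaite")
}
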
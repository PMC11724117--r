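# Single-SNP association testing with population parameters previously
# determined (P3D): variance components are estimated once under the
# no-SNP null model and reused for every SNP, whose fixed regression
# coefficient is then obtained by generalised least squares through the
# projection P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1 of the null model.
# An exact-refit mode (variance components re-estimated per SNP) is
# available for validation.

# P %*% M from a fitted null model (keep_vinv = TRUE)
null_project <- function(fit, M) {
  VM <- fit$Vinv %*% M
  VM - fit$VinvX %*% solve(fit$XtViX, crossprod(fit$VinvX, M))
}

# GLS effect and SE for a batch of single covariates (columns of Xs)
gls_scan <- function(fit, Xs, chunk = 512) {
  m <- ncol(Xs)
  beta <- se <- rep(NA_real_, m)
  for (j0 in seq(1, m, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1, m)
    Xc <- Xs[, jj, drop = FALSE]
    PX <- null_project(fit, Xc)
    xpx <- colSums(Xc * PX)
    xpy <- colSums(Xc * fit$Py)
    ok <- xpx > 1e-10 * pmax(colSums(Xc^2), 1)
    beta[jj] <- ifelse(ok, xpy / xpx, NA_real_)
    se[jj] <- ifelse(ok, sqrt(1 / xpx), NA_real_)
  }
  list(beta = beta, se = se)
}

# dosage covariates mapped to plot rows, mean-imputed within `lines`
snp_covariates <- function(gm, snps, lines, row_lines) {
  d <- impute_mean(gm$dosage[match(lines, gm$samples$line), snps, drop = FALSE])
  d[match(row_lines, lines), , drop = FALSE]
}

finish_assoc <- function(out, mode, alpha) {
  out$z <- out$beta / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out$p[!is.na(out$beta) & out$beta == 0] <- 1
  m <- sum(!is.na(out$p))
  thr <- if (m >= 1) bonferroni_threshold(m, alpha)$threshold else NA_real_
  out$significant <- !is.na(out$p) & !is.na(thr) & out$p <= thr
  structure(out,
    mode = mode, alpha = alpha, m_tests = m, bonferroni = thr,
    class = c("mpgwas_gwas", class(out))
  )
}

#' Single-population GWAS
#'
#' Tests every SNP with minor allele count >= 30 in the population by
#' adding its alt-allele dosage as a fixed regression to the plot-level
#' mixed model. The Wald z score is the estimated coefficient over its
#' standard error; two-sided p values come from the standard normal
#' survival function.
#'
#' @param plots Plot records.
#' @param gm A [geno_matrix()].
#' @param trait Trait column name.
#' @param population Population label.
#' @param grm Optional precomputed GRM over the population's phenotyped
#'   lines (computed from `gm` if omitted).
#' @param null_fit Optional [fit_plot_lmm()] fit to reuse (P3D).
#' @param snps Optional variant ids overriding the MAC filter.
#' @param spatial_mode,terms Model structure, see [fit_plot_lmm()].
#' @param alpha Genome-wide type-1 error rate for the Bonferroni
#'   threshold (default 0.05).
#' @param refit Re-estimate variance components for every SNP instead of
#'   reusing the null-model estimates (slow; for validation).
#' @param ... Passed to [reml_fit()].
#' @return An `mpgwas_gwas` tibble: `id`, `chrom`, `pos`, `mac`, `beta`,
#'   `se`, `z`, `p`, `significant`; attributes `mode`, `m_tests`,
#'   `bonferroni`. SNPs collinear with the fixed effects get `NA`
#'   estimates.
#' @export
gwas_single <- function(plots, gm, trait, population, grm = NULL,
                        null_fit = NULL, snps = NULL,
                        spatial_mode = "none",
                        terms = c("additive", "line", "gxe"),
                        alpha = 0.05, refit = FALSE, ...) {
  plots <- filter(as_tibble(plots), !is.na(.data[[trait]]),
                  .data$population == !!population)
  if (is.null(snps)) snps <- retained_snps(gm, "single30", population)
  lines <- sort(unique(plots$line))
  grm <- grm %n% compute_grm(gm, lines = lines)
  if (is.null(null_fit)) {
    null_fit <- fit_plot_lmm(plots, trait, grm,
      spatial_mode = spatial_mode, terms = terms, ...
    )
  }
  Xs <- snp_covariates(gm, snps, lines, null_fit$plots$line)
  res <- if (refit) {
    refit_scan(null_fit, Xs, ...)
  } else {
    gls_scan(null_fit$fit, Xs)
  }
  vi <- match(snps, gm$variants$id)
  out <- tibble(
    id = snps,
    chrom = gm$variants$chrom[vi],
    pos = gm$variants$pos[vi],
    mac = as.integer(minor_allele_count(gm, snps, lines)),
    beta = res$beta,
    se = res$se
  )
  out <- finish_assoc(out, "single", alpha)
  attr(out, "population") <- population
  attr(out, "null_fit") <- null_fit
  out
}

# exact refit: variance components re-estimated with the SNP in the model
refit_scan <- function(null_lmm, Xs, ...) {
  tv <- term_vlist(null_lmm$design, null_lmm$G_aligned, null_lmm$terms)
  y <- null_lmm$plots[[null_lmm$trait]]
  beta <- se <- rep(NA_real_, ncol(Xs))
  for (j in seq_len(ncol(Xs))) {
    Xa <- cbind(null_lmm$design$X, mpgwas_snp = Xs[, j])
    f <- tryCatch(
      reml_fit(y, Xa, tv$Vlist, q_levels = tv$q, keep_vinv = TRUE,
               init = pmax(null_lmm$fit$theta, 1e-8), ...),
      error = function(e) NULL
    )
    if (is.null(f)) next
    k <- match("mpgwas_snp", colnames(f$X))
    if (is.na(k)) next
    beta[j] <- f$beta[k]
    se[j] <- sqrt(f$beta_cov[k, k])
  }
  list(beta = beta, se = se)
}

#' Joint univariate multi-population GWAS (MP1)
#'
#' The trait is treated as identical across populations: one shared SNP
#' effect is fitted to the combined data with environments nested within
#' populations as fixed effects and a joint genomic relationship matrix.
#' SNPs must pass the combined MAC filter (total >= 30, >= 10 in every
#' population).
#'
#' @inheritParams gwas_single
#' @param populations Character vector of populations to combine.
#' @return An `mpgwas_gwas` tibble as in [gwas_single()].
#' @export
gwas_mp1 <- function(plots, gm, trait, populations, grm = NULL,
                     null_fit = NULL, snps = NULL,
                     spatial_mode = "none",
                     terms = c("additive", "line", "gxe"),
                     alpha = 0.05, ...) {
  plots <- filter(as_tibble(plots), !is.na(.data[[trait]]),
                  .data$population %in% populations)
  if (is.null(snps)) snps <- retained_snps(gm, "multi30_10", populations)
  lines <- sort(unique(plots$line))
  grm <- grm %n% compute_grm(gm, lines = lines)
  if (is.null(null_fit)) {
    null_fit <- fit_plot_lmm(plots, trait, grm,
      spatial_mode = spatial_mode, terms = terms, ...
    )
  }
  Xs <- snp_covariates(gm, snps, lines, null_fit$plots$line)
  res <- gls_scan(null_fit$fit, Xs)
  vi <- match(snps, gm$variants$id)
  out <- tibble(
    id = snps,
    chrom = gm$variants$chrom[vi],
    pos = gm$variants$pos[vi],
    mac = as.integer(minor_allele_count(gm, snps, lines)),
    beta = res$beta,
    se = res$se
  )
  out <- finish_assoc(out, "mp1", alpha)
  attr(out, "populations") <- populations
  attr(out, "null_fit") <- null_fit
  out
}

#' Multivariate multi-population GWAS (MP2)
#'
#' The trait in each population is a separate, genetically correlated
#' response ([fit_multipop_lmm()]). Each SNP gets one fixed regression
#' coefficient per population; the estimation-error covariances between
#' the population-specific coefficients come from the inverse coefficient
#' matrix of the joint GLS system, and the per-SNP statistics are merged
#' by [combine_scaled()] into one scaled coefficient, z score and p
#' value. With a single population the result reduces to
#' [gwas_single()].
#'
#' @inheritParams gwas_mp1
#' @param null_fit Optional [fit_multipop_lmm()] fit to reuse.
#' @return An `mpgwas_gwas` tibble with per-population columns
#'   `beta_<pop>`, `se_<pop>`, pairwise `cov_<pop1>_<pop2>`, combined
#'   `b_scaled`, `se_scaled`, `z`, `p`, `significant`.
#' @export
gwas_mp2 <- function(plots, gm, trait, populations, grm = NULL,
                     null_fit = NULL, snps = NULL,
                     spatial_mode = "none",
                     terms = c("additive", "line", "gxe"),
                     alpha = 0.05, ...) {
  np <- length(populations)
  plots <- filter(as_tibble(plots), !is.na(.data[[trait]]),
                  .data$population %in% populations)
  if (np == 1) {
    return(gwas_single(plots, gm, trait, populations, grm,
      snps = snps, spatial_mode = spatial_mode, terms = terms,
      alpha = alpha, ...
    ))
  }
  if (is.null(snps)) snps <- retained_snps(gm, "multi30_10", populations)
  lines <- sort(unique(plots$line))
  grm <- grm %n% compute_grm(gm, lines = lines)
  if (is.null(null_fit)) {
    null_fit <- fit_multipop_lmm(plots, trait, grm, populations,
      spatial_mode = spatial_mode, terms = terms, ...
    )
  }
  fit <- null_fit$fit
  # stacked rows: group_plots order
  row_lines <- unlist(lapply(null_fit$group_plots, function(d) d$line), use.names = FALSE)
  n <- length(row_lines)
  Xall <- snp_covariates(gm, snps, lines, row_lines)
  m <- length(snps)
  # per-population masked covariates and their projections
  masks <- lapply(seq_len(np), function(k) {
    msk <- rep(0, n)
    msk[null_fit$rows[[k]]] <- 1
    msk
  })
  M <- array(0, c(np, np, m))
  v <- matrix(0, np, m)
  chunk <- 512
  for (j0 in seq(1, m, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1, m)
    Xc <- Xall[, jj, drop = FALSE]
    Xk <- lapply(masks, function(msk) Xc * msk)
    Tk <- lapply(Xk, function(Xm) null_project(fit, Xm))
    for (a in seq_len(np)) {
      v[a, jj] <- colSums(Xk[[a]] * fit$Py)
      for (b in seq_len(np)) {
        if (b < a) next
        M[a, b, jj] <- M[b, a, jj] <- colSums(Xk[[a]] * Tk[[b]])
      }
    }
  }
  beta <- se <- matrix(NA_real_, m, np)
  covs <- matrix(NA_real_, m, np * (np - 1) / 2)
  comb <- matrix(NA_real_, m, 4) # b_scaled, se_scaled, z, p
  pair_idx <- which(upper.tri(diag(np)), arr.ind = TRUE)
  for (i in seq_len(m)) {
    Mi <- M[, , i]
    if (any(diag(Mi) <= 1e-10)) next
    Ci <- tryCatch(solve(Mi), error = function(e) NULL)
    if (is.null(Ci)) next
    bi <- drop(Ci %*% v[, i])
    beta[i, ] <- bi
    se[i, ] <- sqrt(diag(Ci))
    covs[i, ] <- Ci[pair_idx]
    cs <- combine_scaled(bi, sqrt(diag(Ci)), Ci)
    comb[i, ] <- c(cs$b_scaled, cs$se_scaled, cs$z, cs$p)
  }
  vi <- match(snps, gm$variants$id)
  out <- tibble(
    id = snps,
    chrom = gm$variants$chrom[vi],
    pos = gm$variants$pos[vi],
    mac = as.integer(minor_allele_count(gm, snps, lines))
  )
  for (k in seq_len(np)) {
    out[[paste0("beta_", populations[k])]] <- beta[, k]
    out[[paste0("se_", populations[k])]] <- se[, k]
  }
  for (pr in seq_len(nrow(pair_idx))) {
    out[[paste0("cov_", populations[pair_idx[pr, 1]], "_",
                populations[pair_idx[pr, 2]])]] <- covs[, pr]
  }
  out$b_scaled <- comb[, 1]
  out$se_scaled <- comb[, 2]
  out$z <- comb[, 3]
  out$p <- comb[, 4]
  bf <- bonferroni_threshold(sum(!is.na(out$p)), alpha)
  out$significant <- !is.na(out$p) & out$p <= bf$threshold
  out <- structure(out,
    mode = "mp2", alpha = alpha, m_tests = bf$m, bonferroni = bf$threshold,
    populations = populations, null_fit = null_fit,
    class = c("mpgwas_gwas", class(out))
  )
  out
}

#' Combine scaled SNP regressions across populations
#'
#' The combined coefficient is the sum of the per-population coefficients
#' scaled by their standard errors; its standard error is
#' `sqrt(a' V a)` with `a` a ones vector and `V` the correlation-scale
#' covariance matrix of the scaled regressions (unit diagonal,
#' off-diagonals `cov(b_j, b_k) / (SE_j SE_k)`).
#'
#' @param beta Per-population coefficients.
#' @param se Their standard errors (all > 0).
#' @param cov_mat Estimation-error covariance matrix of `beta` (its
#'   diagonal must equal `se^2`; scaled off-diagonals must not exceed 1
#'   in magnitude).
#' @return List with `b_scaled`, `se_scaled`, `z`, `p`, `V` (scaled
#'   covariance matrix).
#' @export
combine_scaled <- function(beta, se, cov_mat) {
  if (any(se <= 0)) abort("standard errors must be > 0")
  V <- cov_mat / tcrossprod(se)
  diag(V) <- 1
  off <- V[upper.tri(V)]
  if (any(abs(off) > 1 + 1e-6)) {
    abort("scaled covariance exceeds 1 in magnitude: invalid covariance input")
  }
  off <- pmin(pmax(off, -1), 1)
  V[upper.tri(V)] <- off
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  b_scaled <- sum(beta / se)
  se_scaled <- sqrt(sum(V))
  z <- b_scaled / se_scaled
  list(
    b_scaled = b_scaled, se_scaled = se_scaled, z = z,
    p = 2 * pnorm(-abs(z)), V = V
  )
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return One-row tibble: `m`, `alpha`, `threshold` (`alpha / m`) and
#'   `neg_log10` (its -log10 form).
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) abort("`m` must be >= 1")
  tibble(m = m, alpha = alpha, threshold = alpha / m,
         neg_log10 = -log10(alpha / m))
}

#' Proportion of additive genetic variance explained by markers
#'
#' `PVE = 2 p (1 - p) b^2 / sigma2_g_raw`, where `p` is the alt-allele
#' frequency, `b` the estimated regression coefficient and
#' `sigma2_g_raw` the population's additive genetic variance *before*
#' the mean-diagonal inbreeding adjustment.
#'
#' @param freq Allele frequency (or vector).
#' @param beta Estimated SNP effect(s).
#' @param var_additive_raw Raw additive genetic variance (> 0).
#' @return Tibble: `freq`, `beta`, `pve` (fraction), `pve_pct`.
#' @export
pve <- function(freq, beta, var_additive_raw) {
  if (var_additive_raw <= 0) abort("`var_additive_raw` must be > 0")
  val <- 2 * freq * (1 - freq) * beta^2 / var_additive_raw
  tibble(freq = freq, beta = beta, pve = val, pve_pct = 100 * val)
}

#' Group significant associations into candidate QTLs
#'
#' Significant SNPs on a chromosome are merged into one candidate QTL
#' while successive positions are at most `max_gap` apart; the interval
#' spans the first to the last member SNP (a point interval for a
#' singleton) and the lead SNP is the member with the smallest p value.
#'
#' @param assoc An association tibble with columns `id`, `chrom`, `pos`,
#'   `p` (e.g. from [gwas_single()]).
#' @param threshold Significance threshold on `p` (default: the result's
#'   Bonferroni attribute).
#' @param max_gap Maximum within-QTL gap between successive significant
#'   SNPs, bp (default 5 Mbp).
#' @return Tibble: `chrom`, `start`, `end`, `n_snps`, `lead_id`,
#'   `lead_pos`, `lead_p`.
#' @export
group_qtls <- function(assoc, threshold = NULL, max_gap = 5e6) {
  threshold <- threshold %n% attr(assoc, "bonferroni")
  if (is.null(threshold)) abort("no `threshold` given and no Bonferroni attribute")
  sig <- assoc %>%
    filter(!is.na(.data$p), .data$p <= threshold) %>%
    arrange(.data$chrom, .data$pos)
  if (nrow(sig) == 0) {
    return(tibble(
      chrom = character(0), start = numeric(0), end = numeric(0),
      n_snps = integer(0), lead_id = character(0), lead_pos = numeric(0),
      lead_p = numeric(0)
    ))
  }
  sig <- sig %>%
    group_by(.data$chrom) %>%
    mutate(qtl_no = cumsum(c(1, as.integer(diff(.data$pos) > max_gap)))) %>%
    ungroup()
  sig %>%
    group_by(.data$chrom, .data$qtl_no) %>%
    summarise(
      start = min(.data$pos), end = max(.data$pos), n_snps = n(),
      lead_id = .data$id[which.min(.data$p)],
      lead_pos = .data$pos[which.min(.data$p)],
      lead_p = min(.data$p), .groups = "drop"
    ) %>%
    select(-"qtl_no") %>%
    arrange(.data$chrom, .data$start)
}
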
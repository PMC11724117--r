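# Validation studies bundled with the package. Each experiment builds
# its own simulated data at fixed study conditions, runs the relevant
# pipeline stage, and returns the measured quantities; the acceptance
# script and the test suite both call these functions.

#' Null calibration of the three GWAS modes
#'
#' Simulates two differentiated populations with *no* QTLs but a real
#' polygenic background (the per-SNP null hypothesis of a heritable
#' trait, which the models must correct through the genomic relationship
#' matrix), runs single-population, MP1 and MP2 scans, and measures the
#' empirical type-1 error at alpha = 0.05 together with
#' Kolmogorov-Smirnov uniformity statistics of the p values. Setting
#' `var_additive = 0` gives the complete null instead, under which the
#' P3D strategy is conditionally conservative (see the methods
#' vignette).
#'
#' @param seed Integer seed.
#' @param n_families,lines_per_family,snps_per_chrom Study size knobs
#'   (defaults give 2 x 144 lines and about 2400 tested SNPs).
#' @param var_additive Polygenic variance of the simulated trait
#'   (reported scale; default 1).
#' @return List with `p_values` (per mode), `type1` (per-mode empirical
#'   rate at 0.05), `ks_p` (per-mode KS uniformity p value) and
#'   `n_tests`.
#' @export
experiment_null_calibration <- function(seed = 1, n_families = 12,
                                        lines_per_family = 12,
                                        snps_per_chrom = 430,
                                        var_additive = 1) {
  cfg <- sim_config(
    n_populations = 2, n_founders = 12, n_families = n_families,
    lines_per_family = lines_per_family, n_chromosomes = 7,
    snps_per_chrom = snps_per_chrom, fst = 0.15,
    n_environments = 2, n_reps = 2,
    var_additive = var_additive, var_line = 0.2, var_gxe = 0.4,
    var_spatial = 0, var_error = 1, seed = seed
  )
  sim <- simulate_breeding_data(cfg)
  terms <- c("additive", "line", "gxe")
  g1 <- gwas_single(sim$plots, sim$geno, "trait", "pop1", terms = terms)
  g2 <- gwas_single(sim$plots, sim$geno, "trait", "pop2", terms = terms)
  gm1 <- gwas_mp1(sim$plots, sim$geno, "trait", c("pop1", "pop2"), terms = terms)
  gm2 <- gwas_mp2(sim$plots, sim$geno, "trait", c("pop1", "pop2"), terms = terms)
  p_values <- list(
    single = c(g1$p, g2$p),
    mp1 = gm1$p,
    mp2 = gm2$p
  )
  p_values <- lapply(p_values, function(p) p[!is.na(p)])
  ks <- vapply(p_values, function(p) {
    suppressWarnings(stats::ks.test(p, "punif")$p.value)
  }, numeric(1))
  list(
    p_values = p_values,
    type1 = vapply(p_values, function(p) mean(p < 0.05), numeric(1)),
    ks_p = ks,
    n_tests = vapply(p_values, length, integer(1))
  )
}

#' Variance-component recovery at field-trial scale
#'
#' Simulates one population of 500 doubled-haploid lines phenotyped in 6
#' environments with 2 replicate plots (the variance components of a
#' six-row winter barley heading-date analysis: 3.80 / 0.21 / 1.20 /
#' 0.77 / 0.49 on the reported scale), fits the full plot model with the
#' spatial moving window by AI-REML, and measures per-component relative
#' errors on the reported scale.
#'
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param n_seeds Number of replicate simulations (default 3).
#' @return Tibble: `seed`, `component`, `truth`, `estimate`,
#'   `rel_error`.
#' @export
experiment_recovery <- function(seed = 1, n_seeds = 3) {
  out <- list()
  warm <- NULL
  for (r in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_populations = 1, n_founders = 20, n_families = 50,
      lines_per_family = 10, n_chromosomes = 7, snps_per_chrom = 300,
      n_environments = 6, n_reps = 2, trial_rows = 10, trial_cols = 25,
      var_additive = 3.80, var_line = 0.21, var_gxe = 1.20,
      var_spatial = 0.77, var_error = 0.49, seed = seed + r
    )
    sim <- simulate_breeding_data(cfg)
    grm <- compute_grm(sim$geno)
    fit <- fit_plot_lmm(sim$plots, "trait", grm,
      spatial_mode = "window15", init = warm
    )
    warm <- fit$fit$theta
    truth <- sim$truth$varcomp
    est <- fit$components
    out[[r]] <- tibble(
      seed = seed + r,
      component = est$component,
      truth = truth$reported[match(est$component, truth$component)],
      estimate = est$reported
    )
  }
  bind_rows(out) %>%
    mutate(rel_error = abs(.data$estimate - .data$truth) / .data$truth)
}

#' Cross-population genetic correlation recovery
#'
#' Two populations of 400 lines each share polygenic marker effects with
#' correlation 0.76 (no QTLs); the bivariate cross-population model is
#' fitted and the estimated genetic correlation returned.
#'
#' @param seed Integer seed.
#' @param true_cor True effect correlation (default 0.76).
#' @return One-row tibble from [genetic_correlation_populations()] plus
#'   `truth`.
#' @export
experiment_crosspop_correlation <- function(seed = 1, true_cor = 0.76) {
  cfg <- sim_config(
    n_populations = 2, n_founders = 16, n_families = 40,
    lines_per_family = 10, n_chromosomes = 5, snps_per_chrom = 200,
    fst = 0.15, n_environments = 2, n_reps = 1,
    var_additive = 2, var_line = 0.2, var_gxe = 0, var_spatial = 0,
    var_error = 0.8,
    polygenic_cor = matrix(c(1, true_cor, true_cor, 1), 2), seed = seed
  )
  sim <- simulate_breeding_data(cfg)
  grm <- compute_grm(sim$geno)
  r <- genetic_correlation_populations(
    sim$plots, "trait", grm, c("pop1", "pop2"),
    terms = c("additive", "line")
  )
  r$truth <- true_cor
  r
}

# shared-QTL two-population configuration for the method-contrast study
contrast_config <- function(seed, qtl = NULL, n_families = c(15, 15)) {
  sim_config(
    n_populations = 2, n_founders = 10, n_families = n_families,
    lines_per_family = 10, n_chromosomes = 3, snps_per_chrom = 250,
    fst = 0.15, n_environments = 2, n_reps = 2,
    var_additive = 1.2, var_line = 0.1, var_gxe = 0.3, var_spatial = 0,
    var_error = 0.7, qtl = qtl,
    polygenic_cor = matrix(c(1, 0.7, 0.7, 1), 2), seed = seed
  )
}

# simulate genotypes, then place the QTL on a SNP that segregates well in
# every population (a common shared variant), then draw phenotypes
sim_with_common_qtl <- function(cfg, effects, chrom = "2H", min_mac = 30) {
  set.seed(cfg$seed)
  g <- simulate_population_genotypes(cfg)
  v <- g$geno$variants
  cand <- v$chrom == chrom
  # worst-case (across populations) distance of the allele frequency
  # from 1/2; the QTL goes on the most balanced shared common SNP
  imbalance <- rep(0, nrow(v))
  for (pop in cfg$pop_names) {
    mac <- minor_allele_count(g$geno, lines = lines_of(g$geno, pop))
    cand <- cand & mac >= min_mac
    d <- g$geno$dosage[match(lines_of(g$geno, pop), g$geno$samples$line), ,
                       drop = FALSE]
    imbalance <- pmax(imbalance, abs(colMeans(d, na.rm = TRUE) / 2 - 0.5))
  }
  if (!any(cand)) abort("no shared common SNP available for the QTL")
  pick <- which(cand)[which.min(imbalance[cand])]
  qtl <- tibble(chrom = v$chrom[pick], pos = v$pos[pick])
  for (i in seq_along(cfg$pop_names)) qtl[[cfg$pop_names[i]]] <- effects[i]
  cfg$qtl <- qtl
  ph <- simulate_phenotypes(g$geno, cfg)
  list(geno = g$geno, plots = ph$plots, truth = ph$truth)
}

#' Shared-QTL detection contrast between MP2 and single-population GWAS
#'
#' Two populations of 150 lines carry one shared QTL whose effect is
#' placed between the single-population and combined detection
#' thresholds: the expected single-population Wald z at the QTL sits
#' below the Bonferroni cut while the expected MP2 combined z sits above
#' it. Each replicate runs both single-population scans and MP2 and
#' records whether the QTL (lead SNP within 2 Mbp) is significant in
#' each analysis.
#'
#' @param seed Base seed.
#' @param n_seeds Replicates (default 10).
#' @param effect Shared additive QTL effect in trait units (default
#'   0.55; see the methods vignette for the sizing argument).
#' @return Tibble: one row per replicate with `hit_pop1`, `hit_pop2`,
#'   `hit_mp2`, `mp2_only`, and the per-analysis lead p values.
#' @export
experiment_method_contrast <- function(seed = 1, n_seeds = 10, effect = 0.55) {
  qtl_hit <- function(g, chrom, pos, window = 2e6) {
    near <- g$chrom == chrom & abs(g$pos - pos) <= window & !is.na(g$p)
    if (!any(near)) return(list(hit = FALSE, p = NA_real_))
    list(
      hit = any(g$significant[near]),
      p = min(g$p[near])
    )
  }
  out <- list()
  warm1 <- warm2 <- warm_m <- NULL
  for (r in seq_len(n_seeds)) {
    cfg <- contrast_config(seed + r)
    sim <- sim_with_common_qtl(cfg, effects = c(effect, effect))
    terms <- c("additive", "line", "gxe")
    g1 <- gwas_single(sim$plots, sim$geno, "trait", "pop1", terms = terms,
                      init = warm1)
    g2 <- gwas_single(sim$plots, sim$geno, "trait", "pop2", terms = terms,
                      init = warm2)
    gmp2 <- gwas_mp2(sim$plots, sim$geno, "trait", c("pop1", "pop2"),
                     terms = terms, init = warm_m)
    warm1 <- attr(g1, "null_fit")$fit$theta
    warm2 <- attr(g2, "null_fit")$fit$theta
    warm_m <- attr(gmp2, "null_fit")$fit$theta
    qpos <- sim$truth$qtl$pos[1]
    h1 <- qtl_hit(g1, "2H", qpos)
    h2 <- qtl_hit(g2, "2H", qpos)
    hm <- qtl_hit(gmp2, "2H", qpos)
    out[[r]] <- tibble(
      seed = seed + r,
      hit_pop1 = h1$hit, hit_pop2 = h2$hit, hit_mp2 = hm$hit,
      mp2_only = hm$hit && !h1$hit && !h2$hit,
      p_pop1 = h1$p, p_pop2 = h2$p, p_mp2 = hm$p
    )
  }
  bind_rows(out)
}

#' MP1 attenuation of a small-population-specific QTL
#'
#' One QTL acts only in the smaller of two populations (100 vs 400
#' lines). The MP1 model fits a single shared effect dominated by the
#' larger population, so its estimate is attenuated towards zero
#' relative to the small population's own single-population estimate.
#'
#' @param seed Base seed.
#' @param n_seeds Replicates (default 10).
#' @param effect QTL effect in the small population (default 0.6).
#' @return Tibble: `seed`, `beta_small` (single-population estimate in
#'   the small population), `beta_mp1`, `ratio`.
#' @export
experiment_mp1_attenuation <- function(seed = 1, n_seeds = 10, effect = 0.6) {
  out <- list()
  warm_s <- warm_j <- NULL
  for (r in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_populations = 2, pop_names = c("small", "big"),
      n_founders = 10, n_families = c(10, 40), lines_per_family = 10,
      n_chromosomes = 3, snps_per_chrom = 250, fst = 0.15,
      n_environments = 2, n_reps = 2,
      var_additive = 1.2, var_line = 0.1, var_gxe = 0.3, var_spatial = 0,
      var_error = 0.7,
      polygenic_cor = matrix(c(1, 0.7, 0.7, 1), 2), seed = seed + r
    )
    sim <- sim_with_common_qtl(cfg, effects = c(effect, 0))
    qid <- sim$truth$qtl$id[1]
    terms <- c("additive", "line", "gxe")
    gs <- gwas_single(sim$plots, sim$geno, "trait", "small",
                      snps = qid, terms = terms, init = warm_s)
    gm <- gwas_mp1(sim$plots, sim$geno, "trait", c("small", "big"),
                   snps = qid, terms = terms, init = warm_j)
    warm_s <- attr(gs, "null_fit")$fit$theta
    warm_j <- attr(gm, "null_fit")$fit$theta
    out[[r]] <- tibble(
      seed = seed + r,
      beta_small = gs$beta[1],
      beta_mp1 = gm$beta[1],
      ratio = gm$beta[1] / gs$beta[1]
    )
  }
  bind_rows(out)
}

#' Theoretical versus empirical detection power
#'
#' Replicated in independent blocks: each block simulates a fresh
#' population of 200 lines, fits the null plot model (whose components
#' then stay fixed for the block, the same P3D convention as the scans)
#' and locates a mid-frequency probe SNP. The hypothetical effect is
#' chosen once, where the first block's theoretical curve predicts
#' `target_power`; every block then contributes its theoretical power at
#' that effect and `reps_per_block` phenotype redraws (drawn from the
#' generator's stochastic model on the block's design, with the probe
#' effect added) scored at the first block's Bonferroni threshold.
#' Blocking over independent data sets averages out the per-fit error in
#' the null components that a single-fit design would inherit.
#'
#' @param seed Integer seed.
#' @param n_blocks Independent simulated data sets (default 10).
#' @param reps_per_block Phenotype replicates per block (default 40).
#' @param target_power Theoretical power at which the probe effect is
#'   placed (default 0.6).
#' @return List: `b` (probe effect), `alpha`, `theoretical` (mean over
#'   blocks), `empirical`, `n_reps`.
#' @export
experiment_power_agreement <- function(seed = 1, n_blocks = 10,
                                       reps_per_block = 40,
                                       target_power = 0.6) {
  terms <- c("additive", "line", "gxe")
  b <- NULL
  alpha <- NULL
  crit <- NULL
  theo <- numeric(n_blocks)
  hits <- logical(0)
  warm <- NULL
  for (blk in seq_len(n_blocks)) {
    cfg <- sim_config(
      n_populations = 1, n_founders = 12, n_families = 20,
      lines_per_family = 10, n_chromosomes = 3, snps_per_chrom = 250,
      n_environments = 2, n_reps = 2,
      var_additive = 1.2, var_line = 0.1, var_gxe = 0.3, var_spatial = 0,
      var_error = 0.7, seed = seed + blk
    )
    sim <- simulate_breeding_data(cfg)
    g0 <- gwas_single(sim$plots, sim$geno, "trait", "pop1", terms = terms,
                      init = warm)
    null_fit <- attr(g0, "null_fit")
    warm <- null_fit$fit$theta
    ok <- !is.na(g0$se)
    probe <- g0$id[ok][which.min(abs(g0$mac[ok] - quantile(g0$mac[ok], 0.75)))]
    se <- g0$se[g0$id == probe]
    if (blk == 1) {
      alpha <- attr(g0, "bonferroni")
      crit <- qchisq(1 - alpha, 1)
      # effect with the requested first-block theoretical power
      # (folded-normal inversion of the non-central chi-square tail)
      b <- (sqrt(crit) + qnorm(target_power)) * se
    }
    theo[blk] <- pchisq(crit, 1, ncp = (b / se)^2, lower.tail = FALSE)
    # replicate phenotypes from the generator's stochastic model on the
    # block design; fixed effects are omitted because the projection P
    # annihilates them exactly
    x <- snp_covariates(sim$geno, probe, null_fit$lines, null_fit$plots$line)
    Px <- null_project(null_fit$fit, x)
    xpx <- sum(x * Px)
    lines <- null_fit$lines
    d <- sim$geno$dosage[lines, , drop = FALSE]
    pfreq <- colMeans(d) / 2
    Zc <- sweep(d, 2, 2 * pfreq)
    G <- null_fit$G_aligned
    poly_scale <- sqrt((cfg$var_additive[1] / mean(diag(G))) /
      (2 * sum(pfreq * (1 - pfreq) * (pfreq > 0 & pfreq < 1))))
    li <- match(null_fit$plots$line, lines)
    cell <- paste(null_fit$plots$line, null_fit$plots$year,
                  null_fit$plots$location)
    cells <- unique(cell)
    ci <- match(cell, cells)
    n <- nrow(null_fit$plots)
    for (r in seq_len(reps_per_block)) {
      poly <- drop(Zc %*% (rnorm(ncol(Zc)) * poly_scale))
      gl <- rnorm(length(lines), 0, sqrt(cfg$var_line[1]))
      w <- rnorm(length(cells), 0, sqrt(cfg$var_gxe[1]))
      y <- poly[li] + gl[li] + w[ci] +
        rnorm(n, 0, sqrt(cfg$var_error[1])) + b * drop(x)
      z <- (sum(Px * y) / xpx) * sqrt(xpx)
      hits <- c(hits, 2 * pnorm(-abs(z)) <= alpha)
    }
  }
  list(
    b = unname(b), alpha = alpha,
    theoretical = mean(theo), empirical = mean(hits),
    n_reps = n_blocks * reps_per_block
  )
}
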
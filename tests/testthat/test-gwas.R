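# Association scans: GLS oracle, combination of scaled regressions,
# Bonferroni, PVE, QTL grouping, the MP1/MP2 reduction and duplication
# properties, and allele-orientation symmetry.

test_that("the combined scaled statistic matches direct evaluation", {
  # equal z, independent errors: combined z = sqrt(2) * z0
  cs <- combine_scaled(c(0.4, 0.2), c(0.2, 0.1), diag(c(0.2, 0.1)^2))
  expect_equal(cs$z, sqrt(2) * 2, tolerance = 1e-12)
  # perfect redundancy: combined z = z0
  V <- matrix(c(0.04, 0.02, 0.02, 0.01), 2)
  cs2 <- combine_scaled(c(0.4, 0.2), c(0.2, 0.1), V)
  expect_equal(cs2$z, 2, tolerance = 1e-12)
  # z = (3, 1), scaled covariance 0.2: combined z = 4 / sqrt(2.4)
  V3 <- matrix(c(1, 0.2, 0.2, 1), 2)
  cs3 <- combine_scaled(c(3, 1), c(1, 1), V3)
  expect_equal(cs3$z, 4 / sqrt(2.4), tolerance = 1e-12)
  expect_equal(cs3$z, 2.582, tolerance = 1e-3)
  # invalid covariance input
  Vbad <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(combine_scaled(c(1, 1), c(1, 1), Vbad), "exceeds 1")
  expect_error(combine_scaled(c(1, 1), c(0, 1), diag(2)), "> 0")
})

test_that("Bonferroni thresholds match the published panel and the trivial case", {
  bf <- bonferroni_threshold(12644)
  expect_equal(signif(bf$threshold, 3), 3.95e-06)
  expect_equal(round(bf$neg_log10, 1), 5.4)
  expect_equal(bonferroni_threshold(1)$threshold, 0.05)
})

test_that("PVE follows 2p(1-p)b^2 over the raw additive variance", {
  expect_equal(pve(0.3, 0, 2)$pve, 0)
  expect_equal(pve(0.5, sqrt(3.6), 3.6)$pve, 0.5)
  expect_equal(pve(0.1, 1, 3.6)$pve, 0.05)
  expect_error(pve(0.1, 1, 0), "> 0")
})

test_that("significant SNPs group into candidate QTLs by gap rule", {
  assoc <- tibble::tibble(
    id = paste0("s", 1:5),
    chrom = c("1H", "1H", "1H", "1H", "2H"),
    pos = c(1.0e6, 1.2e6, 1.3e6, 139e6, 25e6),
    p = c(1e-8, 1e-7, 5e-9, 1e-8, 1e-9)
  )
  q <- group_qtls(assoc, threshold = 1e-6, max_gap = 5e6)
  expect_equal(nrow(q), 3)
  q1 <- q[q$chrom == "1H" & q$start == 1.0e6, ]
  expect_equal(q1$end, 1.3e6)
  expect_equal(q1$n_snps, 3L)
  expect_equal(q1$lead_id, "s3")
  # the isolated hit becomes a point interval
  q2 <- q[q$chrom == "1H" & q$start == 139e6, ]
  expect_equal(q2$start, q2$end)
  expect_equal(q2$n_snps, 1L)
})

test_that("single-SNP GLS estimates match brute-force projection on a small instance", {
  sim <- flat_sim()
  plots <- sim$plots[1:30, ]
  lines <- sort(unique(plots$line))
  grm <- compute_grm(sim$geno, lines = lines)
  snps <- retained_snps(sim$geno, "single30", "pop1")[1:20]
  fit <- fit_plot_lmm(plots, "trait", grm, spatial_mode = "none",
                      terms = c("additive"))
  g <- gwas_single(plots, sim$geno, "trait", "pop1", grm = grm,
                   null_fit = fit, snps = snps)
  # brute force from the fitted covariance: V = th_a ZGZ' + th_e I
  th <- fit$fit$theta
  X <- fit$design$X
  Z <- as.matrix(fit$design$Z_line)
  G <- as.matrix(grm)[fit$lines, fit$lines]
  V <- th["additive"] * Z %*% G %*% t(Z) + th["error"] * diag(nrow(plots))
  Vi <- solve(V)
  y <- fit$plots$trait
  for (j in c(1, 7, 15)) {
    x <- mpgwas:::snp_covariates(sim$geno, snps[j], fit$lines, fit$plots$line)
    Xa <- cbind(X, drop(x))
    co <- solve(t(Xa) %*% Vi %*% Xa)
    bhat <- drop(co %*% t(Xa) %*% Vi %*% y)
    k <- ncol(Xa)
    expect_equal(g$beta[j], unname(bhat[k]), tolerance = 1e-8)
    expect_equal(g$se[j], sqrt(co[k, k]), tolerance = 1e-8)
  }
})

test_that("exact per-SNP refit agrees with P3D when components are stable", {
  sim <- flat_sim()
  grm <- compute_grm(sim$geno)
  snps <- retained_snps(sim$geno, "single30", "pop1")[1:5]
  g_p3d <- gwas_single(sim$plots, sim$geno, "trait", "pop1", grm = grm,
                       snps = snps, terms = c("additive", "gxe"))
  g_refit <- gwas_single(sim$plots, sim$geno, "trait", "pop1", grm = grm,
                         snps = snps, terms = c("additive", "gxe"),
                         refit = TRUE)
  expect_equal(g_refit$beta, g_p3d$beta, tolerance = 0.05)
  expect_equal(g_refit$se, g_p3d$se, tolerance = 0.05)
})

test_that("MP1 on duplicated data equals single-population estimates with SE scaled by 1/sqrt(2)", {
  sim <- flat_sim()
  gm <- sim$geno
  lines <- gm$samples$line
  d <- rbind(gm$dosage, gm$dosage)
  rownames(d) <- c(lines, paste0("c_", lines))
  gm2 <- geno_matrix(
    d, gm$variants,
    tibble::tibble(line = rownames(d),
                   population = rep(c("a", "b"), each = length(lines)))
  )
  plots <- dplyr::bind_rows(
    dplyr::mutate(sim$plots, population = "a"),
    dplyr::mutate(sim$plots, population = "b", line = paste0("c_", line),
                  trial = paste0("c_", trial))
  )
  snps <- retained_snps(gm2, "multi30_10", c("a", "b"))[1:40]
  # treat the copies as unrelated: block-diagonal joint GRM
  G1 <- as.matrix(compute_grm(gm, lines = lines))
  Gj <- rbind(cbind(G1, 0 * G1), cbind(0 * G1, G1))
  dimnames(Gj) <- list(rownames(d), rownames(d))
  g_single <- gwas_single(sim$plots, gm, "trait", "pop1", snps = snps,
                          terms = c("additive", "gxe"))
  g_mp1 <- gwas_mp1(plots, gm2, "trait", c("a", "b"), grm = Gj, snps = snps,
                    terms = c("additive", "gxe"))
  expect_equal(g_mp1$beta, g_single$beta, tolerance = 0.02)
  ratio <- g_mp1$se / g_single$se
  expect_equal(median(ratio), 1 / sqrt(2), tolerance = 0.05)
})

test_that("MP2 with one population reduces to the single-population scan", {
  sim <- flat_sim()
  grm <- compute_grm(sim$geno)
  snps <- retained_snps(sim$geno, "single30", "pop1")[1:25]
  g1 <- gwas_single(sim$plots, sim$geno, "trait", "pop1", grm = grm,
                    snps = snps, terms = c("additive", "gxe"))
  g2 <- gwas_mp2(sim$plots, sim$geno, "trait", "pop1", grm = grm,
                 snps = snps, terms = c("additive", "gxe"))
  expect_equal(g2$beta, g1$beta, tolerance = 1e-10)
  expect_equal(g2$p, g1$p, tolerance = 1e-10)
})

test_that("MP2 per-population effects match single-population runs at fixed null components", {
  sim <- small_sim()
  gm <- sim$geno
  snps <- retained_snps(gm, "multi30_10", c("pop1", "pop2"))[1:30]
  plots <- sim$plots
  lines <- sort(unique(plots$line))
  grm_joint <- compute_grm(gm, lines = lines)
  # fixed variance components, zero cross-population covariance
  init_multi <- c(
    additive.pop1 = 0.8, line.pop1 = 0.1, gxe.pop1 = 0.3, error.pop1 = 0.5,
    additive.pop2 = 0.8, line.pop2 = 0.1, gxe.pop2 = 0.3, error.pop2 = 0.5,
    cov_additive.pop1.pop2 = 0
  )
  null_multi <- fit_multipop_lmm(plots, "trait", grm_joint, c("pop1", "pop2"),
                                 init = init_multi[c(1:4, 5:8, 9)],
                                 max_iter = 0)
  # reorder init to the engine order (per-group blocks then covariances)
  g_mp2 <- gwas_mp2(plots, gm, "trait", c("pop1", "pop2"), grm = grm_joint,
                    null_fit = null_multi, snps = snps)
  for (p in c("pop1", "pop2")) {
    plots_p <- dplyr::filter(plots, population == p)
    lines_p <- sort(unique(plots_p$line))
    Gp <- as.matrix(grm_joint)[lines_p, lines_p]
    attr(Gp, "mean_diag") <- mean(diag(Gp))
    init_p <- c(additive = 0.8, line = 0.1, gxe = 0.3, error = 0.5)
    null_p <- fit_plot_lmm(plots_p, "trait", Gp, spatial_mode = "none",
                           init = init_p, max_iter = 0)
    g_p <- gwas_single(plots_p, gm, "trait", p, grm = Gp, null_fit = null_p,
                       snps = snps)
    expect_equal(g_mp2[[paste0("beta_", p)]], g_p$beta, tolerance = 1e-6)
    expect_equal(g_mp2[[paste0("se_", p)]], g_p$se, tolerance = 1e-6)
  }
})

test_that("flipping the effect allele flips the sign of the estimate but not the p value", {
  sim <- flat_sim()
  gm <- sim$geno
  snps <- retained_snps(gm, "single30", "pop1")[1:10]
  g1 <- gwas_single(sim$plots, gm, "trait", "pop1", snps = snps,
                    terms = c("additive", "gxe"))
  flip <- snps[4]
  d <- gm$dosage
  d[, flip] <- 2 - d[, flip]
  gm2 <- geno_matrix(d, gm$variants, gm$samples)
  g2 <- gwas_single(sim$plots, gm2, "trait", "pop1", snps = snps,
                    terms = c("additive", "gxe"))
  expect_equal(g2$beta[4], -g1$beta[4], tolerance = 1e-6)
  expect_equal(g2$p[4], g1$p[4], tolerance = 1e-8)
  expect_equal(g2$p[-4], g1$p[-4], tolerance = 1e-6)
})

test_that("the V matrix of every MP2 SNP has unit diagonal and bounded off-diagonals", {
  sim <- small_sim()
  g <- gwas_mp2(sim$plots, sim$geno, "trait", c("pop1", "pop2"),
                terms = c("additive", "gxe"))
  ok <- !is.na(g$beta_pop1)
  scaled_cov <- g$cov_pop1_pop2[ok] / (g$se_pop1[ok] * g$se_pop2[ok])
  expect_true(all(abs(scaled_cov) <= 1 + 1e-8))
  # reconstructed combined z agrees with the stored z
  z_re <- (g$beta_pop1[ok] / g$se_pop1[ok] + g$beta_pop2[ok] / g$se_pop2[ok]) /
    sqrt(2 + 2 * scaled_cov)
  expect_equal(z_re, g$z[ok], tolerance = 1e-8)
  expect_true(all(g$p[ok] > 0 & g$p[ok] <= 1))
})

test_that("a shared QTL between detection thresholds can be caught only by the combined test", {
  # fixed-seed instance of the combined-analysis advantage: the QTL
  # reaches genome-wide significance in MP2 while both 150-line
  # single-population scans miss it
  mc <- experiment_method_contrast(seed = 2, n_seeds = 1, effect = 0.55)
  expect_true(mc$mp2_only)
  expect_lt(mc$p_mp2, mc$p_pop1)
  expect_lt(mc$p_mp2, mc$p_pop2)
})
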
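# Founder divergence, meiosis and inbreeding, phenotype composition,
# ground-truth bookkeeping and fixture round trips.

test_that("zero divergence leaves per-population frequencies at the ancestral values", {
  set.seed(1)
  f <- simulate_founder_haplotypes(sim_config(
    n_populations = 2, fst = 0, n_chromosomes = 1, snps_per_chrom = 200
  ))
  expect_identical(f$populations$pop1$freq, f$ancestral_freq)
  expect_identical(f$populations$pop2$freq, f$ancestral_freq)
})

test_that("stronger divergence lowers the between-population frequency correlation", {
  cors <- function(fst, seed) {
    set.seed(seed)
    f <- simulate_founder_haplotypes(sim_config(
      n_populations = 2, fst = fst, n_chromosomes = 1, snps_per_chrom = 2000
    ))
    cor(f$populations$pop1$freq, f$populations$pop2$freq)
  }
  lo <- vapply(1:20, function(s) cors(0.05, s), numeric(1))
  hi <- vapply(1:20, function(s) cors(0.30, s), numeric(1))
  expect_lt(mean(hi), mean(lo))
})

test_that("centered GRM of one simulated population has near-zero mean off-diagonal", {
  sim <- memo("grm_offdiag_sim", simulate_breeding_data(sim_config(
    n_populations = 1, n_founders = 12, n_families = 20, lines_per_family = 10,
    n_chromosomes = 3, snps_per_chrom = 200, seed = 99
  )))
  G <- as.matrix(compute_grm(sim$geno))
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("DH lines are fully homozygous and SSD_F4 lines keep (1/2)^4 heterozygosity", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chrom = 5000,
                    chrom_length_bp = 1.5e8)
  blocks <- cfg
  m <- cfg$snps_per_chrom
  # fully informative cross: parent1 hom ref, parent2 hom alt everywhere
  p1 <- list(rep(0, m), rep(0, m))
  p2 <- list(rep(1, m), rep(1, m))
  set.seed(4)
  dh <- simulate_cross_and_inbreed(p1, p2, "DH", cfg, n_offspring = 10)
  het_dh <- vapply(dh, function(o) mean(o[[1]] != o[[2]]), numeric(1))
  expect_identical(unname(het_dh), rep(0, 10))
  ssd <- simulate_cross_and_inbreed(p1, p2, "SSD_F4", cfg, n_offspring = 200)
  het <- mean(vapply(ssd, function(o) mean(o[[1]] != o[[2]]), numeric(1)))
  expect_lt(abs(het - 1 / 16), 0.01)
})

test_that("identical homozygous parents produce identical offspring", {
  m <- 300
  cfg <- sim_config(n_chromosomes = 1, snps_per_chrom = m)
  hap <- rbinom(m, 1, 0.4)
  parent <- list(hap, hap)
  set.seed(5)
  offs <- simulate_cross_and_inbreed(parent, parent, "DH", cfg, n_offspring = 5)
  for (o in offs) {
    expect_equal(o[[1]], hap, ignore_attr = TRUE)
    expect_equal(o[[2]], hap, ignore_attr = TRUE)
  }
})

test_that("a noise-free configuration returns population mean plus environment effect exactly", {
  cfg <- sim_config(
    n_populations = 1, n_founders = 6, n_families = 4, lines_per_family = 5,
    n_chromosomes = 1, snps_per_chrom = 50, var_additive = 0, var_line = 0,
    var_gxe = 0, var_spatial = 0, var_error = 0, pop_mean = 10, seed = 12
  )
  sim <- simulate_breeding_data(cfg)
  env <- sim$truth$env_effects
  expected <- 10 + env$effect[match(
    paste(sim$plots$year, sim$plots$location),
    paste(env$year, env$location)
  )]
  expect_equal(sim$plots$trait, expected, tolerance = 1e-12)
})

test_that("the spatial window sums 15 effects with variance 15x the raw component", {
  sim <- small_sim()
  plots1 <- dplyr::filter(sim$plots, population == "pop1",
                          year == "Y1", location == "L1")
  plots1 <- dplyr::filter(plots1, trial == plots1$trial[1])
  members <- mpgwas:::window_members(plots1)
  sizes <- lengths(members)
  interior <- plots1$x >= 3 & plots1$x <= max(plots1$x) - 2 &
    plots1$y >= 2 & plots1$y <= max(plots1$y) - 1
  expect_true(all(sizes[interior] == 15))
  expect_true(all(sizes <= 15))
  # corner of a full trial: 3 columns x 2 rows of the stencil remain
  corner <- which(plots1$x == 1 & plots1$y == 1)
  expect_equal(sizes[corner], 6L)
  # empirical variance of complete window sums across many draws
  Zs <- mpgwas:::spatial_incidence(plots1)
  v_raw <- 0.05
  set.seed(42)
  sums <- replicate(400, {
    s <- rnorm(nrow(plots1), 0, sqrt(v_raw))
    as.numeric(Zs %*% s)[interior][1:5]
  })
  expect_lt(abs(var(as.numeric(sums)) / (15 * v_raw) - 1), 0.15)
})

test_that("breeding values equal QTL value plus polygenic term exactly", {
  sim <- small_sim()
  tr <- sim$truth$breeding_values
  expect_equal(tr$breeding_value, tr$qtl_value + tr$polygenic, tolerance = 1e-12)
  # and the QTL value is reconstructible from dosages and the effect table
  q <- sim$truth$qtl
  d <- sim$geno$dosage[, q$id, drop = FALSE]
  for (pop in c("pop1", "pop2")) {
    lines_p <- lines_of(sim$geno, pop)
    expected <- as.numeric(d[lines_p, , drop = FALSE] %*% q[[pop]])
    got <- tr$qtl_value[match(lines_p, tr$line)]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("polygenic marker effects are correlated across populations as configured", {
  sim <- memo("crosspop_sim", simulate_breeding_data(sim_config(
    n_populations = 2, n_founders = 20, n_families = 20, lines_per_family = 10,
    n_chromosomes = 3, snps_per_chrom = 200, n_environments = 1, n_reps = 1,
    polygenic_cor = matrix(c(1, 0.76, 0.76, 1), 2), seed = 321
  )))
  eff <- sim$truth$marker_effects
  a1 <- eff$effect[eff$population == "pop1"]
  a2 <- eff$effect[eff$population == "pop2"]
  expect_lt(abs(cor(a1, a2) - 0.76), 0.06)
  # and each population's polygenic values have the configured variance
  tr <- sim$truth$breeding_values
  v1 <- var(tr$polygenic[tr$population == "pop1"])
  expect_lt(abs(v1 / 3.80 - 1), 0.45)
})

test_that("plot-level variance decomposition matches the configuration within sampling error", {
  sim <- memo("varcomp_anova_sim", simulate_breeding_data(sim_config(
    n_populations = 1, n_founders = 16, n_families = 30, lines_per_family = 10,
    n_chromosomes = 3, snps_per_chrom = 150, n_environments = 4, n_reps = 2,
    var_additive = 2, var_line = 0.4, var_gxe = 0.8, var_spatial = 0.75,
    var_error = 0.5, seed = 17
  )))
  plots <- sim$plots
  tr <- sim$truth$breeding_values
  env <- sim$truth$env_effects
  bv <- tr$breeding_value[match(plots$line, tr$line)]
  env_eff <- env$effect[match(paste(plots$year, plots$location),
                              paste(env$year, env$location))]
  # realized additive variance across lines tracks the configured value
  expect_lt(abs(var(tr$breeding_value) / 2 - 1), 0.45)
  # what remains after removing the known mean structure and breeding
  # values is line + GxE + spatial-window + error variance; window
  # truncation at trial edges makes the spatial share slightly smaller
  res <- plots$trait - bv - env_eff
  expected <- 0.4 + 0.8 + 0.75 + 0.5
  expect_lt(abs(var(res) - expected) / expected, 0.35)
})

test_that("fixtures round-trip exactly and deterministically", {
  sim <- small_sim()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_sim_fixture(sim, dir1)
  write_sim_fixture(sim, dir2)
  # byte-identical outputs on repeat runs
  for (f in c("genotypes.vcf", "plots.tsv", "truth.json", "samples.tsv")) {
    expect_identical(
      readLines(file.path(dir1, f)), readLines(file.path(dir2, f))
    )
  }
  back <- read_sim_fixture(dir1)
  expect_identical(back$geno$dosage, sim$geno$dosage)
  expect_equal(back$plots$trait, sim$plots$trait, tolerance = 1e-12)
  expect_equal(nrow(back$truth$qtl), nrow(sim$truth$qtl))
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(recomb_rate_cm_mbp = 0), "recomb")
  expect_error(sim_config(var_error = -1), "var_error")
  bad_cor <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sim_config(n_populations = 2, polygenic_cor = bad_cor), "polygenic_cor")
  nonpsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(sim_config(n_populations = 3, polygenic_cor = nonpsd),
               "positive semi-definite")
  expect_error(
    sim_config(qtl = data.frame(chrom = "1H", pos = 123, effect = 1)),
    "grid"
  )
  expect_error(
    simulate_cross_and_inbreed(list(0, 0), list(0, 0), "DH",
                               list(chroms = character(0)), 1),
    "empty"
  )
})
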
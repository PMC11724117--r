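# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# tiny hand-built genotype matrix: 4 lines, 2 populations, 5 SNPs
tiny_gm <- function() {
  dosage <- rbind(
    l1 = c(0, 0, 2, 0, 1),
    l2 = c(2, 0, 2, 2, NA),
    l3 = c(2, 0, 0, 2, 0),
    l4 = c(2, 0, 2, 2, 2)
  )
  variants <- tibble::tibble(
    id = paste0("s", 1:5),
    chrom = c("1H", "1H", "1H", "2H", "2H"),
    pos = c(1L, 11L, 31L, 5L, 10005L),
    ref = "A", alt = "B"
  )
  samples <- tibble::tibble(
    line = rownames(dosage),
    population = c("p1", "p1", "p2", "p2")
  )
  geno_matrix(dosage, variants, samples)
}

# small two-population simulated data set with a strong shared QTL
small_sim <- function() {
  memo("small_sim", {
    qtl <- data.frame(chrom = "1H", pos = 18750000, effect = 0.9)
    simulate_breeding_data(sim_config(
      n_populations = 2, n_founders = 8, n_families = 12,
      lines_per_family = 12, n_chromosomes = 3, snps_per_chrom = 100,
      n_environments = 2, n_reps = 2, var_additive = 1.5, var_line = 0.15,
      var_gxe = 0.4, var_spatial = 0.75, var_error = 0.5,
      qtl = qtl, polygenic_cor = matrix(c(1, 0.7, 0.7, 1), 2), seed = 202
    ))
  })
}

# single-population data with no spatial term, for quick model fits
flat_sim <- function() {
  memo("flat_sim", {
    simulate_breeding_data(sim_config(
      n_populations = 1, n_founders = 10, n_families = 15,
      lines_per_family = 10, n_chromosomes = 2, snps_per_chrom = 80,
      n_environments = 3, n_reps = 2, var_additive = 2, var_line = 0.3,
      var_gxe = 0.5, var_spatial = 0, var_error = 0.6, seed = 303
    ))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / abs(expected), tol)
}

# Markov-chain genotypes: dosage flips between adjacent SNPs with a
# probability giving r(d) = exp(-d / (2 * delta))
markov_geno <- function(n, pos, delta) {
  m <- length(pos)
  d <- matrix(0, n, m)
  d[, 1] <- sample(c(0, 2), n, replace = TRUE)
  for (j in 2:m) {
    r_step <- exp(-(pos[j] - pos[j - 1]) / (2 * delta))
    flip <- runif(n) < (1 - r_step) / 2
    d[, j] <- ifelse(flip, 2 - d[, j - 1], d[, j - 1])
  }
  d
}
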
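# Genotype container, VCF round trips, allele counting and MAC filters,
# VanRaden GRM, PCA outlier rule, SNP density statistics.

test_that("VCF round trip preserves dosages, metadata and missingness", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, dplyr::rename(gm$samples, sample = line))
  expect_identical(back$dosage, gm$dosage)
  expect_equal(back$variants$pos, gm$variants$pos)
  expect_equal(back$samples$population, gm$samples$population)
  expect_true(is.na(back$dosage["l2", "s5"]))
})

test_that("multiallelic records are rejected with their coordinates", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1H>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "1H\t100\ts1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1H\t250\ts2\tA\tC,G\t.\tPASS\t.\tGT\t0/0\t1/2"
  ), path)
  map <- data.frame(sample = c("a", "b"), population = "p1")
  expect_error(read_vcf(path, map), "1H:250")
})

test_that("GT fields code alt-allele dosage 0/1/2 and phased calls work", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1H>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "1H\t100\ts1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1"
  ), path)
  map <- data.frame(sample = c("a", "b", "c"), population = "p1")
  gm <- read_vcf(path, map)
  expect_equal(unname(gm$dosage[, "s1"]), c(0, 1, 2))
})

test_that("minor allele count is min(alt, ref) over non-missing calls", {
  gm <- tiny_gm()
  # s1 dosages 0,2,2,2: alt 6, ref 2 -> MAC 2
  expect_equal(unname(minor_allele_count(gm, "s1")), 2L)
  # s2 monomorphic -> 0
  expect_equal(unname(minor_allele_count(gm, "s2")), 0L)
  # s4 over lines l1,l2,l4 with l2 masked: handled via subset with missing s5
  # s5 dosages 1,NA,0,2: alt 3, ref 3 -> MAC 3; missing excluded
  expect_equal(unname(minor_allele_count(gm, "s5")), 3L)
  d <- gm$dosage
  d["l3", "s1"] <- NA
  gm2 <- geno_matrix(d, gm$variants, gm$samples)
  # s1 now 0,2,NA,2: alt 4, ref 2 -> MAC 2
  expect_equal(unname(minor_allele_count(gm2, "s1")), 2L)
})

make_mac_gm <- function(mac_p1, mac_p2, n1 = 40, n2 = 40) {
  # one SNP per requested (pop1, pop2) MAC pair; dosages are 2s for the
  # first mac/2 lines (mac even) within each population
  stopifnot(all(mac_p1 %% 2 == 0), all(mac_p2 %% 2 == 0))
  m <- length(mac_p1)
  d1 <- vapply(mac_p1, function(k) c(rep(2, k / 2), rep(0, n1 - k / 2)), numeric(n1))
  d2 <- vapply(mac_p2, function(k) c(rep(2, k / 2), rep(0, n2 - k / 2)), numeric(n2))
  dosage <- rbind(d1, d2)
  rownames(dosage) <- paste0("l", seq_len(n1 + n2))
  geno_matrix(
    dosage,
    tibble::tibble(
      id = paste0("s", seq_len(m)), chrom = "1H",
      pos = seq_len(m) * 1000L, ref = "A", alt = "B"
    ),
    tibble::tibble(
      line = rownames(dosage),
      population = rep(c("p1", "p2"), c(n1, n2))
    )
  )
}

test_that("multi-population MAC filter applies both the total and per-population rules", {
  gm <- make_mac_gm(mac_p1 = c(12, 16, 20, 40), mac_p2 = c(8, 14, 16, 40))
  f <- filter_snps(gm, "multi30_10", populations = c("p1", "p2"))
  # {12, 8}: per-pop rule fails (8 < 10)
  expect_false(f$retained[f$id == "s1"])
  # {16, 14}: total 30 passes, both >= 10 -> retained
  expect_true(f$retained[f$id == "s2"])
  # {20, 16}: retained
  expect_true(f$retained[f$id == "s3"])
  gm2 <- make_mac_gm(mac_p1 = 16, mac_p2 = 12)
  f2 <- filter_snps(gm2, "multi30_10", populations = c("p1", "p2"))
  # total 28 < 30 -> excluded even though both pops >= 10
  expect_false(f2$retained)
})

test_that("multi30_10 retention is a subset of the total-MAC >= 30 rule", {
  sim <- small_sim()
  f <- filter_snps(sim$geno, "multi30_10", populations = c("pop1", "pop2"))
  total_pass <- f$mac_total >= 30
  expect_true(all(!f$retained | total_pass))
})

test_that("single-population MAC filter keeps MAC >= 30 in that population", {
  gm <- make_mac_gm(mac_p1 = c(28, 30, 32), mac_p2 = c(0, 0, 0))
  f <- filter_snps(gm, "single30", populations = "p1")
  expect_equal(f$retained, c(FALSE, TRUE, TRUE))
  expect_error(filter_snps(gm, "single30"), "exactly one")
})

test_that("VanRaden GRM matches the hand-computed two-line example", {
  dosage <- rbind(a = 0, b = 2)
  gm <- geno_matrix(
    dosage,
    tibble::tibble(id = "s1", chrom = "1H", pos = 1L, ref = "A", alt = "B"),
    tibble::tibble(line = c("a", "b"), population = "p")
  )
  G <- compute_grm(gm)
  # p = 0.5, Z = (-1, +1), denominator 2 * 0.25 = 0.5
  expect_equal(unname(as.matrix(G)), rbind(c(2, -2), c(-2, 2)))
  expect_equal(mean_diag(G), 2)
})

test_that("duplicated lines give identical GRM rows and permutation equivariance holds", {
  sim <- flat_sim()
  lines <- sim$geno$samples$line[1:30]
  d <- sim$geno$dosage[lines, ]
  d <- rbind(d, dup = d[1, ])
  gm <- geno_matrix(
    d,
    sim$geno$variants,
    tibble::tibble(line = rownames(d), population = "p")
  )
  G <- compute_grm(gm)
  expect_equal(unname(G[1, ]), unname(G[nrow(G), ]))
  # permutation equivariance
  perm <- rev(lines)
  G1 <- compute_grm(sim$geno, lines = lines)
  G2 <- compute_grm(sim$geno, lines = perm)
  expect_equal(unname(as.matrix(G2)), unname(as.matrix(G1)[perm, perm][, ]),
               ignore_attr = TRUE)
})

test_that("fully inbred lines have GRM mean diagonal near 2", {
  sim <- memo("inbred_grm_sim", simulate_breeding_data(sim_config(
    n_populations = 1, n_founders = 12, n_families = 20, lines_per_family = 10,
    n_chromosomes = 7, snps_per_chrom = 300, inbreeding = "DH", seed = 77
  )))
  G <- compute_grm(sim$geno)
  expect_lt(abs(mean_diag(G) - 2), 0.05)
})

test_that("all-monomorphic input is rejected (zero GRM denominator)", {
  dosage <- matrix(2, 3, 2, dimnames = list(paste0("l", 1:3), NULL))
  gm <- geno_matrix(
    dosage,
    tibble::tibble(id = c("s1", "s2"), chrom = "1H", pos = c(1L, 2L),
                   ref = "A", alt = "B"),
    tibble::tibble(line = paste0("l", 1:3), population = "p")
  )
  expect_error(compute_grm(gm), "monomorphic")
})

test_that("PCA outlier rule flags exactly a relabeled line and is idempotent", {
  sim <- memo("pca_sim", simulate_breeding_data(sim_config(
    n_populations = 2, n_founders = 8, n_families = 8, lines_per_family = 8,
    n_chromosomes = 2, snps_per_chrom = 150, fst = 0.35, seed = 55
  )))
  gm <- sim$geno
  scan <- pca_outlier_scan(gm)
  expect_false(any(scan$outlier))
  # swap one label
  samples <- gm$samples
  swapped <- samples$line[1]
  samples$population[1] <- "pop2"
  gm2 <- geno_matrix(gm$dosage, gm$variants, samples)
  scan2 <- pca_outlier_scan(gm2)
  expect_identical(scan2$line[scan2$outlier], swapped)
  # removing the flagged line leaves a clean second pass
  gm3 <- subset_geno(gm2, lines = setdiff(samples$line, swapped))
  expect_false(any(pca_outlier_scan(gm3)$outlier))
})

test_that("single population yields no PCA outliers by definition", {
  sim <- flat_sim()
  expect_false(any(pca_outlier_scan(sim$geno)$outlier))
})

test_that("SNP density statistics match hand-computed values", {
  gm <- tiny_gm()
  # 1H gaps {10, 20}, 2H gap {10000} -> median of {10, 20, 10000} = 20
  st <- snp_density_stats(gm)
  expect_equal(st$median_neighbour_distance, 20)
  expect_equal(st$density$n_snps[st$density$chrom == "1H"], 3L)
  # uniform 10-kbp grid
  gm2 <- geno_matrix(
    matrix(c(0, 2), 2, 6, dimnames = list(c("a", "b"), NULL)),
    tibble::tibble(id = paste0("g", 1:6), chrom = "3H",
                   pos = seq(10000L, 60000L, 10000L), ref = "A", alt = "B"),
    tibble::tibble(line = c("a", "b"), population = "p")
  )
  expect_equal(snp_density_stats(gm2)$median_neighbour_distance, 10000)
  # one SNP per chromosome -> undefined
  gm3 <- geno_matrix(
    matrix(c(0, 2), 2, 2, dimnames = list(c("a", "b"), NULL)),
    tibble::tibble(id = c("x1", "x2"), chrom = c("1H", "2H"),
                   pos = c(5L, 9L), ref = "A", alt = "B"),
    tibble::tibble(line = c("a", "b"), population = "p")
  )
  expect_true(is.na(snp_density_stats(gm3)$median_neighbour_distance))
})

test_that("the merged-panel filter keeps MAC >= 20 over all lines", {
  gm <- make_mac_gm(mac_p1 = c(10, 10, 4), mac_p2 = c(8, 10, 6))
  f <- filter_snps(gm, "merge20")
  # total MACs 18, 20, 10
  expect_equal(f$retained, c(FALSE, TRUE, FALSE))
})
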
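# Pairwise LD, kinship-corrected r_v, decay curves, linkage phase
# similarity and the reverse-phase window scan.

ld_gm <- function(dosage, pos = NULL, chrom = "1H", pops = "p") {
  n <- nrow(dosage)
  m <- ncol(dosage)
  rownames(dosage) <- paste0("l", seq_len(n))
  geno_matrix(
    dosage,
    tibble::tibble(
      id = paste0("s", seq_len(m)), chrom = chrom,
      pos = pos %||% (seq_len(m) * 1000L), ref = "A", alt = "B"
    ),
    tibble::tibble(line = rownames(dosage), population = rep_len(pops, n))
  )
}

test_that("pairwise r matches hand-computed Pearson correlations", {
  d <- cbind(
    a = c(0, 0, 2, 2),
    b = c(0, 2, 0, 2),
    c2 = c(2, 2, 0, 0), # complement of a
    mono = c(2, 2, 2, 2)
  )
  gm <- ld_gm(d)
  expect_equal(ld_r(gm, "s1", "s1")$r, 1)
  expect_equal(ld_r(gm, "s1", "s3")$r, -1)
  expect_equal(ld_r(gm, "s1", "s2")$r, 0)
  expect_true(is.na(ld_r(gm, "s1", "s4")$r))
})

test_that("r_v with identity kinship reproduces plain r to ten digits", {
  set.seed(31)
  for (rep in 1:5) {
    d <- matrix(sample(c(0, 2), 50 * 4, replace = TRUE), 50, 4)
    gm <- ld_gm(d)
    K <- diag(50)
    dimnames(K) <- list(gm$samples$line, gm$samples$line)
    r <- ld_r(gm, "s1", "s2")$r
    rv <- ld_rv(gm, K, "s1", "s2", ridge = 0)$rv
    expect_equal(rv, r, tolerance = 1e-10)
  }
})

test_that("r_v of a SNP with itself is 1 and allele flips change its sign", {
  set.seed(32)
  d <- matrix(sample(c(0, 2), 40 * 2, replace = TRUE), 40, 2)
  gm <- ld_gm(d)
  K <- diag(40)
  dimnames(K) <- list(gm$samples$line, gm$samples$line)
  expect_equal(ld_rv(gm, K, "s1", "s1")$rv, 1, tolerance = 1e-10)
  flipped <- d
  flipped[, 2] <- 2 - flipped[, 2]
  gm2 <- ld_gm(flipped)
  expect_equal(ld_rv(gm2, K, "s1", "s2")$rv,
               -ld_rv(gm, K, "s1", "s2")$rv, tolerance = 1e-10)
})

test_that("kinship correction recovers the unique-line correlation under duplication", {
  set.seed(33)
  d <- matrix(sample(c(0, 2), 30 * 2, replace = TRUE), 30, 2)
  r_unique <- cor(d[, 1], d[, 2])
  d2 <- rbind(d, d) # every line twice: perfect kinship blocks
  gm <- ld_gm(d2)
  K <- kronecker(matrix(1, 2, 2), diag(30)) * 2
  dimnames(K) <- list(rownames(gm$dosage), rownames(gm$dosage))
  rv <- ld_rv(gm, K, "s1", "s2", ridge = 1e-6)$rv
  expect_equal(rv, r_unique, tolerance = 1e-4)
})

test_that("distance bins are left-closed right-open 10-kbp intervals", {
  set.seed(34)
  base <- sample(c(0, 2), 60, replace = TRUE)
  noisy <- function() ifelse(runif(60) < 0.2, sample(c(0, 2), 60, TRUE), base)
  d <- cbind(base, noisy(), noisy())
  gm <- ld_gm(d, pos = c(1L, 10000L, 20000L))
  curve <- ld_decay_curve(gm)
  # pair (1, 10000): distance 9999 -> bin 1; (10000, 20000): 10000 -> bin 2;
  # (1, 20000): 19999 -> bin 2
  expect_equal(curve$n_pairs[curve$bin == 1], 1L)
  expect_equal(curve$n_pairs[curve$bin == 2], 2L)
})

test_that("a flat curve at r2 = 1 never crosses the decay threshold", {
  d <- cbind(c(0, 0, 2, 2), c(0, 0, 2, 2), c(2, 2, 0, 0))
  gm <- ld_gm(d, pos = c(1L, 15000L, 42000L))
  curve <- ld_decay_curve(gm)
  expect_true(all(curve$mean_r2 == 1))
  expect_true(is.na(attr(curve, "decay_distance")))
})

test_that("the decay distance of a constructed exponential decay is recovered within one bin", {
  # Markov construction: dosages flip between adjacent SNPs with a
  # per-step probability chosen so r(d) = exp(-d / (2 * delta)), hence
  # r2(d) = exp(-d / delta) crosses 0.2 at delta * log(5)
  set.seed(35)
  n <- 600
  delta <- 3e4
  pos <- seq(0L, 120000L, by = 2000L) + 1L
  m <- length(pos)
  d <- matrix(0, n, m)
  d[, 1] <- sample(c(0, 2), n, replace = TRUE)
  for (j in 2:m) {
    gap <- pos[j] - pos[j - 1]
    r_step <- exp(-gap / (2 * delta))
    flip <- runif(n) < (1 - r_step) / 2
    d[, j] <- ifelse(flip, 2 - d[, j - 1], d[, j - 1])
  }
  gm <- ld_gm(d, pos = pos)
  curve <- ld_decay_curve(gm)
  expected <- delta * log(5)
  expect_lt(abs(attr(curve, "decay_distance") - expected), 1e4)
})

test_that("identical populations give LPS 1 in every bin and no negative windows", {
  set.seed(36)
  pos <- seq(5000L, 3000000L, by = 50000L)
  d0 <- markov_geno(200, pos, 2.5e5)
  d <- rbind(d0, d0) # population b is an exact relabeled copy
  rownames(d) <- paste0("l", seq_len(nrow(d)))
  gm2 <- geno_matrix(
    d,
    tibble::tibble(id = paste0("s", seq_along(pos)), chrom = "1H",
                   pos = pos, ref = "A", alt = "B"),
    tibble::tibble(line = rownames(d), population = rep(c("a", "b"), each = 200))
  )
  Ga <- compute_grm(gm2, lines = lines_of(gm2, "a"))
  Gb <- compute_grm(gm2, lines = lines_of(gm2, "b"))
  lps <- lps_curve(gm2, Ga, Gb, "a", "b")
  expect_true(all(abs(lps$lps - 1) < 1e-8, na.rm = TRUE))
  scan <- lps_window_scan(gm2, Ga, Gb, "a", "b")
  expect_gt(nrow(scan), 0)
  expect_false(any(scan$reverse_phase))
  expect_true(all(scan$n_pairs >= 2))
  # sparse maps leave no window with two pairs: result is empty, not NA
  gm_sparse <- ld_gm(d0[, 1:3], pos = c(1L, 2000000L, 4000000L), pops = "a")
  expect_equal(nrow(suppressWarnings(
    lps_window_scan(gm2, Ga, Gb, "a", "b", window = 1e4, step = 1e7)
  )), 0)
})

test_that("LPS of a three-pair bin matches the hand-computed cosine", {
  # population B flips the middle SNP: pairs (1,2) and (2,3) change sign,
  # pair (1,3) does not; with K = I, r_v = r so the cosine is computable
  # from plain Pearson correlations
  set.seed(37)
  base <- sample(c(0, 2), 80, replace = TRUE)
  jitter <- function(p) ifelse(runif(80) < p, 2 - base, base)
  da <- cbind(base, jitter(0.15), jitter(0.3))
  db <- da
  db[, 2] <- 2 - db[, 2]
  r <- c(
    cor(da[, 1], da[, 2]), cor(da[, 1], da[, 3]), cor(da[, 2], da[, 3])
  )
  rb <- c(-r[1], r[2], -r[3])
  expected <- sum(r * rb) / sqrt(sum(r^2) * sum(rb^2))
  d <- rbind(da, db)
  rownames(d) <- paste0("l", seq_len(nrow(d)))
  gm <- geno_matrix(
    d,
    tibble::tibble(id = paste0("s", 1:3), chrom = "1H",
                   pos = c(1000L, 3000L, 5000L), ref = "A", alt = "B"),
    tibble::tibble(line = rownames(d), population = rep(c("a", "b"), each = 80))
  )
  Ka <- diag(80); Kb <- diag(80)
  dimnames(Ka) <- list(rownames(d)[1:80], rownames(d)[1:80])
  dimnames(Kb) <- list(rownames(d)[81:160], rownames(d)[81:160])
  lps <- lps_curve(gm, Ka, Kb, "a", "b", ridge = 0)
  expect_equal(nrow(lps), 1L)
  expect_equal(lps$lps, expected, tolerance = 1e-8)
  # and LPS is symmetric in the population order
  lps_rev <- lps_curve(gm, Kb, Ka, "b", "a", ridge = 0)
  expect_equal(lps_rev$lps, lps$lps, tolerance = 1e-12)
})

test_that("an inverted-phase block is flagged by the window scan", {
  # Markov-chain genotypes with positive adjacent-SNP coupling in both
  # populations; population B flips alternate SNPs inside a 1-Mbp block,
  # reversing the sign of its adjacent-pair LD there
  set.seed(38)
  pos <- seq(100000L, 5000000L, by = 100000L)
  da <- markov_geno(500, pos, 2.5e5)
  db <- markov_geno(500, pos, 2.5e5)
  block <- which(pos >= 2e6 & pos < 3e6)
  flip <- block[seq_along(block) %% 2 == 1]
  db[, flip] <- 2 - db[, flip]
  d <- rbind(da, db)
  rownames(d) <- paste0("l", seq_len(nrow(d)))
  gm <- geno_matrix(
    d,
    tibble::tibble(id = paste0("s", seq_along(pos)), chrom = "1H",
                   pos = pos, ref = "A", alt = "B"),
    tibble::tibble(line = rownames(d), population = rep(c("a", "b"), each = 500))
  )
  Ka <- diag(500); Kb <- diag(500)
  dimnames(Ka) <- list(rownames(d)[1:500], rownames(d)[1:500])
  dimnames(Kb) <- list(rownames(d)[501:1000], rownames(d)[501:1000])
  scan <- lps_window_scan(gm, Ka, Kb, "a", "b")
  inside <- scan$start >= 2e6 & scan$end <= 3e6
  outside <- scan$end <= 2e6 | scan$start >= 3e6
  expect_true(all(scan$lps[inside] < 0))
  expect_true(all(scan$reverse_phase[inside]))
  expect_true(all(scan$lps[outside] > 0))
})
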
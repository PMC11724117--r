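# Haplotypes are 0/1 vectors over the full SNP grid (chromosomes
# concatenated); an individual is a list of two haplotypes. The genetic map
# is uniform, so crossover counts are Poisson in the chromosome's Morgan
# length and crossover positions are uniform in bp (no interference).

chrom_blocks <- function(config) {
  map <- snp_map(config)
  chroms <- unique(map$chrom)
  morgans <- config$chrom_length_bp / 1e6 * config$recomb_rate_cm_mbp / 100
  list(
    map = map,
    chroms = chroms,
    idx = lapply(chroms, function(ch) which(map$chrom == ch)),
    pos = lapply(chroms, function(ch) map$pos[map$chrom == ch]),
    morgans = rep(morgans, length(chroms))
  )
}

# one meiotic gamete from an individual
gamete <- function(ind, blocks) {
  out <- numeric(length(ind[[1]]))
  for (c_i in seq_along(blocks$chroms)) {
    idx <- blocks$idx[[c_i]]
    pos <- blocks$pos[[c_i]]
    n_cx <- rpois(1, blocks$morgans[c_i])
    start <- sample.int(2, 1)
    if (n_cx == 0) {
      phase <- rep(start, length(pos))
    } else {
      cx <- sort(runif(n_cx, 0, max(pos)))
      phase <- (start - 1 + findInterval(pos, cx)) %% 2 + 1
    }
    out[idx] <- ifelse(phase == 1, ind[[1]][idx], ind[[2]][idx])
  }
  out
}

#' Simulate founder haplotypes for differentiated populations
#'
#' Ancestral allele frequencies are drawn once from Uniform(0.05, 0.5);
#' each population's frequencies are then drawn by a Balding-Nichols
#' divergence step with its `fst` parameter (`fst = 0` leaves the ancestral
#' frequencies untouched), and founder haplotypes are sampled site-wise
#' from the per-population frequencies.
#'
#' Draws come from the current RNG state; seed control belongs to the
#' caller (see [simulate_breeding_data()], which seeds once).
#'
#' @param config A [sim_config()].
#' @return A `sim_founders` list: `ancestral_freq`, and per population a
#'   list with `freq` and `haplotypes` (2 x n_founders rows by n_snps).
#' @export
simulate_founder_haplotypes <- function(config) {
  map <- snp_map(config)
  m <- nrow(map)
  anc <- runif(m, 0.05, 0.5)
  pops <- lapply(seq_len(config$n_populations), function(k) {
    fst <- config$fst[k]
    p <- if (fst == 0) anc else {
      rbeta(m, anc * (1 - fst) / fst, (1 - anc) * (1 - fst) / fst)
    }
    n_hap <- 2 * config$n_founders[k]
    hap <- matrix(rbinom(n_hap * m, 1, rep(p, each = n_hap)), nrow = n_hap)
    list(freq = p, haplotypes = hap)
  })
  names(pops) <- config$pop_names
  structure(
    list(ancestral_freq = anc, populations = pops, map = map),
    class = "sim_founders"
  )
}

#' Cross two founders and derive inbred offspring
#'
#' Simulates a biparental cross followed by inbreeding. In `"DH"` mode one
#' gamete of the F1 is doubled, giving a fully homozygous line. In
#' `"SSD_F4"` mode the F1 is selfed to F4 by single-seed descent and the
#' line is genotyped at the F5-equivalent generation (four selfing
#' meioses), leaving about `(1/2)^4` residual heterozygosity at loci
#' segregating in the F1.
#'
#' @param parent1,parent2 Individuals: lists of two 0/1 haplotype vectors
#'   over the same variant set.
#' @param mode `"DH"` or `"SSD_F4"`.
#' @param blocks Genetic map blocks from the configuration (internal
#'   structure created by [simulate_breeding_data()]); alternatively pass a
#'   [sim_config()] and the map is derived from it.
#' @param n_offspring Number of inbred lines to derive (>= 1).
#' @return List of individuals (each a list of two haplotypes).
#' @export
simulate_cross_and_inbreed <- function(parent1, parent2, mode, blocks, n_offspring) {
  if (inherits(blocks, "sim_config")) blocks <- chrom_blocks(blocks)
  if (length(blocks$chroms) == 0) abort("empty genetic map")
  if (n_offspring < 1) abort("`n_offspring` must be >= 1")
  if (length(parent1[[1]]) != length(parent2[[1]])) {
    abort("parents must share the variant set")
  }
  f1 <- list(gamete(parent1, blocks), gamete(parent2, blocks))
  lapply(seq_len(n_offspring), function(i) {
    if (mode == "DH") {
      g <- gamete(f1, blocks)
      list(g, g)
    } else {
      ind <- f1
      for (gen in 1:4) ind <- list(gamete(ind, blocks), gamete(ind, blocks))
      ind
    }
  })
}

#' Simulate genotypes for every population in a configuration
#'
#' Founders are paired into biparental crosses (parents drawn without
#' replacement per family from the population's founder set) and each
#' family contributes `lines_per_family` inbred lines.
#'
#' @param config A [sim_config()].
#' @param founders Optional precomputed [simulate_founder_haplotypes()]
#'   result (drawn fresh if omitted).
#' @return A list: `geno` (a [geno_matrix()]), `pedigree` (tibble: line,
#'   population, family, parents) and `founders`.
#' @export
simulate_population_genotypes <- function(config, founders = NULL) {
  founders <- founders %n% simulate_founder_haplotypes(config)
  blocks <- chrom_blocks(config)
  map <- founders$map
  all_dos <- list()
  ped <- list()
  for (k in seq_len(config$n_populations)) {
    pop <- config$pop_names[k]
    hap <- founders$populations[[pop]]$haplotypes
    n_f <- config$n_founders[k]
    founder_ind <- lapply(seq_len(n_f), function(i) {
      list(hap[2 * i - 1, ], hap[2 * i, ])
    })
    for (fam in seq_len(config$n_families[k])) {
      pr <- sample.int(n_f, 2, replace = FALSE)
      offs <- simulate_cross_and_inbreed(
        founder_ind[[pr[1]]], founder_ind[[pr[2]]],
        config$inbreeding[k], blocks, config$lines_per_family[k]
      )
      dos <- t(vapply(offs, function(o) o[[1]] + o[[2]], numeric(nrow(map))))
      ids <- sprintf("%s_f%02d_%02d", pop, fam, seq_along(offs))
      rownames(dos) <- ids
      all_dos[[length(all_dos) + 1]] <- dos
      ped[[length(ped) + 1]] <- tibble(
        line = ids, population = pop, family = sprintf("%s_f%02d", pop, fam),
        parent1 = pr[1], parent2 = pr[2]
      )
    }
  }
  dosage <- do.call(rbind, all_dos)
  ped <- bind_rows(ped)
  variants <- mutate(map, ref = "A", alt = "B")
  gm <- geno_matrix(
    dosage,
    variants[, c("id", "chrom", "pos", "ref", "alt")],
    tibble(line = ped$line, population = ped$population)
  )
  list(geno = gm, pedigree = ped, founders = founders)
}
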
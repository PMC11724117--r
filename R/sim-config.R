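#' Configuration for the multi-population breeding simulator
#'
#' Describes a set of genetically differentiated inbred breeding populations
#' (full-sib families from biparental crosses, inbred by doubled haploids or
#' single-seed descent), their genome and genetic map, shared and
#' population-specific QTLs, the cross-population correlation of polygenic
#' marker effects, and the plot-level variance structure (environment fixed
#' effects, genotype-by-environment interaction, spatial moving-window and
#' residual effects).
#'
#' Per-population arguments accept a scalar (recycled) or a vector of length
#' `n_populations`. Variance components are given on the reported scale used
#' in results tables: `var_additive` is the additive variance *after*
#' multiplication by the mean diagonal of the population's genomic
#' relationship matrix, and `var_spatial` is the window-sum spatial variance
#' (15 x the per-plot raw spatial variance when windows are complete). The
#' generator converts both to their raw counterparts internally.
#'
#' @param n_populations Number of populations.
#' @param pop_names Population labels.
#' @param n_founders,n_families,lines_per_family Breeding-programme sizes
#'   per population.
#' @param inbreeding `"DH"` (doubled haploid: fully homozygous) or
#'   `"SSD_F4"` (selfing to F4 by single-seed descent, genotyped at the
#'   F5-equivalent generation), per population.
#' @param n_chromosomes,snps_per_chrom,chrom_length_bp Genome layout; SNPs
#'   are placed on an even grid along each chromosome.
#' @param recomb_rate_cm_mbp Uniform genetic map density (cM per Mbp).
#' @param fst Balding-Nichols divergence of each population from the common
#'   ancestral pool, in `[0, 1)`.
#' @param qtl `NULL` or a data frame with columns `chrom`, `pos` and either
#'   a single `effect` column (shared across populations) or one column per
#'   population name, giving additive effects in trait units per alt allele.
#'   Every `pos` must coincide with a simulated SNP position (see
#'   [snp_map()]). QTL effects apply to the first trait.
#' @param polygenic_cor Correlation matrix (`n_populations` square) of
#'   per-SNP polygenic effects between populations; must be symmetric with
#'   unit diagonal and positive semi-definite.
#' @param var_additive,var_line,var_gxe,var_spatial,var_error Variance
#'   components per population, trait units squared (reported scale, see
#'   above).
#' @param n_environments Number of year x location combinations per
#'   population.
#' @param env_effect_sd SD of the environment fixed effects, drawn once per
#'   year x location (trait units; default 2).
#' @param n_reps Replicate plots per line and environment.
#' @param trial_rows,trial_cols Field layout of each trial (y rows by x
#'   columns).
#' @param pop_mean Population trait mean (fixed), per population.
#' @param n_traits Number of traits; polygenic effects between traits are
#'   correlated with `trait_cor` while non-genetic effects are independent.
#' @param trait_cor Genetic correlation matrix between traits.
#' @param seed Integer seed; all randomness in [simulate_breeding_data()]
#'   flows from a single generator seeded here.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_populations = 2,
                       pop_names = paste0("pop", seq_len(n_populations)),
                       n_founders = 16,
                       n_families = 25,
                       lines_per_family = 12,
                       inbreeding = "DH",
                       n_chromosomes = 7,
                       snps_per_chrom = 300,
                       chrom_length_bp = 1.5e8,
                       recomb_rate_cm_mbp = 1,
                       fst = 0.15,
                       qtl = NULL,
                       polygenic_cor = diag(n_populations),
                       var_additive = 3.80,
                       var_line = 0.21,
                       var_gxe = 1.20,
                       var_spatial = 0.77,
                       var_error = 0.49,
                       n_environments = 6,
                       env_effect_sd = 2,
                       n_reps = 2,
                       trial_rows = 10,
                       trial_cols = 25,
                       pop_mean = 14,
                       n_traits = 1,
                       trait_cor = diag(n_traits),
                       seed = 1) {
  np <- n_populations
  cfg <- list(
    n_populations = np,
    pop_names = pop_names,
    n_founders = recycle_pop(n_founders, np, "n_founders"),
    n_families = recycle_pop(n_families, np, "n_families"),
    lines_per_family = recycle_pop(lines_per_family, np, "lines_per_family"),
    inbreeding = recycle_pop(inbreeding, np, "inbreeding"),
    n_chromosomes = n_chromosomes,
    snps_per_chrom = snps_per_chrom,
    chrom_length_bp = chrom_length_bp,
    recomb_rate_cm_mbp = recomb_rate_cm_mbp,
    fst = recycle_pop(fst, np, "fst"),
    qtl = if (!is.null(qtl)) as_tibble(qtl) else NULL,
    polygenic_cor = polygenic_cor,
    var_additive = recycle_pop(var_additive, np, "var_additive"),
    var_line = recycle_pop(var_line, np, "var_line"),
    var_gxe = recycle_pop(var_gxe, np, "var_gxe"),
    var_spatial = recycle_pop(var_spatial, np, "var_spatial"),
    var_error = recycle_pop(var_error, np, "var_error"),
    n_environments = recycle_pop(n_environments, np, "n_environments"),
    env_effect_sd = env_effect_sd,
    n_reps = recycle_pop(n_reps, np, "n_reps"),
    trial_rows = trial_rows,
    trial_cols = trial_cols,
    pop_mean = recycle_pop(pop_mean, np, "pop_mean"),
    n_traits = n_traits,
    trait_names = if (n_traits == 1) "trait" else paste0("trait", seq_len(n_traits)),
    trait_cor = trait_cor,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  if (length(cfg$pop_names) != cfg$n_populations || anyDuplicated(cfg$pop_names)) {
    abort("`pop_names` must be unique and match `n_populations`")
  }
  if (!all(cfg$inbreeding %in% c("DH", "SSD_F4"))) {
    abort("`inbreeding` must be \"DH\" or \"SSD_F4\"")
  }
  if (any(cfg$fst < 0 | cfg$fst >= 1)) abort("`fst` must lie in [0, 1)")
  if (cfg$recomb_rate_cm_mbp <= 0) abort("`recomb_rate_cm_mbp` must be > 0")
  for (nm in c("var_additive", "var_line", "var_gxe", "var_spatial", "var_error")) {
    if (any(cfg[[nm]] < 0)) abort(paste0("`", nm, "` must be >= 0"))
  }
  check_cor_matrix(cfg$polygenic_cor, cfg$n_populations, "polygenic_cor")
  check_cor_matrix(cfg$trait_cor, cfg$n_traits, "trait_cor")
  if (!is.null(cfg$qtl)) {
    need <- c("chrom", "pos")
    if (!all(need %in% names(cfg$qtl))) abort("`qtl` needs columns chrom, pos")
    eff_cols <- setdiff(names(cfg$qtl), need)
    if (!(identical(eff_cols, "effect") || all(cfg$pop_names %in% eff_cols))) {
      abort("`qtl` needs an `effect` column or one effect column per population")
    }
    map <- snp_map(cfg)
    hit <- paste(cfg$qtl$chrom, cfg$qtl$pos) %in% paste(map$chrom, map$pos)
    if (!all(hit)) {
      abort(paste0(
        "QTL position(s) not on the simulated SNP grid: ",
        paste(paste0(cfg$qtl$chrom[!hit], ":", cfg$qtl$pos[!hit]), collapse = ", ")
      ))
    }
  }
  cfg
}

check_cor_matrix <- function(R, n, name) {
  if (!is.matrix(R) || any(dim(R) != n)) {
    abort(sprintf("`%s` must be a %d x %d matrix", name, n, n))
  }
  if (max(abs(R - t(R))) > 1e-8) abort(paste0("`", name, "` must be symmetric"))
  if (max(abs(diag(R) - 1)) > 1e-8) abort(paste0("`", name, "` must have unit diagonal"))
  if (any(abs(R) > 1 + 1e-8)) abort(paste0("`", name, "` entries must lie in [-1, 1]"))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort(paste0("`", name, "` must be positive semi-definite"))
  invisible(R)
}

#' SNP positions implied by a simulator configuration
#'
#' SNPs sit on an even grid along each chromosome; chromosomes are named
#' `1H`, `2H`, ... following the barley convention.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `id`, `chrom`, `pos`.
#' @export
snp_map <- function(config) {
  chroms <- paste0(seq_len(config$n_chromosomes), "H")
  step <- config$chrom_length_bp / config$snps_per_chrom
  pos <- round(step / 2 + step * (seq_len(config$snps_per_chrom) - 1))
  tibble(
    chrom = rep(chroms, each = config$snps_per_chrom),
    pos = rep(pos, config$n_chromosomes)
  ) %>%
    mutate(id = paste0(.data$chrom, "_", .data$pos)) %>%
    select("id", "chrom", "pos")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d population(s): %s\n", x$n_populations,
    paste(sprintf(
      "%s (%d fam x %d, %s)", x$pop_names, x$n_families,
      x$lines_per_family, x$inbreeding
    ), collapse = "; ")
  ))
  cat(sprintf(
    "genome: %d chromosomes x %d SNPs, %.0f Mbp, %.2f cM/Mbp; %d trait(s); seed %d\n",
    x$n_chromosomes, x$snps_per_chrom, x$chrom_length_bp / 1e6,
    x$recomb_rate_cm_mbp, x$n_traits, x$seed
  ))
  invisible(x)
}
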
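# Field layout: plots of one environment are shuffled over trials of
# trial_rows x trial_cols cells, filled row-major. Spatial effects live on
# occupied plot positions; a plot's moving window covers the occupied cells
# of the 5-column x 3-row stencil centered on it (|dx| <= 2, |dy| <= 1)
# within its own trial, i.e. up to 15 effects, fewer at trial edges.

layout_plots <- function(lines, pop, envs, n_reps, trial_rows, trial_cols) {
  capacity <- trial_rows * trial_cols
  out <- list()
  for (e in seq_len(nrow(envs))) {
    plot_lines <- sample(rep(lines, n_reps))
    n <- length(plot_lines)
    trial_no <- (seq_len(n) - 1) %/% capacity + 1
    within <- (seq_len(n) - 1) %% capacity
    out[[e]] <- tibble(
      line = plot_lines,
      population = pop,
      year = envs$year[e],
      location = envs$location[e],
      trial = sprintf("%s_%s_%s_t%d", pop, envs$year[e], envs$location[e], trial_no),
      x = within %% trial_cols + 1,
      y = within %/% trial_cols + 1
    )
  }
  bind_rows(out)
}

# indices of window members (incl. self) per plot, grouped by trial
window_members <- function(plots) {
  members <- vector("list", nrow(plots))
  for (idx in split(seq_len(nrow(plots)), plots$trial)) {
    x <- plots$x[idx]
    y <- plots$y[idx]
    for (i in seq_along(idx)) {
      members[[idx[i]]] <- idx[abs(x - x[i]) <= 2 & abs(y - y[i]) <= 1]
    }
  }
  members
}

# sparse plot -> spatial-position incidence (positions = plots)
spatial_incidence <- function(plots) {
  members <- window_members(plots)
  Matrix::sparseMatrix(
    i = rep(seq_along(members), lengths(members)),
    j = unlist(members),
    x = 1,
    dims = c(nrow(plots), nrow(plots))
  )
}

sim_environments <- function(n_env) {
  tibble(
    year = paste0("Y", (seq_len(n_env) - 1) %/% 3 + 1),
    location = paste0("L", (seq_len(n_env) - 1) %% 3 + 1)
  )
}

#' Simulate plot-level phenotypes for simulated genotypes
#'
#' For every population, plot records are generated for each line in
#' `n_reps` replicates per environment and phenotypes are composed as
#' population mean + environment fixed effect + breeding value (QTL plus
#' polygenic) + residual line effect + line-by-environment interaction +
#' the sum of spatial effects over the plot's moving window + residual
#' error. Polygenic effects are built from per-SNP marker effects whose
#' correlation across populations (and traits) follows the configuration,
#' so that the genetic value of a line is exactly the sum of its QTL
#' dosage effects and its polygenic term, and the additive values satisfy
#' `g ~ N(0, G * sigma2_raw)` under the population's own VanRaden GRM.
#'
#' Draws come from the current RNG state (see [simulate_breeding_data()]).
#'
#' @param geno A [geno_matrix()] from [simulate_population_genotypes()].
#' @param config The [sim_config()] used to generate `geno`.
#' @return A list: `plots` (tibble of plot records with one column per
#'   trait) and `truth` (ground-truth list: breeding values, QTL table,
#'   variance components on raw and reported scale, environment effects,
#'   GRM mean diagonals).
#' @export
simulate_phenotypes <- function(geno, config) {
  np <- config$n_populations
  nt <- config$n_traits
  traits <- config$trait_names
  # marker effects correlated across population x trait combinations
  R <- kronecker(config$polygenic_cor, config$trait_cor)
  Rc <- chol_psd(R)
  m <- nrow(geno$variants)
  alpha_std <- matrix(rnorm(m * np * nt), m, np * nt) %*% Rc # unit-variance effects
  qtl <- normalise_qtl(config)

  plots_all <- list()
  truth_alpha <- list()
  truth_bv <- list()
  truth_vc <- list()
  truth_env <- list()
  mean_diags <- numeric(np)
  names(mean_diags) <- config$pop_names

  for (k in seq_len(np)) {
    pop <- config$pop_names[k]
    lines <- lines_of(geno, pop)
    nl <- length(lines)
    d <- geno$dosage[match(lines, geno$samples$line), , drop = FALSE]
    G <- compute_grm(geno, lines = lines)
    mean_diags[k] <- mean_diag(G)
    raw_additive <- config$var_additive[k] / mean_diag(G)
    denom <- attr(G, "denom")
    p <- colMeans(d) / 2
    Zc <- sweep(d, 2, 2 * p)

    # per-trait genetic values
    qtl_val <- matrix(0, nl, nt)
    poly_val <- matrix(0, nl, nt)
    for (t_i in seq_len(nt)) {
      col <- (k - 1) * nt + t_i
      a_scaled <- alpha_std[, col] * sqrt(raw_additive / denom)
      poly_val[, t_i] <- as.numeric(Zc %*% a_scaled)
      truth_alpha[[length(truth_alpha) + 1]] <- tibble(
        id = geno$variants$id, population = pop, trait = traits[t_i],
        effect = a_scaled
      )
    }
    if (!is.null(qtl) && nt >= 1) {
      j <- match(qtl$id, geno$variants$id)
      eff <- qtl[[pop]]
      qtl_val[, 1] <- as.numeric(d[, j, drop = FALSE] %*% eff)
    }
    bv <- qtl_val + poly_val

    envs <- sim_environments(config$n_environments[k])
    env_eff <- matrix(
      rnorm(nrow(envs) * nt, 0, config$env_effect_sd),
      nrow(envs), nt
    )
    gl <- matrix(rnorm(nl * nt, 0, sqrt(config$var_line[k])), nl, nt)
    w <- array(
      rnorm(nl * nrow(envs) * nt, 0, sqrt(config$var_gxe[k])),
      c(nl, nrow(envs), nt)
    )

    plots <- layout_plots(
      lines, pop, envs, config$n_reps[k],
      config$trial_rows, config$trial_cols
    )
    li <- match(plots$line, lines)
    ei <- match(paste(plots$year, plots$location), paste(envs$year, envs$location))
    Zs <- spatial_incidence(plots)
    var_spatial_raw <- config$var_spatial[k] / 15
    for (t_i in seq_len(nt)) {
      s <- rnorm(nrow(plots), 0, sqrt(var_spatial_raw))
      e <- rnorm(nrow(plots), 0, sqrt(config$var_error[k]))
      plots[[traits[t_i]]] <- config$pop_mean[k] +
        env_eff[ei, t_i] +
        bv[li, t_i] + gl[li, t_i] + w[cbind(li, ei, t_i)] +
        as.numeric(Zs %*% s) + e
    }
    plots_all[[k]] <- plots

    truth_bv[[k]] <- tibble(
      line = rep(lines, nt),
      population = pop,
      trait = rep(traits, each = nl),
      qtl_value = as.numeric(qtl_val),
      polygenic = as.numeric(poly_val),
      breeding_value = as.numeric(bv)
    )
    truth_vc[[k]] <- tibble(
      population = pop,
      component = c("additive", "line", "gxe", "spatial", "error"),
      reported = c(
        config$var_additive[k], config$var_line[k], config$var_gxe[k],
        config$var_spatial[k], config$var_error[k]
      ),
      raw = c(
        raw_additive, config$var_line[k], config$var_gxe[k],
        var_spatial_raw, config$var_error[k]
      )
    )
    truth_env[[k]] <- tibble(
      population = pop,
      year = rep(envs$year, nt),
      location = rep(envs$location, nt),
      trait = rep(traits, each = nrow(envs)),
      effect = as.numeric(env_eff)
    )
  }

  truth <- structure(
    list(
      breeding_values = bind_rows(truth_bv),
      marker_effects = bind_rows(truth_alpha),
      qtl = qtl,
      varcomp = bind_rows(truth_vc),
      env_effects = bind_rows(truth_env),
      grm_mean_diag = mean_diags,
      polygenic_cor = config$polygenic_cor,
      trait_cor = config$trait_cor
    ),
    class = "sim_truth"
  )
  list(plots = bind_rows(plots_all), truth = truth)
}

# upper-triangular factor of a PSD correlation matrix (rank-safe)
chol_psd <- function(R) {
  es <- eigen(R, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  t(es$vectors %*% diag(sqrt(ev), length(ev)) %*% t(es$vectors))
}

# qtl table with one effect column per population and an `id` column
normalise_qtl <- function(config) {
  qtl <- config$qtl
  if (is.null(qtl)) return(NULL)
  map <- snp_map(config)
  qtl$id <- map$id[match(paste(qtl$chrom, qtl$pos), paste(map$chrom, map$pos))]
  if ("effect" %in% names(qtl)) {
    for (pop in config$pop_names) qtl[[pop]] <- qtl$effect
  }
  qtl
}

#' Simulate a complete multi-population breeding data set
#'
#' Seeds the RNG once from `config$seed` and draws, in order: ancestral
#' and per-population allele frequencies, founder haplotypes, crossing and
#' inbreeding meioses (population by population, family by family), marker
#' effects, environment effects, and the plot-level random terms. Repeat
#' calls with the same configuration are identical.
#'
#' @param config A [sim_config()].
#' @return A `sim_data` list: `geno`, `plots`, `truth`, `pedigree`,
#'   `config`.
#' @export
simulate_breeding_data <- function(config) {
  set.seed(config$seed)
  g <- simulate_population_genotypes(config)
  ph <- simulate_phenotypes(g$geno, config)
  structure(
    list(
      geno = g$geno, plots = ph$plots, truth = ph$truth,
      pedigree = g$pedigree, config = config
    ),
    class = "sim_data"
  )
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(
    "<sim_data> %d lines x %d SNPs, %d plots, %d trait(s), seed %d\n",
    nrow(x$geno$dosage), ncol(x$geno$dosage), nrow(x$plots),
    x$config$n_traits, x$config$seed
  ))
  invisible(x)
}
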
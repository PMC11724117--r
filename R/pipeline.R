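#' Run the full multi-population GWAS pipeline
#'
#' Configuration-driven driver tying together simulation (or file input),
#' PCA outlier removal, MAC filtering, GRM construction, REML variance
#' components and heritability, the three GWAS modes, candidate-QTL
#' grouping, LD/LPS summaries and theoretical power, writing every stage
#' as TSV into a run directory together with a provenance manifest
#' (config hash, seed, package and R versions, stage log).
#'
#' The configuration is a named list (or a YAML file path) with fields:
#' * `seed`: integer;
#' * exactly one of `simulate` (arguments for [sim_config()]) or `input`
#'   (`vcf`, `plots`, `sample_map` paths);
#' * `trait`: trait column; `populations`: populations to analyse;
#' * `modes`: subset of `"single"`, `"mp1"`, `"mp2"` (default all);
#' * optional `alpha` (0.05), `max_gap` (5e6), `spatial_mode` (`"none"`),
#'   `terms`, `ld`, `lps`, `power` (logicals), `remove_outliers` (TRUE).
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (default `config$output_dir`).
#' @return Invisibly, a list with the run directory, the manifest, and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_run_config(config)
  out_dir <- out_dir %n% cfg$output_dir %n% abort("config field `output_dir` missing")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    inform(line)
    log_lines <<- c(log_lines, line)
  }
  results <- list()

  set.seed(cfg$seed)
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %n% cfg$seed
    if (!is.null(sim_args$polygenic_cor)) {
      sim_args$polygenic_cor <- as.matrix_checked(sim_args$polygenic_cor)
    }
    sim <- simulate_breeding_data(do.call(sim_config, sim_args))
    geno <- sim$geno
    plots <- sim$plots
    results$truth <- sim$truth
    write_sim_fixture(sim, file.path(out_dir, "simulated"))
    note("simulate: %d lines, %d SNPs, %d plots", nrow(geno$dosage),
         ncol(geno$dosage), nrow(plots))
  } else {
    geno <- read_vcf(cfg$input$vcf, cfg$input$sample_map)
    plots <- as_tibble(utils::read.delim(cfg$input$plots, sep = "\t"))
    note("input: %d lines, %d SNPs, %d plots", nrow(geno$dosage),
         ncol(geno$dosage), nrow(plots))
  }
  pops <- cfg$populations %n% unique(geno$samples$population)
  unknown <- setdiff(pops, unique(geno$samples$population))
  if (length(unknown) > 0) {
    abort(paste0("config field `populations`: unknown population(s) ",
                 paste(unknown, collapse = ", ")))
  }
  trait <- cfg$trait %n% "trait"
  if (!trait %in% names(plots)) {
    abort(paste0("config field `trait`: column `", trait, "` not in plot table"))
  }

  if (isTRUE(cfg$remove_outliers %n% TRUE) && length(unique(geno$samples$population)) > 1) {
    scan <- pca_outlier_scan(geno)
    write_tsv_plain(scan, file.path(out_dir, "pca_outliers.tsv"))
    drop_lines <- scan$line[scan$outlier]
    note("pca_outliers: %d line(s) removed", length(drop_lines))
    if (length(drop_lines) > 0) {
      keep <- setdiff(geno$samples$line, drop_lines)
      geno <- subset_geno(geno, lines = keep)
      plots <- filter(plots, !.data$line %in% drop_lines)
    }
    results$outliers <- scan
  }

  alpha <- cfg$alpha %n% 0.05
  spatial_mode <- cfg$spatial_mode %n% "none"
  terms <- cfg$terms %n% c("additive", "line", "gxe")
  modes <- cfg$modes %n% c("single", "mp1", "mp2")

  # per-population variance components and heritability
  comp_rows <- list()
  herit_rows <- list()
  grms <- list()
  lmms <- list()
  for (p in pops) {
    lines_p <- sort(unique(plots$line[plots$population == p & !is.na(plots[[trait]])]))
    grms[[p]] <- compute_grm(geno, lines = lines_p)
    lmms[[p]] <- fit_plot_lmm(
      filter(plots, .data$population == p), trait, grms[[p]],
      spatial_mode = spatial_mode, terms = terms
    )
    comp_rows[[p]] <- mutate(lmms[[p]]$components, population = p)
    h <- heritability(lmms[[p]]$components, lmms[[p]]$n_env, max(1, lmms[[p]]$n_rep))
    herit_rows[[p]] <- mutate(h, population = p)
    note("reml[%s]: %d plots, logLik %.2f", p, nrow(lmms[[p]]$plots),
         lmms[[p]]$fit$loglik)
  }
  results$components <- bind_rows(comp_rows)
  results$heritability <- bind_rows(herit_rows)
  write_tsv_plain(results$components, file.path(out_dir, "variance_components.tsv"))
  write_tsv_plain(results$heritability, file.path(out_dir, "heritability.tsv"))

  # GWAS modes
  results$gwas <- list()
  for (mode in modes) {
    res <- switch(mode,
      single = {
        per_pop <- lapply(pops, function(p) {
          r <- gwas_single(plots, geno, trait, p,
            grm = grms[[p]], null_fit = lmms[[p]], alpha = alpha
          )
          mutate(r, population = !!p)
        })
        bind_rows(per_pop)
      },
      mp1 = if (length(pops) >= 2) {
        gwas_mp1(plots, geno, trait, pops,
          spatial_mode = spatial_mode, terms = terms, alpha = alpha
        )
      },
      mp2 = if (length(pops) >= 2) {
        gwas_mp2(plots, geno, trait, pops,
          spatial_mode = spatial_mode, terms = terms, alpha = alpha
        )
      },
      abort(paste0("config field `modes`: unknown mode `", mode, "`"))
    )
    if (is.null(res)) next
    results$gwas[[mode]] <- res
    write_tsv_plain(res, file.path(out_dir, paste0("gwas_", mode, ".tsv")))
    n_sig <- sum(res$significant, na.rm = TRUE)
    note("gwas[%s]: %d SNP(s) tested, %d significant", mode,
         sum(!is.na(res$p)), n_sig)
    if (mode != "single") {
      qtls <- group_qtls(res, max_gap = cfg$max_gap %n% 5e6)
      if (nrow(qtls) > 0) {
        # per-population PVE of each lead SNP (Eq.-10 convention: allele
        # frequency and effect against the population's raw additive
        # variance)
        for (p in pops) {
          lines_p <- lines_of(geno, p)
          freq <- colMeans(
            geno$dosage[match(lines_p, geno$samples$line), qtls$lead_id,
                        drop = FALSE],
            na.rm = TRUE
          ) / 2
          beta_col <- if (mode == "mp2") paste0("beta_", p) else "beta"
          bhat <- res[[beta_col]][match(qtls$lead_id, res$id)]
          raw_add <- results$components$raw[
            results$components$population == p &
              results$components$component == "additive"
          ]
          qtls[[paste0("pve_pct_", p)]] <- if (raw_add > 0) {
            pve(freq, bhat, raw_add)$pve_pct
          } else {
            NA_real_
          }
        }
      }
      results$qtl[[mode]] <- qtls
      write_tsv_plain(qtls, file.path(out_dir, paste0("qtl_", mode, ".tsv")))
    }
  }

  if (isTRUE(cfg$ld)) {
    for (p in pops) {
      curve <- ld_decay_curve(geno, lines = lines_of(geno, p))
      write_tsv_plain(curve, file.path(out_dir, paste0("ld_decay_", p, ".tsv")))
    }
    note("ld: decay curves written for %d population(s)", length(pops))
  }
  if (isTRUE(cfg$lps) && length(pops) >= 2) {
    prs <- utils::combn(pops, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      lc <- lps_curve(geno, grms[[a]], grms[[b]], a, b)
      write_tsv_plain(lc, file.path(out_dir, paste0("lps_", a, "_", b, ".tsv")))
    }
    note("lps: %d population pair(s)", ncol(prs))
  }
  if (isTRUE(cfg$power %n% TRUE)) {
    pw <- list()
    for (mode in names(results$gwas)) {
      res <- results$gwas[[mode]]
      if (mode == "single") {
        for (p in pops) {
          sub <- filter(as_tibble(res), .data$population == !!p)
          attr(sub, "mode") <- "single"
          attr(sub, "population") <- p
          attr(sub, "bonferroni") <-
            bonferroni_threshold(sum(!is.na(sub$p)), alpha)$threshold
          pw[[paste0("single_", p)]] <- mutate(
            power_curve_gwas(sub, geno, populations = pops),
            mode = paste0("single_", !!p)
          )
        }
      } else {
        pw[[mode]] <- power_curve_gwas(res, geno, populations = pops)
      }
    }
    results$power <- bind_rows(pw)
    write_tsv_plain(results$power, file.path(out_dir, "power.tsv"))
    note("power: %d curve(s)", length(pw))
  }

  manifest <- list(
    package = "mpgwas",
    version = as.character(utils::packageVersion("mpgwas")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    config = cfg[setdiff(names(cfg), "simulate_data")],
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(dir = out_dir, manifest = manifest, results = results))
}

as.matrix_checked <- function(x) {
  if (is.matrix(x)) return(x)
  m <- do.call(rbind, x)
  storage.mode(m) <- "double"
  m
}

validate_run_config <- function(config) {
  if (!is.list(config)) abort("config must be a named list or YAML path")
  if (is.null(config$seed)) abort("config field `seed` missing")
  config$seed <- as.integer(config$seed)
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("config must contain exactly one of `simulate` or `input`")
  }
  if (has_input) {
    for (f in c("vcf", "plots", "sample_map")) {
      if (is.null(config$input[[f]])) {
        abort(paste0("config field `input$", f, "` missing"))
      }
    }
  }
  config
}
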
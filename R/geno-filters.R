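#' Minor allele counts
#'
#' The minor allele count (MAC) of a biallelic SNP is the smaller of the alt
#' and ref allele counts over the non-missing calls in the chosen lines.
#'
#' @param gm A [geno_matrix()].
#' @param snps Variant ids (default: all SNPs).
#' @param lines Line ids to count over (default: all lines).
#' @return Named integer vector of MACs, one per SNP.
#' @export
minor_allele_count <- function(gm, snps = NULL, lines = NULL) {
  snps <- snps %n% gm$variants$id
  lines <- lines %n% gm$samples$line
  if (length(lines) == 0) abort("`lines` must be non-empty")
  d <- gm$dosage[match(lines, gm$samples$line), match(snps, gm$variants$id), drop = FALSE]
  alt <- colSums(d, na.rm = TRUE)
  n_called <- colSums(!is.na(d))
  ref <- 2 * n_called - alt
  setNames(as.integer(pmin(alt, ref)), snps)
}

#' Filter SNPs on minor allele count
#'
#' Three MAC rules are supported:
#' * `"merge20"`: MAC >= 20 over all lines (the merged-panel filter);
#' * `"single30"`: MAC >= 30 within the analysis population;
#' * `"multi30_10"`: total MAC >= 30 over the combined populations *and*
#'   MAC >= 10 within every included population.
#'
#' @param gm A [geno_matrix()].
#' @param mode One of `"merge20"`, `"single30"`, `"multi30_10"`.
#' @param populations Populations defining the analysis set. Required for
#'   `"single30"` (exactly one) and `"multi30_10"` (two or more); ignored
#'   for `"merge20"`.
#' @return A tibble with columns `id`, `chrom`, `pos`, the MAC column(s)
#'   used by the rule, and logical `retained`.
#' @export
filter_snps <- function(gm, mode = c("merge20", "single30", "multi30_10"),
                        populations = NULL) {
  mode <- match.arg(mode)
  out <- select(gm$variants, "id", "chrom", "pos")
  if (mode == "merge20") {
    out$mac <- unname(minor_allele_count(gm))
    out$retained <- out$mac >= 20
  } else if (mode == "single30") {
    if (length(populations) != 1) abort("`single30` needs exactly one population")
    out$mac <- unname(minor_allele_count(gm, lines = lines_of(gm, populations)))
    out$retained <- out$mac >= 30
  } else {
    if (length(populations) < 2) abort("`multi30_10` needs two or more populations")
    per_pop <- matrix(
      vapply(
        populations,
        function(p) minor_allele_count(gm, lines = lines_of(gm, p)),
        numeric(nrow(out))
      ),
      nrow = nrow(out), dimnames = list(NULL, paste0("mac_", populations))
    )
    out$mac_total <- unname(minor_allele_count(gm, lines = lines_of(gm, populations)))
    out <- bind_cols_matrix(out, per_pop)
    out$retained <- out$mac_total >= 30 & apply(per_pop >= 10, 1, all)
  }
  out
}

bind_cols_matrix <- function(df, m) {
  for (j in colnames(m)) df[[j]] <- as.integer(m[, j])
  df
}

#' Retained variant ids under a MAC filter
#'
#' @inheritParams filter_snps
#' @return Character vector of variant ids passing the rule.
#' @export
retained_snps <- function(gm, mode, populations = NULL) {
  f <- filter_snps(gm, mode, populations)
  f$id[f$retained]
}

#' SNP density statistics
#'
#' Counts SNPs in 1-Mbp windows per chromosome and computes the median
#' distance between neighbouring SNPs (successive sorted positions within
#' chromosomes). With fewer than two SNPs on every chromosome the median
#' neighbour distance is reported as `NA`.
#'
#' @param gm A [geno_matrix()].
#' @param window_bp Window width for density counts (default 1 Mbp).
#' @return A list with `density` (tibble: `chrom`, `window_start`,
#'   `window_end`, `n_snps`) and `median_neighbour_distance` (scalar bp,
#'   possibly `NA`).
#' @export
snp_density_stats <- function(gm, window_bp = 1e6) {
  v <- arrange(gm$variants, .data$chrom, .data$pos)
  density <- purrr::map_dfr(split(v, v$chrom), function(vc) {
    starts <- seq(1, max(vc$pos), by = window_bp)
    idx <- floor((vc$pos - 1) / window_bp) + 1
    tibble(
      chrom = vc$chrom[1],
      window_start = starts,
      window_end = starts + window_bp - 1,
      n_snps = as.integer(tabulate(idx, nbins = length(starts)))
    )
  })
  gaps <- unlist(lapply(split(v$pos, v$chrom), diff), use.names = FALSE)
  list(
    density = density,
    median_neighbour_distance = if (length(gaps) > 0) median(gaps) else NA_real_
  )
}
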
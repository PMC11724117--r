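#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes `G = Z Z' / (2 * sum(p * (1 - p)))` where `Z` is the dosage
#' matrix column-centered at `2p` and `p` are the alt-allele frequencies in
#' the analysis subset. Missing dosages are mean-imputed per SNP within the
#' subset before centering. Monomorphic SNPs contribute nothing to either
#' numerator or denominator; an all-monomorphic input is an error (zero
#' denominator).
#'
#' The mean of the diagonal of `G` (about `1 + F` for inbreeding
#' coefficient `F`; close to 2 in fully inbred lines) is stored and used as
#' the inbreeding adjustment factor when reporting additive variance
#' components.
#'
#' @param gm A [geno_matrix()].
#' @param lines Line ids defining the analysis subset (default: all lines).
#' @param snps Variant ids to use (default: all).
#' @return A `mpgwas_grm`: the relationship matrix with attributes
#'   `mean_diag`, `n_snps` (polymorphic SNPs used) and `denom`.
#' @export
compute_grm <- function(gm, lines = NULL, snps = NULL) {
  lines <- lines %n% gm$samples$line
  snps <- snps %n% gm$variants$id
  d <- gm$dosage[match(lines, gm$samples$line), match(snps, gm$variants$id), drop = FALSE]
  d <- impute_mean(d)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all SNPs monomorphic in the subset: GRM denominator is zero")
  Z <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(lines, lines)
  structure(G,
    mean_diag = mean(diag(G)), n_snps = sum(poly), denom = denom,
    class = c("mpgwas_grm", "matrix", "array")
  )
}

# per-column mean imputation of missing dosages
impute_mean <- function(d) {
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    d[nas] <- mu[nas[, 2]]
  }
  d
}

#' Mean diagonal of a GRM
#'
#' @param grm A matrix from [compute_grm()].
#' @return Scalar mean of the diagonal.
#' @export
mean_diag <- function(grm) {
  attr(grm, "mean_diag") %n% mean(diag(as.matrix(grm)))
}

#' @export
as.matrix.mpgwas_grm <- function(x, ...) {
  y <- unclass(x)
  attr(y, "mean_diag") <- NULL
  attr(y, "n_snps") <- NULL
  attr(y, "denom") <- NULL
  y
}

#' @export
print.mpgwas_grm <- function(x, ...) {
  cat(sprintf(
    "<mpgwas_grm> %d lines, %d SNPs, mean diagonal %.3f\n",
    nrow(x), attr(x, "n_snps"), mean_diag(x)
  ))
  invisible(x)
}

#' PCA-based population outlier scan
#'
#' Principal components are computed on centered (not standardised) mean
#' imputed dosages. For every population the componentwise median in
#' PC1-PC3 space is taken; a line is flagged as an outlier when its
#' Euclidean distance to another population's median is smaller than the
#' distance to the median of its assigned population.
#'
#' @param gm A [geno_matrix()] with at least two populations.
#' @param n_pc Number of leading components for the rule (default 3).
#' @return A tibble with one row per line: `line`, `population`,
#'   `nearest_population`, `dist_assigned`, `dist_nearest`, `outlier`.
#' @export
pca_outlier_scan <- function(gm, n_pc = 3) {
  pops <- unique(gm$samples$population)
  if (length(pops) < 2) {
    return(mutate(gm$samples,
      nearest_population = .data$population,
      dist_assigned = 0, dist_nearest = 0, outlier = FALSE
    ))
  }
  d <- impute_mean(gm$dosage)
  keep <- apply(d, 2, function(x) var(x) > 0)
  pc <- prcomp(d[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < n_pc) abort(sprintf("fewer than %d informative PCs", n_pc))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  medians <- vapply(
    pops,
    function(p) apply(scores[gm$samples$population == p, , drop = FALSE], 2, median),
    numeric(n_pc)
  ) # n_pc x n_pop
  dist_to <- vapply(
    pops,
    function(p) sqrt(rowSums(sweep(scores, 2, medians[, p])^2)),
    numeric(nrow(scores))
  ) # lines x n_pop
  own <- dist_to[cbind(seq_len(nrow(scores)), match(gm$samples$population, pops))]
  other <- dist_to
  other[cbind(seq_len(nrow(scores)), match(gm$samples$population, pops))] <- Inf
  nearest_idx <- apply(other, 1, which.min)
  dist_nearest <- other[cbind(seq_along(nearest_idx), nearest_idx)]
  tibble(
    line = gm$samples$line,
    population = gm$samples$population,
    nearest_population = pops[nearest_idx],
    dist_assigned = own,
    dist_nearest = dist_nearest,
    outlier = dist_nearest < own
  )
}
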
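# Pairwise LD as Pearson correlation of dosages (r, r2) and its
# kinship-corrected analogue r_v: the generalised-least-squares
# correlation under covariance K = GRM + ridge, i.e. dosages are centered
# at their GLS means and correlated in the K^-1 inner product. With
# K = I the two coincide.

#' Pairwise LD between two SNPs
#'
#' @param gm A [geno_matrix()].
#' @param snp_a,snp_b Variant ids.
#' @param lines Line subset (default: all lines).
#' @return A one-row tibble with `r` (signed) and `r2`; both `NA` when a
#'   SNP is monomorphic in the subset.
#' @export
ld_r <- function(gm, snp_a, snp_b, lines = NULL) {
  lines <- lines %n% gm$samples$line
  d <- gm$dosage[match(lines, gm$samples$line), c(snp_a, snp_b), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (var(d[, 1]) == 0 || var(d[, 2]) == 0) {
    return(tibble(snp_a = snp_a, snp_b = snp_b, r = NA_real_, r2 = NA_real_))
  }
  r <- cor(d[, 1], d[, 2])
  tibble(snp_a = snp_a, snp_b = snp_b, r = r, r2 = r^2)
}

# K^-1 with a ridge of 1e-6 x mean diagonal (GRMs built from few SNPs are
# rank-deficient)
kinship_inverse <- function(grm, ridge = 1e-6) {
  K <- as.matrix(grm)
  K <- K + diag(ridge * mean(diag(K)), nrow(K))
  ch <- tryCatch(chol(K), error = function(e) {
    abort("kinship matrix singular even after ridge regularisation")
  })
  chol2inv(ch)
}

# GLS-centered K^-1 correlation matrix of dosage columns
gls_corr_matrix <- function(d, Kinv) {
  ones <- rep(1, nrow(d))
  s <- sum(Kinv)
  mu <- colSums(Kinv %*% d) / s
  dc <- sweep(d, 2, mu)
  M <- crossprod(dc, Kinv %*% dc)
  sd <- sqrt(diag(M))
  ok <- sd > 0
  R <- M / tcrossprod(sd)
  R[!ok, ] <- NA_real_
  R[, !ok] <- NA_real_
  R
}

#' Kinship-corrected pairwise LD (r_v)
#'
#' @inheritParams ld_r
#' @param grm Relationship matrix over `lines` (from [compute_grm()]).
#' @param ridge Relative ridge added to the kinship diagonal before
#'   inversion (default `1e-6` of the mean diagonal).
#' @return A one-row tibble with `rv` (signed) and `rv2`.
#' @export
ld_rv <- function(gm, grm, snp_a, snp_b, lines = NULL, ridge = 1e-6) {
  lines <- lines %n% gm$samples$line
  d <- impute_mean(gm$dosage[match(lines, gm$samples$line), c(snp_a, snp_b), drop = FALSE])
  Kinv <- kinship_inverse(as.matrix(grm)[lines, lines], ridge)
  R <- gls_corr_matrix(d, Kinv)
  tibble(snp_a = snp_a, snp_b = snp_b, rv = R[1, 2], rv2 = R[1, 2]^2)
}

# all intra-chromosomal pairs: distance + correlation value, one tibble
pairwise_ld_table <- function(gm, lines, grm = NULL, corrected = FALSE,
                              ridge = 1e-6) {
  li <- match(lines, gm$samples$line)
  Kinv <- if (corrected) kinship_inverse(as.matrix(grm)[lines, lines], ridge)
  out <- list()
  for (ch in unique(gm$variants$chrom)) {
    j <- which(gm$variants$chrom == ch)
    d <- impute_mean(gm$dosage[li, j, drop = FALSE])
    poly <- apply(d, 2, var) > 0
    if (sum(poly) < 2) next
    d <- d[, poly, drop = FALSE]
    pos <- gm$variants$pos[j][poly]
    R <- if (corrected) gls_corr_matrix(d, Kinv) else suppressWarnings(cor(d))
    ut <- which(upper.tri(R), arr.ind = TRUE)
    out[[ch]] <- tibble(
      chrom = ch,
      dist = abs(pos[ut[, 2]] - pos[ut[, 1]]),
      value = R[ut]
    )
  }
  bind_rows(out)
}

#' Binned LD-decay curve
#'
#' All within-chromosome SNP pairs are assigned to left-closed,
#' right-open distance bins of `bin_width` bp (first bin `[0, 10)` kbp by
#' default) and the mean squared correlation per bin is reported, together
#' with the distance at which LD decays to `threshold` (default 0.2):
#' the first linear-interpolated crossing between consecutive bin means,
#' anchored at (0 bp, r2 = 1) before the first bin. `NA` when the curve
#' never crosses.
#'
#' @inheritParams ld_rv
#' @param corrected Use kinship-corrected `rv2` (requires `grm`)?
#' @param bin_width Bin width in bp (default 10 kbp).
#' @param threshold LD-decay threshold (default 0.2).
#' @return An `mpgwas_ld_decay` tibble: `bin`, `dist_lo`, `dist_hi`,
#'   `mean_dist`, `mean_r2`, `n_pairs`; decay distance in attribute
#'   `"decay_distance"` (and `attr(, "corrected")`).
#' @export
ld_decay_curve <- function(gm, lines = NULL, grm = NULL, corrected = FALSE,
                           bin_width = 1e4, threshold = 0.2, ridge = 1e-6) {
  lines <- lines %n% gm$samples$line
  if (corrected && is.null(grm)) abort("`grm` required when corrected = TRUE")
  pairs <- pairwise_ld_table(gm, lines, grm, corrected, ridge)
  if (nrow(pairs) == 0) {
    out <- tibble(
      bin = integer(0), dist_lo = numeric(0), dist_hi = numeric(0),
      mean_dist = numeric(0), mean_r2 = numeric(0), n_pairs = integer(0)
    )
    return(structure(out,
      decay_distance = NA_real_, corrected = corrected,
      class = c("mpgwas_ld_decay", class(out))
    ))
  }
  pairs <- filter(pairs, !is.na(.data$value))
  pairs$bin <- floor(pairs$dist / bin_width) + 1
  curve <- pairs %>%
    group_by(.data$bin) %>%
    summarise(
      mean_dist = mean(.data$dist),
      mean_r2 = mean(.data$value^2),
      n_pairs = n(), .groups = "drop"
    ) %>%
    mutate(
      dist_lo = (.data$bin - 1) * bin_width,
      dist_hi = .data$bin * bin_width
    ) %>%
    arrange(.data$bin) %>%
    select("bin", "dist_lo", "dist_hi", "mean_dist", "mean_r2", "n_pairs")
  decay <- decay_distance(curve$mean_dist, curve$mean_r2, threshold)
  structure(curve,
    decay_distance = decay, corrected = corrected, threshold = threshold,
    class = c("mpgwas_ld_decay", class(curve))
  )
}

# first downward crossing of `threshold`, linear interpolation between
# consecutive (distance, value) points, anchored at (0, 1)
decay_distance <- function(dist, value, threshold = 0.2) {
  x <- c(0, dist)
  v <- c(1, value)
  for (i in seq_len(length(v) - 1)) {
    if (v[i] >= threshold && v[i + 1] < threshold) {
      return(x[i] + (v[i] - threshold) / (v[i] - v[i + 1]) * (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

#' Linkage phase similarity curve between two populations
#'
#' Within every distance bin, LPS is the cosine similarity of the signed
#' kinship-corrected LD values (`r_v`) of the two populations over the
#' SNP pairs polymorphic in both. LPS lies in `[-1, 1]`; empty bins are
#' absent from the result.
#'
#' @param gm A [geno_matrix()].
#' @param grm_a,grm_b Per-population GRMs over the lines of `pop_a` /
#'   `pop_b`.
#' @param pop_a,pop_b Population labels.
#' @param bin_width Bin width in bp (default 10 kbp).
#' @inheritParams ld_rv
#' @return An `mpgwas_lps` tibble: `bin`, `dist_lo`, `dist_hi`,
#'   `mean_dist`, `lps`, `n_pairs`.
#' @export
lps_curve <- function(gm, grm_a, grm_b, pop_a, pop_b, bin_width = 1e4,
                      ridge = 1e-6) {
  pairs <- shared_rv_pairs(gm, grm_a, grm_b, pop_a, pop_b, ridge)
  pairs$bin <- floor(pairs$dist / bin_width) + 1
  out <- pairs %>%
    group_by(.data$bin) %>%
    summarise(
      mean_dist = mean(.data$dist),
      lps = cosine_sim(.data$rv_a, .data$rv_b),
      n_pairs = n(), .groups = "drop"
    ) %>%
    mutate(
      dist_lo = (.data$bin - 1) * bin_width,
      dist_hi = .data$bin * bin_width
    ) %>%
    arrange(.data$bin) %>%
    select("bin", "dist_lo", "dist_hi", "mean_dist", "lps", "n_pairs")
  structure(out,
    populations = c(pop_a, pop_b),
    class = c("mpgwas_lps", class(out))
  )
}

cosine_sim <- function(a, b) {
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# signed r_v of both populations for every shared polymorphic SNP pair
shared_rv_pairs <- function(gm, grm_a, grm_b, pop_a, pop_b, ridge = 1e-6) {
  lines_a <- lines_of(gm, pop_a)
  lines_b <- lines_of(gm, pop_b)
  Kinv_a <- kinship_inverse(as.matrix(grm_a)[lines_a, lines_a], ridge)
  Kinv_b <- kinship_inverse(as.matrix(grm_b)[lines_b, lines_b], ridge)
  ia <- match(lines_a, gm$samples$line)
  ib <- match(lines_b, gm$samples$line)
  out <- list()
  for (ch in unique(gm$variants$chrom)) {
    j <- which(gm$variants$chrom == ch)
    da <- impute_mean(gm$dosage[ia, j, drop = FALSE])
    db <- impute_mean(gm$dosage[ib, j, drop = FALSE])
    poly <- apply(da, 2, var) > 0 & apply(db, 2, var) > 0
    if (sum(poly) < 2) next
    da <- da[, poly, drop = FALSE]
    db <- db[, poly, drop = FALSE]
    pos <- gm$variants$pos[j][poly]
    Ra <- gls_corr_matrix(da, Kinv_a)
    Rb <- gls_corr_matrix(db, Kinv_b)
    ut <- which(upper.tri(Ra), arr.ind = TRUE)
    out[[ch]] <- tibble(
      chrom = ch,
      pos_a = pos[ut[, 1]], pos_b = pos[ut[, 2]],
      dist = abs(pos[ut[, 2]] - pos[ut[, 1]]),
      rv_a = Ra[ut], rv_b = Rb[ut]
    )
  }
  bind_rows(out)
}

#' Windowed linkage phase similarity scan
#'
#' Computes LPS over all SNP pairs falling entirely inside overlapping
#' genomic windows (default 1 Mbp, stepping 0.5 Mbp) and flags windows
#' with negative LPS as candidate reverse-phase regions. Windows with
#' fewer than two pairs are dropped.
#'
#' @inheritParams lps_curve
#' @param window Window width in bp (default 1 Mbp).
#' @param step Step between window starts in bp (default 0.5 Mbp).
#' @return Tibble: `chrom`, `start`, `end`, `n_pairs`, `lps`,
#'   `reverse_phase`.
#' @export
lps_window_scan <- function(gm, grm_a, grm_b, pop_a, pop_b,
                            window = 1e6, step = 5e5, ridge = 1e-6) {
  pairs <- shared_rv_pairs(gm, grm_a, grm_b, pop_a, pop_b, ridge)
  empty <- tibble(
    chrom = character(0), start = numeric(0), end = numeric(0),
    n_pairs = integer(0), lps = numeric(0), reverse_phase = logical(0)
  )
  if (nrow(pairs) == 0) return(empty)
  out <- list(empty)
  for (ch in unique(pairs$chrom)) {
    pc <- filter(pairs, .data$chrom == ch)
    max_pos <- max(pc$pos_a, pc$pos_b)
    starts <- seq(0, max(0, max_pos - 1), by = step)
    for (s in starts) {
      inside <- pc$pos_a >= s & pc$pos_b >= s &
        pc$pos_a < s + window & pc$pos_b < s + window
      if (sum(inside) < 2) next
      lps <- cosine_sim(pc$rv_a[inside], pc$rv_b[inside])
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start = s, end = s + window,
        n_pairs = sum(inside), lps = lps,
        reverse_phase = !is.na(lps) && lps < 0
      )
    }
  }
  bind_rows(out)
}
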
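# Theoretical GWAS detection power from non-centrality parameters: a SNP
# with true effect b and estimation standard error SE yields a Wald
# chi-square statistic with 1 degree of freedom and NCP (b / SE)^2; power
# at type-1 error alpha is the non-central tail mass beyond the central
# 1 - alpha quantile.

#' Non-centrality parameter of the single-SNP Wald test
#'
#' @param b Hypothetical SNP effect (trait units per alt allele).
#' @param se Standard error(s) of the estimated SNP effect (> 0), as
#'   produced by an actual GWAS run.
#' @return `(b / se)^2`, vectorised over `se` (and `b`).
#' @export
ncp <- function(b, se) {
  if (any(se <= 0)) abort("`se` must be > 0")
  (b / se)^2
}

#' Non-centrality parameter for the combined MP2 statistic
#'
#' The hypothetical effect `b` is substituted for every population's
#' coefficient: the scaled coefficient is `sum(b / SE_j)` and its SE is
#' `sqrt(a' V a)` with `V` the scaled (unit-diagonal) estimation-error
#' covariance of the SNP.
#'
#' @param b Hypothetical shared SNP effect.
#' @param se Vector of per-population standard errors for one SNP.
#' @param V Scaled covariance matrix of the SNP's per-population
#'   regressions (unit diagonal; default identity, i.e. independent
#'   errors).
#' @return Scalar NCP.
#' @export
ncp_mp2 <- function(b, se, V = diag(length(se))) {
  if (any(se <= 0)) abort("`se` must be > 0")
  b_scaled <- sum(b / se)
  (b_scaled / sqrt(sum(V)))^2
}

#' Theoretical power curve over a grid of SNP effects
#'
#' For every effect size `b` on the grid (0 to sqrt(2) in steps of 0.01,
#' trait units) and every SNP, power is the probability that a
#' non-central chi-square statistic with 1 degree of freedom and NCP
#' `(b / SE)^2` exceeds the central quantile at `1 - alpha`; powers are
#' then averaged over SNPs to give one value per `b`. For the MP2 mode,
#' supply the per-population SE matrix and per-SNP scaled covariance so
#' the combined statistic's NCP is used.
#'
#' @param se For modes `"single"`/`"mp1"`: numeric vector of per-SNP
#'   standard errors. For `"mp2"`: a matrix (SNPs x populations) of
#'   per-population SEs.
#' @param alpha Type-1 error rate, typically the Bonferroni threshold of
#'   the corresponding GWAS run.
#' @param mode `"single"`, `"mp1"` or `"mp2"`.
#' @param Vlist For `"mp2"`: list of per-SNP scaled covariance matrices
#'   (default: independent errors).
#' @param b_grid Effect grid; defaults to 0 to sqrt(2) by 0.01 (values
#'   stored to 2 decimals).
#' @return An `mpgwas_power` tibble: `mode`, `b`, `b2`, `power`
#'   (mean over SNPs); `alpha` and the number of SNPs as attributes.
#' @export
power_curve <- function(se, alpha, mode = c("single", "mp1", "mp2"),
                        Vlist = NULL,
                        b_grid = round(seq(0, sqrt(2), by = 0.01), 2)) {
  mode <- match.arg(mode)
  crit <- qchisq(1 - alpha, df = 1)
  if (mode == "mp2") {
    se <- as.matrix(se)
    if (nrow(se) == 0) abort("empty SNP set")
    if (is.null(Vlist)) Vlist <- rep(list(diag(ncol(se))), nrow(se))
    pow <- vapply(b_grid, function(b) {
      ncps <- vapply(
        seq_len(nrow(se)),
        function(i) ncp_mp2(b, se[i, ], Vlist[[i]]),
        numeric(1)
      )
      mean(pchisq(crit, df = 1, ncp = ncps, lower.tail = FALSE))
    }, numeric(1))
    n_snps <- nrow(se)
  } else {
    se <- se[!is.na(se)]
    if (length(se) == 0) abort("empty SNP set")
    pow <- vapply(b_grid, function(b) {
      mean(pchisq(crit, df = 1, ncp = ncp(b, se), lower.tail = FALSE))
    }, numeric(1))
    n_snps <- length(se)
  }
  out <- tibble(mode = mode, b = b_grid, b2 = b_grid^2, power = pow)
  structure(out,
    alpha = alpha, n_snps = n_snps,
    class = c("mpgwas_power", class(out))
  )
}

#' Power curve from a fitted GWAS result
#'
#' Restricts to SNPs with MAC >= 30 in all analysed populations (the
#' common set) and builds the theoretical power curve from the run's
#' standard errors; for an MP2 result the per-SNP scaled estimation-error
#' covariances are carried over.
#'
#' @param assoc An `mpgwas_gwas` result.
#' @param gm The [geno_matrix()] the GWAS was run on.
#' @param populations Populations defining the common MAC >= 30 set
#'   (default: the run's populations).
#' @param alpha Type-1 error (default: the run's Bonferroni threshold).
#' @inheritParams power_curve
#' @return An `mpgwas_power` tibble.
#' @export
power_curve_gwas <- function(assoc, gm, populations = NULL, alpha = NULL,
                             b_grid = round(seq(0, sqrt(2), by = 0.01), 2)) {
  mode <- attr(assoc, "mode")
  populations <- populations %n%
    (attr(assoc, "populations") %n% attr(assoc, "population"))
  alpha <- alpha %n% attr(assoc, "bonferroni")
  keep <- rep(TRUE, nrow(assoc))
  for (p in populations) {
    keep <- keep & minor_allele_count(gm, assoc$id, lines_of(gm, p)) >= 30
  }
  assoc <- assoc[keep, , drop = FALSE]
  if (mode == "mp2") {
    pops <- attr(assoc, "populations") %n% populations
    se <- as.matrix(assoc[, paste0("se_", pops), drop = FALSE])
    covc <- grep("^cov_", names(assoc), value = TRUE)
    np <- length(pops)
    pair_idx <- which(upper.tri(diag(np)), arr.ind = TRUE)
    Vlist <- lapply(seq_len(nrow(assoc)), function(i) {
      V <- diag(np)
      for (pr in seq_along(covc)) {
        a <- pair_idx[pr, 1]; b <- pair_idx[pr, 2]
        V[a, b] <- V[b, a] <- assoc[[covc[pr]]][i] / (se[i, a] * se[i, b])
      }
      V
    })
    ok <- stats::complete.cases(se)
    power_curve(se[ok, , drop = FALSE], alpha, "mp2", Vlist[ok], b_grid)
  } else {
    power_curve(assoc$se, alpha, mode, b_grid = b_grid)
  }
}
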
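#' Genotype matrix for inbred lines
#'
#' A `geno_matrix` bundles an alt-allele dosage matrix (lines x SNPs, values
#' 0/1/2 or `NA`) with its variant table and a sample table carrying the
#' population assignment of every line.
#'
#' @param dosage Numeric matrix, lines in rows (rownames are line ids), SNPs
#'   in columns (colnames are variant ids). Entries count copies of the alt
#'   allele; `NA` marks a missing call.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per column of `dosage`, in matching order.
#' @param samples Data frame with columns `line` and `population`; one row
#'   per row of `dosage`, in matching order.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, samples) {
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  stopifnot(is.matrix(dosage))
  if (nrow(samples) != nrow(dosage)) {
    abort("`samples` must have one row per line (row of `dosage`)")
  }
  if (nrow(variants) != ncol(dosage)) {
    abort("`variants` must have one row per SNP (column of `dosage`)")
  }
  if (anyDuplicated(samples$line)) abort("duplicated line ids in `samples`")
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- samples$line
  colnames(dosage) <- variants$id
  structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf(
    "<geno_matrix> %d lines x %d SNPs (%d chromosome%s)\n",
    nrow(x$dosage), ncol(x$dosage),
    length(unique(x$variants$chrom)),
    if (length(unique(x$variants$chrom)) == 1) "" else "s"
  ))
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param lines Character vector of line ids (default: all).
#' @param snps Character vector of variant ids (default: all).
#' @return A `geno_matrix` restricted to the requested lines and SNPs.
#' @export
subset_geno <- function(gm, lines = NULL, snps = NULL) {
  lines <- lines %n% gm$samples$line
  snps <- snps %n% gm$variants$id
  miss <- setdiff(lines, gm$samples$line)
  if (length(miss) > 0) abort(paste0("unknown lines: ", paste(head(miss, 5), collapse = ", ")))
  miss <- setdiff(snps, gm$variants$id)
  if (length(miss) > 0) abort(paste0("unknown SNPs: ", paste(head(miss, 5), collapse = ", ")))
  i <- match(lines, gm$samples$line)
  j <- match(snps, gm$variants$id)
  geno_matrix(gm$dosage[i, j, drop = FALSE], gm$variants[j, ], gm$samples[i, ])
}

# population labels for a set of lines, in order
pop_of <- function(gm, lines) {
  gm$samples$population[match(lines, gm$samples$line)]
}

#' Lines belonging to given populations
#'
#' @param gm A [geno_matrix()].
#' @param populations Character vector of population labels.
#' @return Character vector of line ids.
#' @export
lines_of <- function(gm, populations) {
  unknown <- setdiff(populations, unique(gm$samples$population))
  if (length(unknown) > 0) {
    abort(paste0("unknown population(s): ", paste(unknown, collapse = ", ")))
  }
  gm$samples$line[gm$samples$population %in% populations]
}
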
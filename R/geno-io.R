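#' Read biallelic SNP genotypes from a VCF
#'
#' Parses a VCF (v4.x) with `vcfR`, converts GT calls to alt-allele dosages
#' and attaches population labels from a sample map. Only biallelic SNPs are
#' accepted; multiallelic records are rejected with their coordinates.
#' Missing genotypes are preserved as `NA`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param sample_map Data frame with columns `sample` (or `line`) and
#'   `population`, or path to a two-column TSV with that header. Every sample
#'   in the VCF must be present in the map.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, sample_map) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %n% character(0))
  if (any(multi)) {
    where <- paste(fix$CHROM[multi], fix$POS[multi], sep = ":")
    abort(paste0(
      "multiallelic record(s) not supported: ",
      paste(head(where, 5), collapse = ", "),
      if (sum(multi) > 5) sprintf(" (and %d more)", sum(multi) - 5) else ""
    ))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count alt alleles per call; any separator (/ or |)
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(g[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
    out
  }
  dosage <- t(apply(gt, 1, count_alt))
  if (ncol(gt) == 1) dosage <- t(dosage)
  colnames(dosage) <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  if (is.character(sample_map) && length(sample_map) == 1) {
    sample_map <- utils::read.delim(sample_map, sep = "\t", stringsAsFactors = FALSE)
  }
  sample_map <- as_tibble(sample_map)
  if ("sample" %in% names(sample_map)) sample_map <- rename(sample_map, line = "sample")
  unknown <- setdiff(colnames(dosage), sample_map$line)
  if (length(unknown) > 0) {
    abort(paste0("VCF samples missing from sample map: ", paste(head(unknown, 5), collapse = ", ")))
  }
  samples <- tibble(
    line = colnames(dosage),
    population = sample_map$population[match(colnames(dosage), sample_map$line)]
  )
  geno_matrix(t(dosage), variants, samples)
}

#' Write a genotype matrix as plain-text VCF v4.2
#'
#' Serialises dosages back to unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`)
#' with one contig line per chromosome. The output round-trips exactly
#' through [read_vcf()].
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- t(gm$dosage) # SNPs x lines
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$line), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
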
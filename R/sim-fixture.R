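#' Write a simulated data set to disk
#'
#' Emits three plain-text files into `dir`: `genotypes.vcf` (VCF v4.2),
#' `plots.tsv` (tab-separated plot records, full double precision) and
#' `truth.json` (ground truth: QTL table, variance components, breeding
#' values, environment effects). A sample-to-population map
#' (`samples.tsv`) is written alongside for [read_vcf()]. Outputs are
#' byte-identical across repeat calls on the same object.
#'
#' @param sim A `sim_data` object from [simulate_breeding_data()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  check_writable <- file.access(dir, 2) == 0
  if (!check_writable) abort(paste0("directory not writable: ", dir))
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    plots = file.path(dir, "plots.tsv"),
    truth = file.path(dir, "truth.json"),
    samples = file.path(dir, "samples.tsv")
  )
  write_vcf(sim$geno, paths["vcf"])
  write_tsv_plain(sim$plots, paths["plots"])
  write_tsv_plain(rename(sim$geno$samples, sample = "line"), paths["samples"])
  truth <- sim$truth
  jsonlite::write_json(
    list(
      qtl = truth$qtl,
      varcomp = truth$varcomp,
      breeding_values = truth$breeding_values,
      env_effects = truth$env_effects,
      grm_mean_diag = as.list(truth$grm_mean_diag),
      polygenic_cor = truth$polygenic_cor,
      trait_cor = truth$trait_cor,
      seed = sim$config$seed
    ),
    paths["truth"],
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(paths)
}

# deterministic TSV writer (full precision, no scientific drift)
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a simulated fixture back
#'
#' @param dir Directory written by [write_sim_fixture()].
#' @return List with `geno` (a [geno_matrix()]), `plots` (tibble) and
#'   `truth` (list).
#' @export
read_sim_fixture <- function(dir) {
  geno <- read_vcf(file.path(dir, "genotypes.vcf"), file.path(dir, "samples.tsv"))
  plots <- as_tibble(utils::read.delim(file.path(dir, "plots.tsv"), sep = "\t"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(geno = geno, plots = plots, truth = truth)
}
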
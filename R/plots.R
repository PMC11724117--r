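# ggplot2 methods for the package's result types. These cover the
# standard displays: Manhattan plots for association scans, decay curves
# for LD, per-bin similarity for LPS and power-vs-effect curves.

#' @export
autoplot.mpgwas_gwas <- function(object, threshold = NULL, ...) {
  threshold <- threshold %n% attr(object, "bonferroni")
  df <- filter(as_tibble(object), !is.na(.data$p))
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos / 1e6, y = -log10(.data$p), colour = .data$chrom
  )) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mbp)", y = expression(-log[10](italic(p))),
      title = paste0("GWAS (", attr(object, "mode"), ")")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = -log10(threshold), linetype = "dashed", colour = "grey30"
    )
  }
  p
}

#' @export
autoplot.mpgwas_ld_decay <- function(object, ...) {
  lab <- if (isTRUE(attr(object, "corrected"))) {
    expression(mean ~ italic(r)[v]^2)
  } else {
    expression(mean ~ italic(r)^2)
  }
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$mean_dist / 1e3, y = .data$mean_r2
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold") %n% 0.2,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "distance (kbp)", y = lab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mpgwas_lps <- function(object, ...) {
  pops <- attr(object, "populations")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$mean_dist / 1e3, y = .data$lps
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "distance (kbp)", y = "linkage phase similarity",
      title = if (!is.null(pops)) paste(pops, collapse = " vs ")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mpgwas_power <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$b2, y = .data$power, colour = .data$mode
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(italic(b)^2 ~ "(squared SNP effect)"),
      y = "mean detection power", colour = NULL
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Long per-population view of an association scan
#'
#' For MP2 results the wide per-population effect columns are pivoted to
#' one row per SNP and population; single/MP1 results are returned with
#' standard column names.
#'
#' @param x An `mpgwas_gwas` tibble.
#' @param ... Unused.
#' @export
tidy.mpgwas_gwas <- function(x, ...) {
  mode <- attr(x, "mode")
  df <- as_tibble(x)
  if (mode != "mp2") {
    return(select(df, dplyr::any_of(c(
      "id", "chrom", "pos", "mac", "beta", "se", "z", "p", "significant",
      "population"
    ))))
  }
  pops <- attr(x, "populations")
  long <- tidyr::pivot_longer(
    select(df, "id", "chrom", "pos",
           dplyr::all_of(c(paste0("beta_", pops), paste0("se_", pops)))),
    cols = -c("id", "chrom", "pos"),
    names_to = c(".value", "population"),
    names_pattern = "(beta|se)_(.*)"
  )
  comb <- select(df, "id", "z", "p", "significant")
  left_join(long, comb, by = "id")
}

#' Summary of an association scan
#'
#' @param x An `mpgwas_gwas` tibble.
#' @param ... Unused.
#' @export
glance.mpgwas_gwas <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    n_tests = attr(x, "m_tests"),
    alpha = attr(x, "alpha"),
    bonferroni = attr(x, "bonferroni"),
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE))
  )
}

#' @export
print.mpgwas_gwas <- function(x, ...) {
  cat(sprintf(
    "<mpgwas_gwas:%s> %d SNPs tested, %d significant (Bonferroni %.3g)\n",
    attr(x, "mode"), sum(!is.na(x$p)), sum(x$significant, na.rm = TRUE),
    attr(x, "bonferroni")
  ))
  NextMethod()
}
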
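# Multivariate extensions of the plot model: the same trait in different
# populations, or two traits on shared plots, are treated as correlated
# responses. Additive effects covary through the (joint) genomic
# relationship matrix; GxE, spatial and line terms stay group-specific,
# and a residual covariance is included only when the two responses share
# plots (trait pairs), never across populations, which share no plots.

fit_grouped_lmm <- function(group_plots, ys, grm, group_lines,
                            spatial_mode = "none",
                            terms = c("additive", "line", "gxe"),
                            cross_error = FALSE, ...) {
  ng <- length(group_plots)
  groups <- names(group_plots)
  designs <- lapply(group_plots, build_design, spatial_mode = spatial_mode)
  n_g <- vapply(group_plots, nrow, integer(1))
  offsets <- cumsum(c(0, n_g))
  n <- sum(n_g)
  rows <- lapply(seq_len(ng), function(g) offsets[g] + seq_len(n_g[g]))

  # block-diagonal fixed effects
  X <- matrix(0, n, sum(vapply(designs, function(d) ncol(d$X), integer(1))))
  cn <- character(0)
  col0 <- 0
  for (g in seq_len(ng)) {
    Xg <- designs[[g]]$X
    X[rows[[g]], col0 + seq_len(ncol(Xg))] <- Xg
    cn <- c(cn, paste0(groups[g], ":", colnames(Xg)))
    col0 <- col0 + ncol(Xg)
  }
  colnames(X) <- cn

  G <- as.matrix(grm)
  place <- function(block, gi, gj) {
    M <- matrix(0, n, n)
    M[rows[[gi]], rows[[gj]]] <- as.matrix(block)
    if (gi != gj) M[rows[[gj]], rows[[gi]]] <- t(as.matrix(block))
    M
  }

  Vlist <- list()
  types <- character(0)
  q <- numeric(0)
  for (g in seq_len(ng)) {
    d <- designs[[g]]
    Gg <- G[group_lines[[g]], group_lines[[g]], drop = FALSE]
    nm <- paste0("additive.", groups[g])
    Vlist[[nm]] <- place(d$Z_line %*% Gg %*% t(as.matrix(d$Z_line)), g, g)
    types <- c(types, "variance")
    q <- c(q, setNames(length(d$lines), nm))
    if ("line" %in% terms) {
      nm <- paste0("line.", groups[g])
      Vlist[[nm]] <- place(Matrix::tcrossprod(d$Z_line), g, g)
      types <- c(types, "variance")
      q <- c(q, setNames(length(d$lines), nm))
    }
    if ("gxe" %in% terms) {
      nm <- paste0("gxe.", groups[g])
      Vlist[[nm]] <- place(Matrix::tcrossprod(d$Z_cell), g, g)
      types <- c(types, "variance")
      q <- c(q, setNames(length(d$cells), nm))
    }
    if ("spatial" %in% terms && !is.null(d$Zs)) {
      nm <- paste0("spatial.", groups[g])
      Vlist[[nm]] <- place(Matrix::tcrossprod(d$Zs), g, g)
      types <- c(types, "variance")
      q <- c(q, setNames(n_g[g], nm))
    }
    nm <- paste0("error.", groups[g])
    Vlist[[nm]] <- place(diag(n_g[g]), g, g)
    types <- c(types, "variance")
    q <- c(q, setNames(n_g[g], nm))
  }
  for (gi in seq_len(ng - 1)) {
    for (gj in seq(gi + 1, ng)) {
      di <- designs[[gi]]
      dj <- designs[[gj]]
      Gij <- G[group_lines[[gi]], group_lines[[gj]], drop = FALSE]
      nm <- paste0("cov_additive.", groups[gi], ".", groups[gj])
      Vlist[[nm]] <- place(di$Z_line %*% Gij %*% t(as.matrix(dj$Z_line)), gi, gj)
      types <- c(types, "covariance")
      q <- c(q, setNames(sqrt(length(di$lines) * length(dj$lines)), nm))
      if (cross_error) {
        if (n_g[gi] != n_g[gj]) abort("residual covariance needs shared plots")
        nm <- paste0("cov_error.", groups[gi], ".", groups[gj])
        Vlist[[nm]] <- place(diag(n_g[gi]), gi, gj)
        types <- c(types, "covariance")
        q <- c(q, setNames(n_g[gi], nm))
      }
    }
  }

  cov_pairs <- list()
  for (nm in names(Vlist)[types == "covariance"]) {
    parts <- strsplit(sub("^cov_", "", nm), ".", fixed = TRUE)[[1]]
    term <- parts[1]
    cov_pairs[[length(cov_pairs) + 1]] <- c(
      match(nm, names(Vlist)),
      match(paste0(term, ".", parts[2]), names(Vlist)),
      match(paste0(term, ".", parts[3]), names(Vlist))
    )
  }
  fit <- reml_fit(unlist(ys, use.names = FALSE), X, Vlist,
    types = types, q_levels = q, keep_vinv = TRUE, cov_pairs = cov_pairs, ...
  )
  structure(
    list(
      fit = fit, designs = designs, groups = groups, rows = rows,
      group_lines = group_lines, grm = grm, n = n
    ),
    class = "mpgwas_lmm_multi"
  )
}

#' @export
print.mpgwas_lmm_multi <- function(x, ...) {
  cat(sprintf(
    "<mpgwas_lmm_multi> %d groups (%s), %d observations\n",
    length(x$groups), paste(x$groups, collapse = ", "), x$n
  ))
  print(round(x$fit$theta, 6))
  invisible(x)
}

#' Multivariate plot model across populations
#'
#' Fits one response per population for a single trait, with additive
#' covariance between populations flowing through the cross-population
#' blocks of the joint genomic relationship matrix. Populations share no
#' plots, so no residual or GxE covariance is included.
#'
#' @param plots Plot records spanning the populations.
#' @param trait Trait column name.
#' @param grm Joint GRM over the lines of all included populations.
#' @param populations Character vector (>= 2) of population labels.
#' @inheritParams fit_plot_lmm
#' @return An `mpgwas_lmm_multi` object.
#' @export
fit_multipop_lmm <- function(plots, trait, grm, populations,
                             spatial_mode = "none",
                             terms = c("additive", "line", "gxe"), ...) {
  plots <- filter(as_tibble(plots), !is.na(.data[[trait]]),
                  .data$population %in% populations)
  group_plots <- lapply(populations, function(p) filter(plots, .data$population == p))
  names(group_plots) <- populations
  ys <- lapply(group_plots, function(d) d[[trait]])
  group_lines <- lapply(group_plots, function(d) sort(unique(d$line)))
  out <- fit_grouped_lmm(group_plots, ys, grm, group_lines,
    spatial_mode = spatial_mode, terms = terms, cross_error = FALSE, ...
  )
  out$trait <- trait
  out$group_plots <- group_plots
  out
}

#' Cross-population genetic correlation for one trait
#'
#' The same trait scored in two populations is modelled as two correlated
#' responses ([fit_multipop_lmm()]); the genetic correlation is the
#' additive covariance divided by the geometric mean of the two additive
#' variances, with a delta-method standard error. When either additive
#' variance is at the variance floor the correlation is undefined and
#' reported as `NA`.
#'
#' @inheritParams fit_multipop_lmm
#' @return A one-row tibble: `group1`, `group2`, `correlation`, `se`,
#'   `covariance`, `var1`, `var2`; the fitted model is attached as
#'   attribute `"fit"`.
#' @export
genetic_correlation_populations <- function(plots, trait, grm, populations,
                                            spatial_mode = "none",
                                            terms = c("additive", "line", "gxe"),
                                            ...) {
  if (length(populations) != 2) abort("exactly two populations required")
  m <- fit_multipop_lmm(plots, trait, grm, populations,
    spatial_mode = spatial_mode, terms = terms, ...
  )
  correlation_from_fit(m, populations)
}

#' Genetic correlation between two traits in one population
#'
#' Restricts the data to plots scored for both traits and fits a bivariate
#' plot model with additive covariance through the shared genomic
#' relationship matrix and a residual covariance between the traits.
#'
#' @param plots Plot records of one population.
#' @param traits Character vector of two trait column names.
#' @inheritParams fit_plot_lmm
#' @return As [genetic_correlation_populations()].
#' @export
genetic_correlation_traits <- function(plots, traits, grm,
                                       spatial_mode = "none",
                                       terms = c("additive", "line", "gxe"),
                                       ...) {
  if (length(traits) != 2) abort("exactly two traits required")
  plots <- as_tibble(plots)
  plots <- plots[complete.cases(plots[, traits]), ]
  if (nrow(plots) == 0) abort("no plots scored for both traits")
  group_plots <- list(plots, plots)
  names(group_plots) <- traits
  ys <- lapply(traits, function(tr) plots[[tr]])
  lines <- sort(unique(plots$line))
  m <- fit_grouped_lmm(group_plots, ys, grm, list(lines, lines),
    spatial_mode = spatial_mode, terms = terms, cross_error = TRUE, ...
  )
  correlation_from_fit(m, traits)
}

correlation_from_fit <- function(m, groups, floor = 1e-9) {
  th <- m$fit$theta
  v1 <- th[paste0("additive.", groups[1])]
  v2 <- th[paste0("additive.", groups[2])]
  cv <- th[paste0("cov_additive.", groups[1], ".", groups[2])]
  if (v1 <= floor || v2 <= floor) {
    r <- NA_real_
    se <- NA_real_
  } else {
    r <- max(min(cv / sqrt(v1 * v2), 1), -1)
    grad <- setNames(numeric(length(th)), names(th))
    grad[paste0("cov_additive.", groups[1], ".", groups[2])] <- 1 / sqrt(v1 * v2)
    grad[paste0("additive.", groups[1])] <- -r / (2 * v1)
    grad[paste0("additive.", groups[2])] <- -r / (2 * v2)
    S <- m$fit$theta_cov
    se <- if (anyNA(S)) NA_real_ else sqrt(drop(t(grad) %*% S %*% grad))
  }
  out <- tibble(
    group1 = groups[1], group2 = groups[2],
    correlation = unname(r), se = unname(se),
    covariance = unname(cv), var1 = unname(v1), var2 = unname(v2)
  )
  attr(out, "fit") <- m
  out
}
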
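# Plot-level mixed model:
#   y = X1 mu + X2 l + Z1 g_a + Z2 g_l + Z3 w + sum_j Zj s + e
# with g_a ~ N(0, G s2_ga), g_l ~ N(0, I s2_gl), w ~ N(0, I s2_w) on
# year x location x line cells, spatial effects s ~ N(0, I s2_s) summed
# over the 15-plot moving window, and e ~ N(0, I s2_e).

#' Build the design of the plot-level mixed model
#'
#' Constructs fixed-effect and random-effect incidence matrices from plot
#' records. Environments (year x location) are fixed effects nested within
#' population. In `"window15"` mode each plot row of the spatial incidence
#' sums the spatial effects of the occupied cells of a 5-column x 3-row
#' stencil centered on the plot, truncated at trial boundaries (at most 15
#' effects). In `"fixed_x"` mode (for trials without y-coordinates) the
#' x-coordinates within trials enter as independent fixed effects and
#' there is no spatial random term; `"none"` drops spatial modelling.
#'
#' @param plots Data frame of plot records with columns `line`,
#'   `population`, `year`, `location`, `trial`, `x`, `y`.
#' @param spatial_mode `"window15"`, `"fixed_x"`, or `"none"`.
#' @return A `mm_design` list: `X` (fixed effects), sparse incidences
#'   `Z_line`, `Z_cell`, `Zs` (or `NULL`), and the `lines` and `cells`
#'   level vectors.
#' @export
build_design <- function(plots, spatial_mode = c("window15", "fixed_x", "none")) {
  spatial_mode <- match.arg(spatial_mode)
  plots <- as_tibble(plots)
  need <- c("line", "population", "year", "location", "trial", "x")
  if (spatial_mode == "window15") need <- c(need, "y")
  missing_cols <- setdiff(need, names(plots))
  if (length(missing_cols) > 0) {
    abort(paste0("plot table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (spatial_mode == "window15") {
    key <- paste(plots$trial, plots$x, plots$y)
    if (anyDuplicated(key)) {
      abort(paste0(
        "duplicate plot coordinates (trial, x, y): ",
        paste(head(unique(key[duplicated(key)]), 3), collapse = "; ")
      ))
    }
  }
  env <- factor(paste(plots$population, plots$year, plots$location, sep = ":"))
  fixed <- tibble(env = env)
  if (spatial_mode == "fixed_x") {
    fixed$xcol <- factor(paste(plots$trial, plots$x, sep = ":"))
  }
  X <- if (nlevels(env) > 1 || spatial_mode == "fixed_x") {
    model.matrix(~., data = fixed)
  } else {
    matrix(1, nrow(plots), 1, dimnames = list(NULL, "(Intercept)"))
  }
  lines <- sort(unique(plots$line))
  Z_line <- Matrix::sparseMatrix(
    i = seq_len(nrow(plots)), j = match(plots$line, lines),
    x = 1, dims = c(nrow(plots), length(lines))
  )
  cell <- paste(plots$line, env, sep = "@")
  cells <- sort(unique(cell))
  Z_cell <- Matrix::sparseMatrix(
    i = seq_len(nrow(plots)), j = match(cell, cells),
    x = 1, dims = c(nrow(plots), length(cells))
  )
  Zs <- if (spatial_mode == "window15") spatial_incidence(plots) else NULL
  structure(
    list(
      X = X, Z_line = Z_line, Z_cell = Z_cell, Zs = Zs,
      lines = lines, cells = cells, env = env, spatial_mode = spatial_mode
    ),
    class = "mm_design"
  )
}

# covariance contributions of the model terms, as dense matrices
term_vlist <- function(design, G, terms) {
  n <- nrow(design$X)
  Vlist <- list()
  q <- numeric(0)
  if ("additive" %in% terms) {
    GZ <- G[, , drop = FALSE] %*% t(as.matrix(design$Z_line))
    Vlist$additive <- as.matrix(design$Z_line %*% GZ)
    q <- c(q, additive = length(design$lines))
  }
  if ("line" %in% terms) {
    Vlist$line <- as.matrix(Matrix::tcrossprod(design$Z_line))
    q <- c(q, line = length(design$lines))
  }
  if ("gxe" %in% terms) {
    Vlist$gxe <- as.matrix(Matrix::tcrossprod(design$Z_cell))
    q <- c(q, gxe = length(design$cells))
  }
  if ("spatial" %in% terms && !is.null(design$Zs)) {
    Vlist$spatial <- as.matrix(Matrix::tcrossprod(design$Zs))
    q <- c(q, spatial = n)
  }
  Vlist$error <- "identity"
  q <- c(q, error = n)
  list(Vlist = Vlist, q = q)
}

#' Fit the plot-level mixed model for one population set
#'
#' Estimates the five variance components of the plot model by AI-REML
#' (see [reml_fit()]) and reports them on both the raw and the adjusted
#' scale: the additive component is multiplied by the mean diagonal of the
#' genomic relationship matrix to account for inbreeding, and the spatial
#' component by 15 for the contribution of the 15 plots in the moving
#' window.
#'
#' @param plots Plot records (may span several populations, in which case
#'   environments are nested within population and a joint `grm` over all
#'   lines is required).
#' @param trait Name of the trait column.
#' @param grm Relationship matrix from [compute_grm()] covering every line
#'   in `plots`.
#' @param spatial_mode See [build_design()].
#' @param terms Random terms to include (default all four plus error).
#' @param ... Passed to [reml_fit()] (`tol`, `max_iter`, `init`, ...).
#' @return An `mpgwas_lmm` object: the underlying `fit` ([reml_fit()]),
#'   the `design`, `components` (tibble with raw and reported scales and
#'   their standard errors), `mean_diag_g`, `n_env` and `n_rep` (average
#'   replicates per line across environments).
#' @export
fit_plot_lmm <- function(plots, trait, grm,
                         spatial_mode = c("window15", "fixed_x", "none"),
                         terms = c("additive", "line", "gxe", "spatial"),
                         ...) {
  spatial_mode <- match.arg(spatial_mode)
  plots <- filter(as_tibble(plots), !is.na(.data[[trait]]))
  design <- build_design(plots, spatial_mode)
  lines <- design$lines
  miss <- setdiff(lines, rownames(grm))
  if (length(miss) > 0) {
    abort(paste0("GRM lacks line(s): ", paste(head(miss, 5), collapse = ", ")))
  }
  G <- as.matrix(grm)[lines, lines]
  tv <- term_vlist(design, G, terms)
  fit <- reml_fit(
    plots[[trait]], design$X, tv$Vlist,
    q_levels = tv$q, keep_vinv = TRUE, ...
  )
  md <- mean_diag(grm)
  spatial_mult <- if (spatial_mode == "window15" && "spatial" %in% names(fit$theta)) 15 else 1
  components <- adjust_components(
    setNames(fit$theta, names(fit$theta)),
    mean_diag_g = md, spatial_mult = spatial_mult,
    se = fit$theta_se
  )
  n_env <- length(unique(design$env))
  n_rep <- nrow(plots) / length(lines) / n_env
  structure(
    list(
      fit = fit, design = design, components = components,
      mean_diag_g = md, spatial_mult = spatial_mult,
      n_env = n_env, n_rep = n_rep, trait = trait,
      plots = plots, lines = lines, G_aligned = G, terms = terms
    ),
    class = "mpgwas_lmm"
  )
}

#' @export
print.mpgwas_lmm <- function(x, ...) {
  cat(sprintf(
    "<mpgwas_lmm> trait '%s': %d plots, %d lines, %d environment(s)\n",
    x$trait, nrow(x$plots), length(x$lines), x$n_env
  ))
  print(x$components)
  invisible(x)
}

#' @rdname fit_plot_lmm
#' @param x An `mpgwas_lmm` object.
#' @param ... Unused.
#' @export
tidy.mpgwas_lmm <- function(x, ...) x$components

#' @rdname fit_plot_lmm
#' @export
glance.mpgwas_lmm <- function(x, ...) {
  tibble(
    logLik = x$fit$loglik,
    iterations = x$fit$iterations,
    converged = x$fit$converged,
    n_plots = nrow(x$plots),
    n_lines = length(x$lines),
    n_env = x$n_env,
    n_rep = x$n_rep
  )
}
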
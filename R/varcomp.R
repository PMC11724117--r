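#' Reporting adjustments for variance components
#'
#' Raw REML estimates are adjusted for reporting: the additive genetic
#' variance (and its SE) is multiplied by the mean diagonal of the genomic
#' relationship matrix to account for inbreeding, and the per-plot spatial
#' variance (and its SE) is multiplied by the window size (15) because each
#' observation sums that many spatial effects. Raw values are retained:
#' the proportion of variance explained by a marker is defined against the
#' *raw* additive variance.
#'
#' @param theta Named numeric vector of raw components (names among
#'   `additive`, `line`, `gxe`, `spatial`, `error`).
#' @param mean_diag_g Mean diagonal of the relevant GRM.
#' @param spatial_mult Spatial window multiplier (15 for the moving-window
#'   model, 1 otherwise).
#' @param se Optional named vector of raw standard errors.
#' @return A tibble with columns `component`, `raw`, `reported`,
#'   `se_raw`, `se_reported`.
#' @export
adjust_components <- function(theta, mean_diag_g, spatial_mult = 15, se = NULL) {
  mult <- rep(1, length(theta))
  names(mult) <- names(theta)
  if ("additive" %in% names(theta)) mult["additive"] <- mean_diag_g
  if ("spatial" %in% names(theta)) mult["spatial"] <- spatial_mult
  tibble(
    component = names(theta),
    raw = unname(theta),
    reported = unname(theta * mult),
    se_raw = if (is.null(se)) NA_real_ else unname(se),
    se_reported = if (is.null(se)) NA_real_ else unname(se * mult)
  )
}

#' Broad- and narrow-sense heritability at plot and entry level
#'
#' Plot-level phenotypic variance is the sum of the five reported
#' components; at the entry (line-mean) level the GxE component is divided
#' by the number of environments `n_e` and the spatial and error
#' components by the average number of replicates per line `n_r`.
#' Broad-sense heritability is `(additive + line) / phenotypic`;
#' narrow-sense is `additive / phenotypic`. Standard errors, when a
#' covariance matrix of the reported components is supplied, use the
#' first-order delta method.
#'
#' @param components Tibble from [adjust_components()] (or any data frame
#'   with columns `component` and `reported`), or a named numeric vector of
#'   reported-scale components. Components `additive` and `error` are
#'   required; `line`, `gxe` and `spatial` default to 0 when absent.
#' @param n_e Number of environments (>= 1).
#' @param n_r Average number of replicate plots per line across all
#'   environments (>= 1).
#' @param vcov Optional covariance matrix of the reported components (rows
#'   and columns named by component) for delta-method SEs.
#' @return Tibble with one row per `level` (`"plot"`, `"entry"`):
#'   `var_phenotypic`, `H2`, `h2` and (if `vcov` given) `se_H2`, `se_h2`.
#' @export
heritability <- function(components, n_e, n_r, vcov = NULL) {
  v <- component_vector(components)
  if (n_e < 1 || n_r < 1) abort("`n_e` and `n_r` must be >= 1")
  lev <- list(
    plot = c(additive = 1, line = 1, gxe = 1, spatial = 1, error = 1),
    entry = c(additive = 1, line = 1, gxe = 1 / n_e, spatial = 1 / n_r, error = 1 / n_r)
  )
  out <- purrr::map_dfr(names(lev), function(level) {
    wts <- lev[[level]]
    sp <- sum(wts * v)
    if (sp <= 0) abort("phenotypic variance is zero")
    res <- tibble(
      level = level,
      var_phenotypic = unname(sp),
      H2 = unname((v["additive"] + v["line"]) / sp),
      h2 = unname(v["additive"] / sp)
    )
    if (!is.null(vcov)) {
      nm <- names(v)
      S <- matrix(0, 5, 5, dimnames = list(nm, nm))
      common <- intersect(nm, rownames(vcov))
      S[common, common] <- vcov[common, common]
      grad_ratio <- function(num_sel) {
        num <- sum(v[num_sel])
        (as.numeric(nm %in% num_sel) * sp - num * wts) / sp^2
      }
      gH <- grad_ratio(c("additive", "line"))
      gh <- grad_ratio("additive")
      res$se_H2 <- sqrt(drop(t(gH) %*% S %*% gH))
      res$se_h2 <- sqrt(drop(t(gh) %*% S %*% gh))
    }
    res
  })
  out
}

component_vector <- function(components) {
  full <- c(additive = 0, line = 0, gxe = 0, spatial = 0, error = 0)
  if (is.data.frame(components)) {
    vals <- setNames(components$reported, components$component)
  } else {
    vals <- components
  }
  unknown <- setdiff(names(vals), names(full))
  if (length(unknown) > 0) {
    abort(paste0("unknown component(s): ", paste(unknown, collapse = ", ")))
  }
  if (!all(c("additive", "error") %in% names(vals))) {
    abort("components must include at least `additive` and `error`")
  }
  full[names(vals)] <- vals
  full
}

#' Published variance components for four barley breeding populations
#'
#' Reported variance-component estimates (adjusted scale) for heading date
#' (days from May 1) and lodging (score 1-9) in four barley breeding
#' populations — two-row/six-row by winter/spring — used as worked-example
#' input for [heritability()]. Values as printed in the source study's
#' results table, trait units squared.
#'
#' @return Tibble with columns `population`, `trait`, `component`,
#'   `reported`.
#' @export
barley_varcomp <- function() {
  comp <- c("additive", "line", "gxe", "spatial", "error")
  rows <- list(
    list("6RW", "heading_date", c(3.80, 0.21, 1.20, 0.77, 0.49)),
    list("2RW", "heading_date", c(6.74, 7.11e-03, 3.51, 0.27, 1.78)),
    list("6RS", "heading_date", c(2.58, 4.13e-06, 0.82, 0.52, 0.98)),
    list("2RS", "heading_date", c(2.93, 0.32, 0.74, 0.24, 0.50)),
    list("6RW", "lodging", c(0.46, 2.37e-06, 0.79, 0.34, 0.65)),
    list("2RW", "lodging", c(0.35, 8.4e-03, 0.85, 0.32, 0.58)),
    list("6RS", "lodging", c(0.38, 5.4e-07, 0.24, 0.11, 0.42)),
    list("2RS", "lodging", c(0.79, 0.21, 1.06, 0.08, 1.10))
  )
  purrr::map_dfr(rows, function(r) {
    tibble(population = r[[1]], trait = r[[2]], component = comp, reported = r[[3]])
  })
}
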
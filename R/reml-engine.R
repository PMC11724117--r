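# Average-information REML for linear variance-component models
#
# The phenotypic covariance is linear in its parameters,
#   V(theta) = sum_k theta_k V_k,
# which covers every model in this package: univariate plot models
# (additive/line/GxE/spatial/error), bivariate trait models and
# cross-population models (where some theta_k are covariances whose V_k
# are symmetric cross blocks). Updates use the average-information matrix
# AI_jk = 1/2 * (V_j P y)' P (V_k P y) with expectation-maximisation
# fallback whenever an AI step leaves the parameter space or decreases
# the restricted likelihood.

#' Fit a linear variance-component model by AI-REML
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (rank-deficient columns are dropped
#'   after pivoted QR).
#' @param Vlist Named list of symmetric n x n matrices (dense, sparse, or
#'   `"identity"` for the residual term), one per parameter.
#' @param types Character vector, `"variance"` (constrained >= floor) or
#'   `"covariance"` (sign-free), one per parameter. Defaults to all
#'   variances.
#' @param q_levels Effective number of levels per parameter (used by the EM
#'   fallback); defaults to `n` for every term.
#' @param init Optional starting values; default splits the OLS residual
#'   variance equally over the variance terms.
#' @param tol Convergence tolerance on the relative change in restricted
#'   log-likelihood (default `1e-8`).
#' @param max_iter Iteration cap; exceeding it raises a diagnostic error
#'   carrying the likelihood trajectory.
#' @param floor Lower bound for variance parameters (default `1e-10`).
#' @param keep_vinv Keep the final `V^{-1}` and projections (needed for
#'   downstream single-SNP GLS scans; costs `n^2` memory).
#' @param cov_pairs Optional list of integer triples `c(cov, var1, var2)`
#'   tying a covariance parameter to its two variance parameters; the
#'   covariance is kept inside `0.999 * sqrt(var1 * var2)` so the
#'   corresponding block structure stays positive semi-definite and AI
#'   steps cannot leave the parameter space along the boundary.
#' @return An object of class `mpgwas_reml` with elements `theta`,
#'   `theta_se`, `theta_cov`, `beta`, `beta_cov`, `loglik`, `iterations`,
#'   `trajectory`, `converged`, and (if `keep_vinv`) `Vinv`, `VinvX`,
#'   `XtViX`, `Py`, `X`, `y`.
#' @export
reml_fit <- function(y, X, Vlist, types = NULL, q_levels = NULL, init = NULL,
                     tol = 1e-8, max_iter = 100, floor = 1e-10,
                     keep_vinv = FALSE, cov_pairs = NULL) {
  n <- length(y)
  K <- length(Vlist)
  if (is.null(names(Vlist))) names(Vlist) <- paste0("vc", seq_len(K))
  types <- types %n% rep("variance", K)
  q_levels <- q_levels %n% rep(n, K)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  p <- ncol(X)
  Vk <- lapply(Vlist, function(v) {
    if (identical(v, "identity")) "identity" else as.matrix(v)
  })

  is_ident <- vapply(Vk, function(v) identical(v, "identity"), logical(1))
  mats <- lapply(Vk, function(v) if (identical(v, "identity")) NULL else v)
  assemble_V <- function(theta) {
    .weighted_mat_sum(mats, theta, sum(theta[is_ident]), n)
  }
  # loglik and GLS byproducts at theta; NULL if V not PD. The explicit
  # V^-1 (needed only for trace terms of accepted states) is deferred:
  # candidate evaluations during step-halving use triangular solves.
  vsolve <- function(ch, M) backsolve(ch, backsolve(ch, M, transpose = TRUE))
  eval_theta <- function(theta, need_vinv = FALSE) {
    V <- assemble_V(theta)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    VinvX <- vsolve(ch, X)
    XtViX <- crossprod(X, VinvX)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    beta <- drop(chol2inv(chx) %*% crossprod(VinvX, y))
    r <- y - drop(X %*% beta)
    Py <- drop(vsolve(ch, r))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + sum(r * Py))
    st <- list(ch = ch, Vinv = NULL, VinvX = VinvX, XtViX = XtViX, chx = chx,
               beta = beta, Py = Py, loglik = ll)
    if (need_vinv) st$Vinv <- chol2inv(ch)
    st
  }
  ensure_vinv <- function(st) {
    if (is.null(st$Vinv)) st$Vinv <- chol2inv(st$ch)
    st
  }
  # P %*% M for a column matrix M, given state
  apply_P <- function(st, M) {
    VM <- st$Vinv %*% M
    VM - st$VinvX %*% (chol2inv(st$chx) %*% crossprod(st$VinvX, M))
  }

  clamp_cov <- function(cand) {
    for (cp in cov_pairs) {
      bound <- 0.999 * sqrt(cand[cp[2]] * cand[cp[3]])
      cand[cp[1]] <- pmin(pmax(cand[cp[1]], -bound), bound)
    }
    cand
  }

  ols_res <- qr.resid(qr(X), y)
  v0 <- sum(ols_res^2) / max(1, n - p)
  if (v0 < 1e-12) {
    # degenerate: response fully explained by fixed effects
    theta <- setNames(ifelse(types == "variance", floor, 0), names(Vlist))
    st <- eval_theta(theta, need_vinv = keep_vinv)
    return(reml_result(theta, st, Vlist, diag(NA_real_, K), 0,
                       numeric(0), TRUE, keep_vinv, X, y, Vk))
  }
  n_var <- sum(types == "variance")
  theta <- init %n% ifelse(types == "variance", v0 / n_var, 0)
  theta <- clamp_cov(theta)
  names(theta) <- names(Vlist)

  st <- eval_theta(theta)
  if (is.null(st)) abort("initial covariance matrix not positive definite")
  st <- ensure_vinv(st)
  trajectory <- st$loglik
  converged <- max_iter == 0 # max_iter = 0: evaluate at `init` and stop
  stall <- 0L
  AI <- diag(K)

  for (iter in seq_len(max_iter)) {
    # score and AI at current theta
    W <- matrix(0, n, K) # V_k P y
    score <- numeric(K)
    for (k in seq_len(K)) {
      if (identical(Vk[[k]], "identity")) {
        W[, k] <- st$Py
        trVinvVk <- sum(diag(st$Vinv))
        B <- crossprod(st$VinvX) # X' Vinv I Vinv X
      } else {
        M <- Vk[[k]]
        W[, k] <- as.numeric(M %*% st$Py)
        trVinvVk <- .trace_hadamard(st$Vinv, M)
        B <- crossprod(st$VinvX, M %*% st$VinvX)
      }
      trPVk <- trVinvVk - sum(chol2inv(st$chx) * B)
      score[k] <- -0.5 * (trPVk - sum(st$Py * W[, k]))
    }
    PW <- apply_P(st, W)
    AI <- 0.5 * crossprod(W, PW)

    # AI step on transformed parameters: log scale for variances (keeps
    # them positive and conditions the information matrix), linear for
    # covariances; chain rule maps score and AI to the transformed scale
    dscale <- ifelse(types == "variance", pmax(theta, floor), 1)
    delta_t <- ai_solve(dscale * AI * rep(dscale, each = K), dscale * score)
    if (!is.null(delta_t)) {
      delta_t <- pmin(pmax(delta_t, -3), 3) # cap log-scale moves
    }
    em_step <- 2 * theta^2 * score / q_levels
    em_step[types == "covariance"] <- 0

    apply_step <- function(step_t) {
      cand <- theta
      v <- types == "variance"
      cand[v] <- pmax(theta[v] * exp(step_t[v]), floor)
      cand[!v] <- theta[!v] + step_t[!v]
      clamp_cov(cand)
    }
    # accept the first step (AI, then halved, then EM) that stays in the
    # parameter space and does not decrease the restricted likelihood
    accepted <- NULL
    if (!is.null(delta_t)) {
      step <- delta_t
      for (half in 0:12) {
        cand <- apply_step(step)
        st_cand <- eval_theta(cand)
        if (!is.null(st_cand) && st_cand$loglik >= st$loglik - 1e-10) {
          accepted <- list(theta = cand, st = st_cand, ai_step = half == 0)
          break
        }
        step <- step / 2
      }
    }
    if (is.null(accepted)) {
      cand <- theta + em_step
      cand[types == "variance"] <- pmax(cand[types == "variance"], floor)
      cand <- clamp_cov(cand)
      st_cand <- eval_theta(cand)
      if (!is.null(st_cand) && st_cand$loglik >= st$loglik - 1e-10) {
        accepted <- list(theta = cand, st = st_cand, ai_step = FALSE)
      }
    }
    if (is.null(accepted)) break # no admissible improvement: treat as converged

    ll_old <- st$loglik
    theta <- accepted$theta
    st <- ensure_vinv(accepted$st)
    trajectory <- c(trajectory, st$loglik)
    rel <- abs(st$loglik - ll_old) / (abs(ll_old) + 1e-10)
    if (rel < tol) {
      converged <- TRUE
      break
    }
    # stagnation: several consecutive near-converged iterations whose
    # steps no longer move the likelihood meaningfully
    stall <- if (rel < 100 * tol) stall + 1L else 0L
    if (stall >= 5L) {
      converged <- TRUE
      break
    }
  }
  if (!converged && length(trajectory) >= max_iter) {
    abort(paste0(
      "AI-REML did not converge in ", max_iter, " iterations; ",
      "log-likelihood trajectory: ",
      paste(sprintf("%.6f", tail(trajectory, 8)), collapse = " -> ")
    ), class = "mpgwas_reml_nonconvergence", trajectory = trajectory)
  }
  reml_result(theta, st, Vlist, AI, length(trajectory) - 1, trajectory,
              TRUE, keep_vinv, X, y, Vk)
}

# solve AI %*% delta = score through an eigen pseudo-inverse so that
# confounded directions (singular AI) are simply not moved along
ai_solve <- function(AI, score) {
  es <- eigen((AI + t(AI)) / 2, symmetric = TRUE)
  pos <- es$values > max(es$values, 0) * 1e-10
  if (!any(pos)) return(NULL)
  U <- es$vectors[, pos, drop = FALSE]
  drop(U %*% (crossprod(U, score) / es$values[pos]))
}

reml_result <- function(theta, st, Vlist, AI, iterations, trajectory,
                        converged, keep_vinv, X, y, Vk = NULL) {
  theta_cov <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  dimnames(theta_cov) <- list(names(Vlist), names(Vlist))
  out <- list(
    theta = setNames(theta, names(Vlist)),
    theta_se = sqrt(pmax(diag(theta_cov), 0)),
    theta_cov = theta_cov,
    beta = st$beta,
    beta_cov = chol2inv(st$chx),
    loglik = st$loglik,
    iterations = iterations,
    trajectory = trajectory,
    converged = converged
  )
  if (keep_vinv) {
    if (is.null(st$Vinv)) st$Vinv <- chol2inv(st$ch)
    out$Vinv <- st$Vinv
    out$VinvX <- st$VinvX
    out$XtViX <- st$XtViX
    out$Py <- st$Py
    out$X <- X
    out$y <- y
    if (!is.null(Vk)) {
      # fitted random contributions Z_k u_k = theta_k V_k P y per term
      rc <- vapply(seq_along(Vk), function(k) {
        if (identical(Vk[[k]], "identity")) {
          theta[k] * st$Py
        } else {
          theta[k] * as.numeric(Vk[[k]] %*% st$Py)
        }
      }, numeric(length(y)))
      colnames(rc) <- names(Vlist)
      out$random_contrib <- rc
    }
  }
  structure(out, class = "mpgwas_reml")
}

#' @export
print.mpgwas_reml <- function(x, ...) {
  cat(sprintf(
    "<mpgwas_reml> %d parameter(s), logLik %.4f, %d iteration(s)%s\n",
    length(x$theta), x$loglik, x$iterations,
    if (x$converged) "" else " (not converged)"
  ))
  print(round(x$theta, 6))
  invisible(x)
}

#' @rdname reml_fit
#' @param x A fitted `mpgwas_reml` object.
#' @param ... Unused.
#' @export
tidy.mpgwas_reml <- function(x, ...) {
  tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = unname(x$theta_se)
  )
}

#' @rdname reml_fit
#' @export
glance.mpgwas_reml <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    n_parameters = length(x$theta),
    iterations = x$iterations,
    converged = x$converged
  )
}
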
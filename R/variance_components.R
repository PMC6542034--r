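# Variance-component estimation by average-information REML with EM
# fallback, the fixed-effect design (herd, parity, Wilmink lactation
# curve), and the heritability / microbiability ratios with delta-method
# standard errors.

VC_LOWER_BOUND <- 1e-9

#' Fixed-effects design matrix for milk traits
#'
#' Columns: intercept, herd indicator contrasts (levels - 1), parity
#' contrasts (levels - 1), `dim` (days in milk, linear) and the Wilmink
#' lactation-curve term `exp(-0.05 * dim)`.  The -0.05 decay constant is
#' fixed, the convention for lactation-stage adjustment of milk records.
#'
#' @param pheno phenotype data frame with `animal_id`, `herd`, `parity`,
#'   `dim`.
#' @return numeric matrix with animal ids as rownames; errors if the design
#'   is rank deficient (e.g. an empty herd level left an all-zero
#'   contrast).
#' @export
build_design_matrix <- function(pheno) {
  pheno <- as_phenotype_records(pheno)
  herd <- factor(pheno$herd)
  parity <- factor(pheno$parity)
  df <- data.frame(herd = herd, parity = parity, dim = pheno$dim,
                   wilmink = exp(-0.05 * pheno$dim))
  terms <- c(if (nlevels(herd) > 1) "herd",
             if (nlevels(parity) > 1) "parity",
             "dim", "wilmink")
  X <- stats::model.matrix(stats::reformulate(terms), df)
  rownames(X) <- pheno$animal_id
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  if (qr(X)$rank < ncol(X))
    stop_config("design matrix is rank deficient (%d columns, rank %d)",
                ncol(X), qr(X)$rank)
  X
}

#' REML variance components for one or more relationship kernels
#'
#' Fits `y = X b + sum_k u_k + e` with `u_k ~ N(0, K_k s_k^2)` and
#' `e ~ N(0, I s_e^2)` by maximizing the restricted likelihood.  Updates
#' are average-information (AI) steps; an AI step that would leave the
#' feasible region or decrease the restricted log-likelihood is halved up
#' to 10 times and then replaced by an EM step, which always ascends.
#' Each variance is bounded below by `1e-9`; estimates pinned there are
#' flagged as boundary solutions.
#'
#' @param y numeric trait vector named by animal id (or aligned with `X`);
#'   animals with missing `y` are dropped from all inputs first.
#' @param X fixed-effects design matrix (full column rank), e.g. from
#'   [build_design_matrix()]; a bare intercept is used if `NULL`.
#' @param kernels a single [rel_matrix()] or a named list of them.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance: maximum relative parameter change
#'   (default 1e-8).
#' @param verbose print per-iteration log-likelihoods.
#' @return an object of class `vc_fit`: list with `sigma2` (named vector
#'   including `residual`), `ai_matrix`, `loglik_reml`, `converged`,
#'   `identifiable` (`FALSE`, with a warning, when the information matrix
#'   is numerically singular, as when a kernel is confounded with the
#'   residual), `n_iterations`, `boundary` (named logical), `beta` (GLS
#'   fixed effects), `ids`, `kernel_names`.
#' @export
reml_fit <- function(y, X = NULL, kernels, max_iter = 200L, tol = 1e-8,
                     verbose = FALSE) {
  if (inherits(kernels, "rel_matrix")) kernels <- list(kernels)
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- vapply(kernels, kernel_kind, character(1L))
  check_ids(names(kernels), "kernel")

  ids <- names(y) %||% rownames(X) %||% rownames(kernels[[1L]])
  if (is.null(ids)) stop_config("cannot align inputs: no animal ids found")
  if (length(y) != length(ids)) stop_config("`y` and ids have different lengths")
  keep <- !is.na(y)
  ids <- ids[keep]
  y <- as.numeric(y[keep])
  n <- length(y)
  if (n < 3L) stop_config("need at least 3 non-missing observations")
  if (is.null(X)) {
    X <- matrix(1, n, 1L, dimnames = list(ids, "(Intercept)"))
  } else {
    X <- X[ids, , drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) stop_config("design matrix is singular")
  Ks <- lapply(kernels, function(K) unclass(align_kernel(K, ids)))
  k <- length(Ks)
  comp <- c(names(Ks), "residual")
  Klist <- c(Ks, list(diag(n)))

  # start: split the OLS residual variance evenly across components
  r0 <- stats::lm.fit(X, y)$residuals
  v0 <- stats::var(r0)
  if (v0 <= 0) v0 <- VC_LOWER_BOUND        # y exactly in span(X): degenerate
  theta <- rep(v0 / (k + 1), k + 1L)
  names(theta) <- comp

  eval_state <- function(theta) {
    V <- matrix(0, n, n)
    for (j in seq_along(Klist)) V <- V + theta[j] * Klist[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - W %*% chol2inv(chx) %*% t(W)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, loglik = ll)
  }

  st <- eval_state(theta)
  if (is.null(st)) stop_config("initial covariance matrix is singular")
  converged <- FALSE
  iter <- 0L
  ai <- NULL

  for (iter in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(Klist, function(K) drop(K %*% Py))
    PK <- lapply(Klist, function(K) P %*% K)
    grad <- vapply(seq_along(Klist), function(j) {
      -0.5 * (sum(diag(PK[[j]])) - sum(Py * KPy[[j]]))
    }, numeric(1L))
    ai <- matrix(0, k + 1L, k + 1L, dimnames = list(comp, comp))
    PKPy <- lapply(KPy, function(v) drop(P %*% v))
    for (a in seq_along(Klist))
      for (b in a:length(Klist))
        ai[a, b] <- ai[b, a] <- 0.5 * sum(KPy[[a]] * PKPy[[b]])

    # Active set: components pinned at the lower bound whose gradient
    # points further down are held fixed; the AI system is solved on the
    # free components only (a pinned component re-enters as soon as its
    # gradient turns positive).
    free <- !(theta <= VC_LOWER_BOUND * (1 + 1e-6) & grad < 0)
    if (!any(free)) {
      converged <- TRUE
      break
    }
    delta <- rep(0, k + 1L)
    delta_free <- tryCatch(
      solve(ai[free, free, drop = FALSE], grad[free]),
      error = function(e) NULL)
    new_theta <- NULL; new_st <- NULL
    if (!is.null(delta_free)) {
      delta[free] <- delta_free
      step <- 1
      for (h in 1:10) {
        cand <- pmax(theta + step * delta, VC_LOWER_BOUND)
        cst <- eval_state(cand)
        if (!is.null(cst) && cst$loglik >= st$loglik - 1e-12) {
          new_theta <- cand; new_st <- cst
          break
        }
        step <- step / 2
      }
    }
    if (is.null(new_theta)) {
      # EM step: theta_j <- theta_j + theta_j^2 (y'PKPy - tr(PK)) / n
      cand <- vapply(seq_along(Klist), function(j) {
        if (!free[j]) return(theta[j])
        theta[j] + theta[j]^2 * (sum(Py * KPy[[j]]) -
                                   sum(diag(PK[[j]]))) / n
      }, numeric(1L))
      cand <- pmax(cand, VC_LOWER_BOUND)
      names(cand) <- comp
      cst <- eval_state(cand)
      if (is.null(cst)) break
      new_theta <- cand; new_st <- cst
    }
    names(new_theta) <- comp
    rel_change <- max(abs(new_theta - theta) / pmax(abs(theta), VC_LOWER_BOUND))
    theta <- new_theta
    st <- new_st
    if (verbose)
      message(sprintf("iter %3d  logL %.8f  max rel change %.3e",
                      iter, st$loglik, rel_change))
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge within ", max_iter, " iterations",
            call. = FALSE)
  identifiable <- TRUE
  if (!is.null(ai) && rcond(ai) < 1e-10) {
    identifiable <- FALSE
    warning("flat restricted likelihood: variance components are not ",
            "separately identifiable (singular information matrix)",
            call. = FALSE)
  }

  # GLS fixed effects at the optimum
  V <- matrix(0, n, n)
  for (j in seq_along(Klist)) V <- V + theta[j] * Klist[[j]]
  Vinv <- chol2inv(chol(V))
  XtVX <- crossprod(X, Vinv %*% X)
  Xty <- crossprod(X, Vinv %*% y)
  beta <- drop(tryCatch(solve(XtVX, Xty),
                        error = function(e) MASS::ginv(XtVX) %*% Xty))
  names(beta) <- colnames(X)

  structure(list(
    sigma2 = theta, ai_matrix = ai, loglik_reml = st$loglik,
    converged = converged, identifiable = identifiable,
    n_iterations = iter,
    boundary = theta <= VC_LOWER_BOUND * (1 + 1e-6),
    beta = beta, ids = ids, kernel_names = names(Ks)
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> REML variance components\n")
  print(round(x$sigma2, 6))
  cat(sprintf("logL = %.4f, %s in %d iterations\n", x$loglik_reml,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Heritability / microbiability ratio with standard error
#'
#' `h^2 = s_c^2 / (s_c^2 + s_e^2)` for a chosen component `c` against the
#' residual, the per-model ratio definition used for both the genomic
#' heritability (G kernel) and the microbiability (M kernel).  The SE comes
#' from the delta method on the inverse average-information matrix:
#' `se^2 = g' AI^{-1} g` with gradient
#' `g = (s_e^2, -s_c^2) / (s_c^2 + s_e^2)^2`.
#'
#' @param fit a [reml_fit()] result.
#' @param component name of the kernel component (default: the first).
#' @return list of class `ratio_estimate`: `name`, `value`, `se`,
#'   `boundary` (TRUE if the component variance sits at its lower bound).
#' @export
variance_ratio <- function(fit, component = fit$kernel_names[1L]) {
  if (!inherits(fit, "vc_fit")) stop_config("`fit` must come from reml_fit()")
  if (!component %in% names(fit$sigma2))
    stop_config("component '%s' not in fit", component)
  s_c <- fit$sigma2[[component]]
  s_e <- fit$sigma2[["residual"]]
  tot <- s_c + s_e
  if (tot <= 0) stop_config("sum of component and residual variance is 0")
  value <- s_c / tot

  idx <- match(c(component, "residual"), names(fit$sigma2))
  grad <- numeric(length(fit$sigma2))
  grad[idx] <- c(s_e, -s_c) / tot^2
  ai_inv <- tryCatch(solve(fit$ai_matrix), error = function(e)
    MASS::ginv(fit$ai_matrix))
  se2 <- drop(crossprod(grad, ai_inv %*% grad))
  structure(list(name = component, value = value,
                 se = sqrt(max(se2, 0)),
                 boundary = fit$boundary[[component]]),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%s ratio = %.4f (SE %.4f)%s\n", x$name, x$value, x$se,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Profile-REML oracle over the variance ratio (single kernel)
#'
#' Independent check of [reml_fit()] for one-kernel models.  For each
#' candidate ratio `lambda = s_k^2 / s_e^2`, `V0 = lambda K + I`; the
#' restricted likelihood is profiled analytically over the overall scale
#' and the fixed effects, using one eigendecomposition of `K` so each grid
#' point costs O(n p^2).  The grid argmax is refined by golden-section
#' search on log(lambda) between its neighbours.
#'
#' @param y trait vector (no missing values).
#' @param X design matrix (or `NULL` for intercept only).
#' @param kernel a single [rel_matrix()] aligned with `y`.
#' @param ratio_grid positive candidate ratios (default `10^seq(-4, 4, 0.1)`).
#' @param refine golden-section refinement of the argmax (default TRUE).
#' @return list: `lambda` (best ratio), `sigma2_k`, `sigma2_e`, `grid`,
#'   `loglik` (profile restricted log-likelihood per grid point).
#' @export
profile_reml_oracle <- function(y, X = NULL, kernel,
                                ratio_grid = 10^seq(-4, 4, by = 0.1),
                                refine = TRUE) {
  ids <- names(y) %||% rownames(kernel)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  p <- ncol(X)
  K <- unclass(align_kernel(kernel, ids[seq_len(n)]))
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ystar <- drop(crossprod(eg$vectors, y))
  Xstar <- crossprod(eg$vectors, X)

  prof_ll <- function(lambda) {
    w <- 1 / (lambda * d + 1)
    XtWX <- crossprod(Xstar, w * Xstar)
    chx <- chol(XtWX)
    bhat <- backsolve(chx, forwardsolve(t(chx), crossprod(Xstar, w * ystar)))
    rss <- sum(w * (ystar - drop(Xstar %*% bhat))^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(lambda * d + 1)) +
              2 * sum(log(diag(chx))) + (n - p))
  }

  ll <- vapply(ratio_grid, prof_ll, numeric(1L))
  best <- which.max(ll)
  lambda <- ratio_grid[best]
  if (refine && length(ratio_grid) > 1L) {
    lo <- log(ratio_grid[max(best - 1L, 1L)])
    hi <- log(ratio_grid[min(best + 1L, length(ratio_grid))])
    if (hi > lo) {
      opt <- stats::optimize(function(lg) prof_ll(exp(lg)),
                             interval = c(lo, hi), maximum = TRUE,
                             tol = 1e-10)
      lambda <- exp(opt$maximum)
    }
  }
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xstar, w * Xstar)
  bhat <- solve(XtWX, crossprod(Xstar, w * ystar))
  s2e <- sum(w * (ystar - drop(Xstar %*% bhat))^2) / (n - p)
  list(lambda = lambda, sigma2_k = lambda * s2e, sigma2_e = s2e,
       grid = ratio_grid, loglik = ll)
}

#' Microbiability / heritability table across traits
#'
#' Fits the single-kernel REML model (fixed herd/parity/Wilmink effects
#' plus one relationship kernel) separately with the genomic and the
#' microbial kernel for each trait, and tabulates the variance ratios with
#' their standard errors — the shape of a classic
#' heritability/microbiability results table.
#'
#' @param pheno phenotype data frame.
#' @param G,M [rel_matrix()] kernels (either may be `NULL` to skip).
#' @param traits trait columns (default: all).
#' @return data frame: `trait`, `h2_g`, `se_g`, `boundary_g`, `h2_B`,
#'   `se_B`, `boundary_B` (columns present only for supplied kernels).
#' @export
microbiability_table <- function(pheno, G = NULL, M = NULL, traits = NULL) {
  pheno <- as_phenotype_records(pheno)
  traits <- traits %||% trait_columns(pheno)
  X <- build_design_matrix(pheno)
  rows <- lapply(traits, function(tr) {
    y <- stats::setNames(pheno[[tr]], pheno$animal_id)
    row <- data.frame(trait = tr)
    if (!is.null(G)) {
      fg <- reml_fit(y, X, list(G = G))
      rg <- variance_ratio(fg, "G")
      row$h2_g <- rg$value; row$se_g <- rg$se; row$boundary_g <- rg$boundary
    }
    if (!is.null(M)) {
      fm <- reml_fit(y, X, list(M = M))
      rm_ <- variance_ratio(fm, "M")
      row$h2_B <- rm_$value; row$se_B <- rm_$se; row$boundary_B <- rm_$boundary
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
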
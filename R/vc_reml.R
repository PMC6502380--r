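#' Connected components of a covariance sparsity pattern
#'
#' Individuals belong to the same block when they are connected through
#' nonzero entries of any of the supplied matrices (e.g. kinship and locus
#' IBD); the REML likelihood then factorizes over blocks.
#'
#' @param ... square matrices of identical dimension
#' @param tol entries with absolute value below `tol` count as zero
#' @return list of integer index vectors, one per block
#' @export
matrix_blocks <- function(..., tol = 1e-12) {
  mats <- list(...)
  mats <- Filter(Negate(is.null), mats)
  n <- nrow(mats[[1]])
  adj <- matrix(FALSE, n, n)
  for (M in mats) adj <- adj | (abs(M) > tol)
  seen <- rep(FALSE, n)
  blocks <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    blocks[[length(blocks) + 1L]] <- sort(comp)
  }
  blocks
}

check_psd <- function(M, name, tol = 1e-6) {
  ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol * max(1, max(abs(M))))
    stop_ctx("%s is not positive semidefinite (min eigenvalue %.3g)",
             name, ev)
}

build_vc_blocks <- function(y, X, G, Z, blocks) {
  lapply(blocks, function(idx) {
    blk <- list(y = y[idx], X = X[idx, , drop = FALSE],
                G = G[idx, idx, drop = FALSE])
    if (!is.null(Z)) blk$Z <- Z[idx, idx, drop = FALSE]
    blk
  })
}

vc_objective <- function(par, cblocks, has_z) {
  as.numeric(.vc_reml_eval(par, cblocks, has_z)$nll)
}

#' REML fit of a variance-component model with given covariance structures
#'
#' Fits y = X b + a (+ q) + e with cov(a) = s2a * G, cov(q) = s2q * Z and
#' iid residuals, by restricted maximum likelihood. The residual variance
#' is profiled out and the variance ratios are optimized on the log scale
#' with an explicit lower bound standing in for the zero boundary; the
#' likelihood factorizes over the blocks of the combined sparsity pattern.
#'
#' @param y response vector
#' @param X fixed-effect design matrix (full column rank)
#' @param G polygenic covariance (additive relationship) matrix
#' @param Z optional locus IBD matrix; omit for the no-QTL model
#' @param blocks optional precomputed [matrix_blocks] result
#' @param check check PSD of G and Z (skip inside scans for speed)
#' @param starts optional matrix of optimizer starting values (log ratios)
#' @return object of class `vc_fit`: `loglik` (REML), `s2a`, `s2q`, `s2e`,
#'   `beta`, `par` (log ratios), `convergence`
#' @export
fit_vc_model <- function(y, X, G, Z = NULL, blocks = NULL, check = TRUE,
                         starts = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(G) == n)
  if (!is.null(Z)) stopifnot(nrow(Z) == n)
  if (check) {
    check_psd(G, "G")
    if (!is.null(Z)) check_psd(Z, "Z")
  }
  if (qr(X)$rank < ncol(X))
    stop_ctx("fit_vc_model: fixed design is rank deficient")
  if (is.null(blocks)) blocks <- matrix_blocks(G, Z)
  cblocks <- build_vc_blocks(y, X, G, Z, blocks)
  lower <- -15; upper <- 8
  if (is.null(starts))
    starts <- rbind(c(log(0.5), -6), c(-6, log(0.3)), c(log(0.5), log(0.5)))
  res <- .vc_reml_fit(cblocks, !is.null(Z), starts, lower, upper)
  if (!is.finite(res$loglik)) stop_ctx("fit_vc_model: optimization failed")
  par <- res$par
  zero_tol <- exp(lower + 1)
  s2a <- if (exp(par[1]) <= zero_tol) 0 else res$s2a
  s2q <- if (is.null(Z)) 0 else if (exp(par[2]) <= zero_tol) 0 else res$s2q
  structure(list(loglik = res$loglik, s2a = s2a, s2q = s2q, s2e = res$s2e,
                 beta = as.numeric(res$beta), par = par,
                 blocks = blocks, has_qtl = !is.null(Z)),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> REML logLik %.3f | s2a = %.4g, s2q = %.4g, s2e = %.4g\n",
              x$loglik, x$s2a, x$s2q, x$s2e))
  invisible(x)
}

#' Fit the no-QTL and QTL variance-component models at one locus
#'
#' Model 0: polygenic effect (covariance `s2a * G`) plus residual.
#' Model 1: adds a locus-specific random effect with covariance `s2q * Z`.
#' Their REML likelihoods feed the boundary-corrected likelihood-ratio
#' test: LRT = 2(logL1 - logL0) clipped at zero, with p-value from the
#' 50:50 mixture of chi-square(0) and chi-square(1).
#'
#' @inheritParams fit_vc_model
#' @param Z locus IBD matrix
#' @return list with `fit0`, `fit1`, `lrt`, `p_value`
#' @export
fit_qtl_models <- function(y, X, G, Z, blocks = NULL, check = TRUE) {
  if (is.null(blocks)) blocks <- matrix_blocks(G, Z)
  fit0 <- fit_vc_model(y, X, G, NULL, blocks = blocks, check = check)
  fit1 <- fit_vc_model(y, X, G, Z, blocks = blocks, check = check)
  lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
  list(fit0 = fit0, fit1 = fit1, lrt = lrt,
       p_value = boundary_mixture_p(lrt))
}

#' P-value of a variance-component LRT at the boundary
#'
#' Null distribution taken as the 50:50 mixture of a point mass at zero
#' and chi-square with 1 df.
#'
#' @param lrt likelihood-ratio statistic(s)
#' @return p-value(s)
#' @export
boundary_mixture_p <- function(lrt) {
  ifelse(lrt <= 1e-10, 1, 0.5 * pchisq(lrt, 1, lower.tail = FALSE))
}

#' Proportion of phenotypic variance attributed to the QTL
#' @param fit1 a QTL-model `vc_fit`
#' @return `s2q / (s2q + s2a + s2e)`
#' @export
qtl_variance_proportion <- function(fit1) {
  fit1$s2q / (fit1$s2q + fit1$s2a + fit1$s2e)
}
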
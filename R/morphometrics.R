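#' Kype length and height from a specimen's measurement points
#'
#' Kype length is the Euclidean distance from the most anterior point of
#' the lower jaw (k1) to the bottom of the gill plate (k2); kype height runs
#' from the dorsal peak of the hook (k3) to the ventral point on the lower
#' jaw where curvature begins (k4). When no curvature point was digitized,
#' the point directly beneath the dorsal peak is used: the vertical
#' projection of k3 onto the lower-jaw segment k1-k2. Coordinates are
#' already in cm (scale applied on read), so distances are cm.
#'
#' @param config a [landmark_config] carrying kype points
#' @return named numeric `c(kype_length=, kype_height=)`; `kype_height` is
#'   `NA` when the hook peak is missing (obscured mouth), both are `NA` when
#'   no kype points were digitized
#' @export
measure_kype <- function(config) {
  stopifnot(inherits(config, "landmark_config"))
  kp <- config$kype_points
  if (is.null(kp))
    return(c(kype_length = NA_real_, kype_height = NA_real_))
  kl <- sqrt(sum((kp[1, ] - kp[2, ])^2))
  if (anyNA(kp[3, ])) {
    kh <- NA_real_
  } else if (anyNA(kp[4, ])) {
    # fallback: vertical drop from the hook peak onto the jaw segment
    dx <- kp[2, 1] - kp[1, 1]
    if (abs(dx) < 1e-12)
      stop_ctx("specimen '%s': lower-jaw segment is vertical; cannot project",
               config$specimen_id)
    ty <- kp[1, 2] + (kp[3, 1] - kp[1, 1]) / dx * (kp[2, 2] - kp[1, 2])
    kh <- abs(kp[3, 2] - ty)
  } else {
    kh <- sqrt(sum((kp[3, ] - kp[4, ])^2))
  }
  c(kype_length = kl, kype_height = kh)
}

# Optimal rotation (det +1, no reflection) aligning X onto target M.
kabsch_rotation <- function(X, M) {
  C <- crossprod(X, M)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis of landmark configurations
#'
#' Centers every configuration, scales it to unit centroid size, and
#' iteratively rotates all configurations onto the current mean shape
#' (rotation only; all photographs show the same lateral side, so
#' reflections are excluded), re-estimating the mean until it moves less
#' than `tol`. The summed squared distance to the mean is non-increasing
#' over iterations.
#'
#' @param configs list of at least two [landmark_config] objects
#' @param tol convergence tolerance on the mean-shape change
#' @param max_iter iteration cap
#' @return object of class `gpa_fit`: list with `aligned` (6 x 2 x n
#'   array), `mean_shape` (unit centroid size), `centroid_sizes` (cm),
#'   `specimen_ids`, `iterations`, `objective` (per-iteration trace)
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 200L) {
  if (length(configs) < 2L) stop_ctx("gpa: need at least 2 configurations")
  n <- length(configs)
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  X <- array(NA_real_, c(6, 2, n))
  csize <- numeric(n)
  for (i in seq_len(n)) {
    p <- configs[[i]]$landmarks
    p <- sweep(p, 2, colMeans(p))
    cs <- sqrt(sum(p^2))
    if (cs < 1e-12)
      stop_ctx("gpa: degenerate configuration '%s' (coincident landmarks)",
               ids[i])
    csize[i] <- cs
    X[, , i] <- p / cs
  }
  # orientation-free initialization: align everything onto the first
  # configuration before the first mean is taken, so the iteration path
  # (and any local optimum it selects) cannot depend on the arbitrary
  # orientations the configurations arrived in
  for (i in seq_len(n)[-1]) X[, , i] <- X[, , i] %*%
      kabsch_rotation(X[, , i], X[, , 1])
  M <- apply(X, c(1, 2), mean)
  obj <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% kabsch_rotation(X[, , i], M)
    M_new <- apply(X, c(1, 2), mean)
    obj <- c(obj, sum(sweep(X, c(1, 2), M_new)^2))
    delta <- sqrt(sum((M_new - M)^2))
    M <- M_new
    if (delta < tol || iter >= max_iter) break
  }
  # canonical orientation: rotate the solution onto the principal axes of
  # the mean shape (rotation only), with a deterministic sign, so the
  # output does not depend on the inputs' arbitrary orientations
  V <- svd(M)$v
  if (det(V) < 0) V[, 2] <- -V[, 2]
  Mc <- M %*% V
  j <- which.max(abs(Mc[, 1]))
  if (Mc[j, 1] > 0) V <- -V
  M <- M %*% V
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% V
  dimnames(X) <- list(NULL, c("x", "y"), ids)
  structure(list(aligned = X, mean_shape = M / sqrt(sum(M^2)),
                 centroid_sizes = setNames(csize, ids),
                 specimen_ids = ids, iterations = iter, objective = obj),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> %d specimens aligned in %d iteration(s), objective %.3e\n",
              length(x$specimen_ids), x$iterations, tail(x$objective, 1)))
  invisible(x)
}

#' Procrustes distance between two aligned shapes
#' @param a,b 6 x 2 coordinate matrices
#' @return square root of summed squared landmark differences
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Closed-form ordinary Procrustes distance between two configurations
#'
#' Centers and unit-scales both configurations and rotates the first onto
#' the second using the SVD of the cross-covariance (rotation only); used as
#' an independent check of the iterative alignment for n = 2.
#'
#' @param a,b [landmark_config] objects or coordinate matrices
#' @return the minimized root summed squared difference
#' @export
ordinary_procrustes_distance <- function(a, b) {
  get_mat <- function(z) if (inherits(z, "landmark_config")) z$landmarks else z
  norm1 <- function(p) {
    p <- sweep(p, 2, colMeans(p)); p / sqrt(sum(p^2))
  }
  A <- norm1(get_mat(a)); B <- norm1(get_mat(b))
  R <- kabsch_rotation(A, B)
  sqrt(sum((A %*% R - B)^2))
}

#' Principal component analysis of aligned Procrustes coordinates
#'
#' Eigendecomposition of the covariance of the flattened (12-dimensional)
#' aligned coordinates; scores are centered coordinates projected onto the
#' eigenvectors.
#'
#' @param aligned a `gpa_fit` or a 6 x 2 x n array of aligned coordinates
#' @return object of class `shape_pca`: list with `mean` (12-vector),
#'   `rotation` (12 x k orthonormal loadings), `scores` (n x k),
#'   `var_prop` (variance proportions), `sdev`
#' @export
shape_pca <- function(aligned) {
  X <- if (inherits(aligned, "gpa_fit")) aligned$aligned else aligned
  n <- dim(X)[3]
  if (is.na(n) || n < 3L) stop_ctx("shape_pca: need at least 3 shapes")
  flat <- t(apply(X, 3, as.numeric))     # n x 12, (x1..x6, y1..y6)
  pc <- prcomp(flat, center = TRUE, scale. = FALSE)
  var_prop <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean = pc$center, rotation = pc$rotation,
                 scores = pc$x, var_prop = var_prop, sdev = pc$sdev,
                 specimen_ids = dimnames(X)[[3]]),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d shapes; PC1-PC3 variance: %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * head(x$var_prop, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Confidence ellipse for a group of 2-D scores
#'
#' Ellipse from the group mean and a multivariate-t scale matrix
#' (estimated by [MASS::cov.trob] with `df` degrees of freedom), with
#' squared radius `2 * qf(level, 2, df)`, so that for t-distributed scores
#' the ellipse has the nominal coverage.
#'
#' @param scores_2d n x 2 matrix of scores (n >= 3)
#' @param level coverage level
#' @param df t degrees of freedom; default `nrow(scores_2d) - 1`
#' @return list with `center`, `scale` (2 x 2), `radius`, semi-`axes`
#'   lengths, `angle` (radians of the major axis), `level`, `df`
#' @export
confidence_ellipse <- function(scores_2d, level = 0.95, df = NULL) {
  scores_2d <- as.matrix(scores_2d)
  if (nrow(scores_2d) < 3L)
    stop_ctx("confidence_ellipse: need at least 3 points")
  if (is.null(df)) df <- nrow(scores_2d) - 1L
  S0 <- stats::cov(scores_2d)
  if (abs(det(S0)) < 1e-14 * max(1, prod(diag(S0))))
    stop_ctx("confidence_ellipse: singular covariance")
  fit <- MASS::cov.trob(scores_2d, nu = df, maxit = 200)
  S <- fit$cov
  r <- sqrt(2 * qf(level, 2, df))
  eg <- eigen(S, symmetric = TRUE)
  list(center = fit$center, scale = S, radius = r,
       axes = r * sqrt(eg$values),
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       level = level, df = df)
}

#' Test whether points fall inside a confidence ellipse
#' @param ellipse output of [confidence_ellipse]
#' @param pts n x 2 matrix
#' @return logical vector
#' @export
ellipse_contains <- function(ellipse, pts) {
  pts <- as.matrix(pts)
  d2 <- stats::mahalanobis(pts, ellipse$center, ellipse$scale)
  d2 <= ellipse$radius^2
}
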
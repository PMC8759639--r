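#' @name spd-geometry
#' @title Affine-invariant geometry of SPD covariance matrices
#' @description
#' Covariance matrices live on the manifold of symmetric
#' positive-definite (SPD) matrices.  The functions here implement the
#' affine-invariant Riemannian toolbox the classification pipelines rely
#' on: matrix square roots and logarithms, the geometric (Frechet/Karcher)
#' mean of a set, the log-map at a reference point, and the isometric
#' half-vectorization that turns tangent matrices into Euclidean feature
#' vectors of dimension `n(n+1)/2`.
NULL

# symmetric eigendecomposition helpers; eigenvalues below floor*max are
# an error rather than silently clamped, so invalid covariances surface.
spd_eigen <- function(m, floor_frac = 1e-12, what = "matrix") {
  m <- (m + t(m)) / 2
  ee <- eigen(m, symmetric = TRUE)
  if (any(ee$values <= floor_frac * max(abs(ee$values))))
    stop(what, " is not positive definite (smallest eigenvalue ",
         format(min(ee$values)), ")")
  ee
}

spd_fun <- function(m, f, what = "matrix") {
  ee <- spd_eigen(m, what = what)
  ee$vectors %*% (f(ee$values) * t(ee$vectors))
}

#' Matrix square root, inverse square root, log and exp of SPD matrices
#'
#' Computed via symmetric eigendecomposition.  Non-positive-definite
#' input (smallest eigenvalue below `1e-12` of the largest) is an error.
#'
#' @param m symmetric positive-definite matrix (for `spd_exp`, any
#'   symmetric matrix).
#' @return matrix of the same dimension.
#' @export
spd_sqrt <- function(m) spd_fun(m, sqrt)

#' @rdname spd_sqrt
#' @export
spd_invsqrt <- function(m) spd_fun(m, function(v) 1 / sqrt(v))

#' @rdname spd_sqrt
#' @export
spd_log <- function(m) spd_fun(m, log)

#' @rdname spd_sqrt
#' @export
spd_exp <- function(m) {
  m <- (m + t(m)) / 2
  ee <- eigen(m, symmetric = TRUE)
  ee$vectors %*% (exp(ee$values) * t(ee$vectors))
}

as_spd <- function(x) {
  if (inherits(x, "spd_matrix")) x$sigma else as.matrix(x)
}

#' Geometric (Frechet/Karcher) mean of SPD matrices
#'
#' The point minimizing the mean squared affine-invariant Riemannian
#' distance to a set of SPD matrices, computed by the standard fixed-point
#' iteration: map the set to the tangent space at the current estimate,
#' average, and map back, until the update's Frobenius norm falls below
#' `tol`.
#'
#' @param matrices list of SPD matrices (plain matrices or
#'   [trial_covariance()] results), all of one size.
#' @param tol convergence tolerance on the tangent-update Frobenius norm.
#' @param max_iter maximum number of fixed-point iterations; exceeding it
#'   is an error carrying the final residual.
#' @details The step size starts at 1 and is halved whenever the update
#'   norm fails to decrease, which keeps the iteration convergent for
#'   ill-conditioned sets (e.g. covariances of nearly noise-free
#'   signals).
#' @return list of class `spd_reference`: `sigma` (the mean), `iterations`,
#'   `final_step_norm`.
#' @export
spd_geometric_mean <- function(matrices, tol = 1e-8, max_iter = 500L) {
  if (length(matrices) == 0L) stop("need at least one matrix")
  ms <- lapply(matrices, as_spd)
  n <- nrow(ms[[1L]])
  if (!all(vapply(ms, function(m) all(dim(m) == n), logical(1L))))
    stop("all matrices must share one size")
  g <- Reduce(`+`, ms) / length(ms)     # arithmetic-mean init
  step <- 1
  prev_norm <- Inf
  step_norm <- Inf
  for (it in seq_len(max_iter)) {
    gis <- spd_invsqrt(g)
    gs <- spd_sqrt(g)
    tangent <- Reduce(`+`, lapply(ms, function(m)
      spd_log(gis %*% m %*% gis))) / length(ms)
    tangent <- (tangent + t(tangent)) / 2
    step_norm <- sqrt(sum(tangent^2))
    if (step_norm < tol)
      return(structure(list(sigma = g, iterations = it,
                            final_step_norm = step_norm),
                       class = "spd_reference"))
    if (step_norm > prev_norm) step <- step / 2
    prev_norm <- step_norm
    g <- gs %*% spd_exp(step * tangent) %*% gs
    g <- (g + t(g)) / 2
  }
  stop("geometric mean did not converge in ", max_iter,
       " iterations (residual ", format(step_norm), ")")
}

as_ref <- function(ref) {
  if (inherits(ref, "spd_reference")) ref$sigma else as_spd(ref)
}

#' Log-map of an SPD matrix at a reference point
#'
#' `Phi(Sigma) = R^{1/2} log(R^{-1/2} Sigma R^{-1/2}) R^{1/2}` for
#' reference `R`: the tangent-space image of `Sigma` at `R` under the
#' affine-invariant metric.  Symmetric by construction.
#'
#' @param sigma SPD matrix to map.
#' @param ref reference point: an SPD matrix or a [spd_geometric_mean()]
#'   result.
#' @return symmetric matrix of the same size.
#' @export
spd_log_map <- function(sigma, ref) {
  r <- as_ref(ref); s <- as_spd(sigma)
  ris <- spd_invsqrt(r); rs <- spd_sqrt(r)
  out <- rs %*% spd_log(ris %*% s %*% ris) %*% rs
  (out + t(out)) / 2
}

#' Inverse of the log-map (exponential map at a reference)
#' @param phi symmetric tangent matrix.
#' @param ref reference point as in [spd_log_map()].
#' @return SPD matrix.
#' @export
spd_exp_map <- function(phi, ref) {
  r <- as_ref(ref)
  ris <- spd_invsqrt(r); rs <- spd_sqrt(r)
  out <- rs %*% spd_exp(ris %*% ((phi + t(phi)) / 2) %*% ris) %*% rs
  (out + t(out)) / 2
}

#' Isometric half-vectorization of a tangent matrix
#'
#' Whitens the symmetric tangent matrix by the reference
#' (`R^{-1/2} S R^{-1/2}`), then stacks the upper triangle row-wise with
#' off-diagonal entries scaled by `sqrt(2)`.  With that weighting the
#' vector's Euclidean norm equals the Frobenius norm of the whitened
#' matrix, so tangent vectors of [spd_log_map()] images have norm equal
#' to the affine-invariant Riemannian distance to the reference.
#'
#' @param s symmetric matrix (e.g. a [spd_log_map()] image).
#' @param ref reference point as in [spd_log_map()].
#' @param sym_tol largest tolerated asymmetry `max|S - S'|`.
#' @return numeric vector of length `n(n+1)/2`.
#' @export
tangent_vectorize <- function(s, ref, sym_tol = 1e-8) {
  s <- as.matrix(s)
  if (max(abs(s - t(s))) > sym_tol)
    stop("input matrix is not symmetric within tolerance ", sym_tol)
  ris <- spd_invsqrt(as_ref(ref))
  w <- ris %*% ((s + t(s)) / 2) %*% ris
  n <- nrow(w)
  ut <- upper.tri(w, diag = TRUE)
  scale <- matrix(sqrt(2), n, n); diag(scale) <- 1
  (t(w * scale))[t(ut)]          # row-wise upper triangle
}

#' Affine-invariant Riemannian distance between SPD matrices
#' @param a,b SPD matrices.
#' @return scalar `||log(a^{-1/2} b a^{-1/2})||_F`.
#' @export
spd_distance <- function(a, b) {
  ais <- spd_invsqrt(as_spd(a))
  sqrt(sum(spd_log(ais %*% as_spd(b) %*% ais)^2))
}

#' Project a set of SPD matrices to a common tangent space
#'
#' If `ref = "fit"`, first computes the geometric mean of the given
#' (training) set and uses it as the reference; the fitted reference is
#' returned so held-out matrices can later be projected without ever
#' influencing it (no leakage).  Each matrix is then log-mapped and
#' vectorized with [tangent_vectorize()].
#'
#' @param matrices list of SPD matrices.
#' @param ref `"fit"`, an SPD matrix, or a [spd_geometric_mean()] result.
#' @param ... passed to [spd_geometric_mean()] when fitting.
#' @return list: `vectors` (matrix, one row per input matrix),
#'   `reference` (an `spd_reference`).
#' @export
tangent_project <- function(matrices, ref = "fit", ...) {
  if (length(matrices) == 0L) stop("need at least one matrix")
  reference <- if (identical(ref, "fit"))
    spd_geometric_mean(matrices, ...)
  else if (inherits(ref, "spd_reference")) ref
  else structure(list(sigma = as_spd(ref), iterations = 0L,
                      final_step_norm = 0), class = "spd_reference")
  d <- nrow(reference$sigma) * (nrow(reference$sigma) + 1L) / 2L
  vecs <- vapply(matrices, function(m)
    tangent_vectorize(spd_log_map(m, reference), reference), numeric(d))
  vecs <- if (d == 1L) matrix(vecs, ncol = 1L) else t(vecs)
  list(vectors = vecs, reference = reference)
}
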
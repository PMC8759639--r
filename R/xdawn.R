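#' Class-average evoked prototype
#'
#' Element-wise mean over all trials of one class: the evoked-potential
#' prototype `P^(k)` used both for grand-average ERP inspection and as
#' the numerator signal of the xDAWN criterion.
#'
#' @param epochs an [epoch_set()].
#' @param class_id class label, 0 or 1.
#' @return list of class `evoked_prototype`: `matrix` (channels x
#'   samples), `class_id`, `n_trials_averaged`, `channel_names`,
#'   `sampling_rate`, `t0_offset`.
#' @export
class_average <- function(epochs, class_id) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$labels == class_id)
  if (length(idx) == 0L) stop("no trials with class ", class_id)
  m <- apply(epochs$data[idx, , , drop = FALSE], c(2L, 3L), mean)
  structure(list(matrix = m, class_id = as.integer(class_id),
                 n_trials_averaged = length(idx),
                 channel_names = epochs$channel_names,
                 sampling_rate = epochs$sampling_rate,
                 t0_offset = epochs$t0_offset),
            class = "evoked_prototype")
}

# deterministic eigenvector sign/tie convention: flip so the
# largest-magnitude entry is positive; ties in eigenvalues are kept in
# the (stable) order returned with ascending index of the largest entry.
fix_filter_signs <- function(w_mat) {
  for (j in seq_len(ncol(w_mat))) {
    v <- w_mat[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) w_mat[, j] <- -v
  }
  w_mat
}

# generalized symmetric eigenproblem A w = lambda B w via Cholesky of B;
# a rank-deficient B (degenerate, e.g. noise-free, signals) gets an
# escalating trace-scaled ridge before giving up.
gen_eigen_spd <- function(a_mat, b_mat) {
  n <- nrow(b_mat)
  ridge <- c(0, 1e-10, 1e-8, 1e-6) * sum(diag(b_mat)) / n
  ch <- NULL
  for (r in ridge) {
    ch <- tryCatch(chol(b_mat + r * diag(n)), error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch))
    stop("denominator matrix is singular even after regularization")
  li <- backsolve(ch, diag(n))            # ch^{-1}
  m <- t(li) %*% a_mat %*% li
  ee <- eigen((m + t(m)) / 2, symmetric = TRUE)
  list(values = ee$values, vectors = li %*% ee$vectors)
}

#' Fit xDAWN spatial filters
#'
#' For each class `k`, estimates the spatial filters maximizing the
#' generalized Rayleigh quotient of evoked energy over total signal
#' energy, i.e. the leading generalized eigenvectors of
#' `(P_k P_k', X X')`, where `P_k` is the class-average prototype and
#' `X` is the concatenation of all trials from both classes along time.
#' The `F` filters with largest eigenvalues are kept per class.
#'
#' @param epochs an [epoch_set()] containing both classes.
#' @param n_filters number of filters `F` kept per class (>= 1, <= number
#'   of channels).  The classical choice giving 12 x 12 augmented
#'   covariances is `F = 3`.
#' @param cond_limit condition-number threshold above which the
#'   denominator `X X'` is ridge-regularized by
#'   `1e-10 * trace / n_channels * I` before solving.
#' @return list of class `spatial_filter_bank`: `W0`, `W1` (channels x F
#'   filter matrices), `W` (channels x 2F, class-0 columns first),
#'   `eigenvalues` (list of the two descending eigenvalue vectors),
#'   `n_filters`, `prototypes` (list of the two [class_average()]
#'   prototypes used).
#' @export
fit_xdawn <- function(epochs, n_filters = 3L, cond_limit = 1e12) {
  stopifnot(inherits(epochs, "epoch_set"))
  e <- dim(epochs$data)[2L]
  if (n_filters < 1L || n_filters > e)
    stop("n_filters must be between 1 and the channel count (", e, ")")
  if (length(unique(epochs$labels)) < 2L)
    stop("both classes must be present to fit xDAWN")
  protos <- lapply(0:1, function(k) class_average(epochs, k))

  # X X' accumulated trial by trial (X = all trials concatenated in time)
  cxx <- matrix(0, e, e)
  for (i in seq_len(n_trials(epochs))) {
    x <- trial_matrix(epochs, i)
    cxx <- cxx + tcrossprod(x)
  }
  if (kappa(cxx, exact = TRUE) > cond_limit)
    cxx <- cxx + (1e-10 * sum(diag(cxx)) / e) * diag(e)

  sol <- lapply(protos, function(p) {
    ge <- tryCatch(gen_eigen_spd(tcrossprod(p$matrix), cxx),
                   error = function(err)
                     stop("total-signal covariance X X' is singular: ",
                          conditionMessage(err)))
    list(values = ge$values[seq_len(n_filters)],
         vectors = fix_filter_signs(
           ge$vectors[, seq_len(n_filters), drop = FALSE]))
  })
  structure(list(W0 = sol[[1L]]$vectors, W1 = sol[[2L]]$vectors,
                 W = cbind(sol[[1L]]$vectors, sol[[2L]]$vectors),
                 eigenvalues = list(class0 = sol[[1L]]$values,
                                    class1 = sol[[2L]]$values),
                 n_filters = as.integer(n_filters),
                 channel_names = epochs$channel_names,
                 prototypes = protos),
            class = "spatial_filter_bank")
}

#' Build the augmented trial of the ERP covariance construction
#'
#' Stacks the spatially filtered class prototypes on top of the filtered
#' single trial: rows are `[W0' P0; W1' P1; W' X_i]`, a `4F x samples`
#' matrix whose covariance captures both the trial's spatial structure
#' and its temporal covariation with the two evoked prototypes.
#'
#' @param trial channels x samples numeric matrix (one trial).
#' @param bank a [fit_xdawn()] filter bank.
#' @param prototypes optional list of the two prototypes (class 0, class
#'   1); defaults to the prototypes stored in `bank` (i.e. the training
#'   set averages, as required when transforming held-out trials).
#' @return `4F x samples` numeric matrix of class `augmented_trial`.
#' @export
augment_trial <- function(trial, bank, prototypes = bank$prototypes) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  trial <- as.matrix(trial)
  e <- nrow(bank$W)
  if (nrow(trial) != e)
    stop("trial has ", nrow(trial), " channels; bank expects ", e)
  p0 <- prototypes[[1L]]$matrix; p1 <- prototypes[[2L]]$matrix
  if (ncol(p0) != ncol(trial) || ncol(p1) != ncol(trial))
    stop("prototype and trial sample counts differ")
  z <- rbind(crossprod(bank$W0, p0),
             crossprod(bank$W1, p1),
             crossprod(bank$W, trial))
  class(z) <- c("augmented_trial", class(z))
  z
}

# ---- covariance estimators -------------------------------------------

# uncentered second-moment matrix over time, divisor = n samples
second_moment <- function(z) tcrossprod(z) / ncol(z)

# Ledoit-Wolf shrinkage toward mu*I of the (uncentered) second moment.
ledoit_wolf_cov <- function(z) {
  n <- nrow(z); t_n <- ncol(z)
  s <- second_moment(z)
  mu <- sum(diag(s)) / n
  delta2 <- sum((s - mu * diag(n))^2)          # Frobenius^2
  beta2 <- 0
  for (t in seq_len(t_n)) {
    d <- tcrossprod(z[, t]) - s
    beta2 <- beta2 + sum(d^2)
  }
  beta2 <- beta2 / t_n^2
  rho <- if (delta2 > 0) min(beta2 / delta2, 1) else 1
  list(sigma = (1 - rho) * s + rho * mu * diag(n), rho = rho)
}

# Oracle-approximating shrinkage (OAS) toward mu*I.
oas_cov <- function(z) {
  n <- nrow(z); t_n <- ncol(z)
  s <- second_moment(z)
  tr_s <- sum(diag(s)); tr_s2 <- sum(s^2)
  mu <- tr_s / n
  num <- (1 - 2 / n) * tr_s2 + tr_s^2
  den <- (t_n + 1 - 2 / n) * (tr_s2 - tr_s^2 / n)
  rho <- if (den > 0) min(num / den, 1) else 1
  list(sigma = (1 - rho) * s + rho * mu * diag(n), rho = rho)
}

#' Per-trial (augmented) covariance matrix
#'
#' Second-moment covariance of the rows of a trial (or augmented trial)
#' over time, optionally shrunk toward a scaled identity with the
#' Ledoit-Wolf or OAS intensity so the result is well conditioned.  The
#' divisor is the number of time samples; rows are not mean-centered, as
#' is conventional for ERP covariances where the prototype rows' means
#' carry signal.
#'
#' @param z rows x samples numeric matrix (e.g. an [augment_trial()]
#'   output).
#' @param estimator `"oas"` (default), `"ledoit_wolf"` or `"empirical"`.
#' @return list of class `spd_matrix`: `sigma` (the matrix), `estimator`,
#'   `shrinkage` (intensity in `[0, 1]`, `0` for empirical).
#' @export
trial_covariance <- function(z,
                             estimator = c("oas", "ledoit_wolf",
                                           "empirical")) {
  estimator <- match.arg(estimator)
  z <- unclass(as.matrix(z))
  if (ncol(z) < 2L) stop("at least 2 time samples are required")
  out <- switch(estimator,
                empirical = list(sigma = second_moment(z), rho = 0),
                ledoit_wolf = ledoit_wolf_cov(z),
                oas = oas_cov(z))
  sigma <- (out$sigma + t(out$sigma)) / 2
  structure(list(sigma = sigma, estimator = estimator,
                 shrinkage = out$rho),
            class = "spd_matrix")
}

#' Rayleigh quotient of a spatial filter
#'
#' Utility returning `w' A w / w' B w`; used to check xDAWN optimality.
#' @param w numeric filter vector.
#' @param a_mat,b_mat symmetric matrices (numerator / denominator).
#' @return scalar quotient.
#' @export
rayleigh_quotient <- function(w, a_mat, b_mat) {
  drop(crossprod(w, a_mat %*% w) / crossprod(w, b_mat %*% w))
}
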
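test_that("class_average is the element-wise trial mean", {
  # single trial -> the trial itself
  tr <- matrix(1:8, 2, 4)
  ep <- epochs_from_trials(list(tr, -tr), c(0, 1))
  expect_equal(class_average(ep, 0)$matrix, tr, ignore_attr = TRUE)

  # X and -X in one class -> zero
  ep2 <- epochs_from_trials(list(tr, -tr), c(0, 0))
  expect_equal(class_average(ep2, 0)$matrix, matrix(0, 2, 4),
               ignore_attr = TRUE)

  # summation oracle on three integer trials
  trials <- list(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4),
                 matrix(c(2, 0, 1, 1, 3, 3, 5, 2), 2, 4),
                 matrix(c(0, 4, 2, 1, 1, 0, 3, 2), 2, 4))
  ep3 <- epochs_from_trials(trials, c(0, 0, 0))
  oracle <- (trials[[1]] + trials[[2]] + trials[[3]]) / 3
  expect_equal(class_average(ep3, 0)$matrix, oracle, ignore_attr = TRUE)
  expect_equal(class_average(ep3, 0)$n_trials_averaged, 3L)
  expect_error(class_average(ep3, 1), "class 1")
})

test_that("xDAWN solves the hand-computable 2-channel eigenproblem", {
  # class-0 prototype has energy only in channel 1; trials are chosen so
  # X X' is proportional to the identity.  Then the top filter is e1 and
  # its eigenvalue is the ratio of prototype to total energy.
  p <- rbind(c(1, 1, -1, -1), c(0, 0, 0, 0))          # channel-1 only
  trials <- list(p + rbind(c(1, -1, 1, -1), 0),
                 p - rbind(c(1, -1, 1, -1), 0),
                 rbind(0, c(2, 0, 0, -2)),
                 rbind(0, c(0, 2, -2, 0)))
  # class 0: two trials averaging to p; class 1: channel-2 only, mean 0
  ep <- epochs_from_trials(trials, c(0, 0, 1, 1))
  cxx <- Reduce(`+`, lapply(trials, tcrossprod))
  expect_equal(cxx, diag(c(16, 16)))                  # identity-scaled
  bank <- fit_xdawn(ep, n_filters = 1)
  w1 <- bank$W0[, 1] / sqrt(sum(bank$W0[, 1]^2))
  expect_equal(abs(w1), c(1, 0), tolerance = 1e-10)
  # eigenvalue = w' P P' w / w' XX' w = 4 / 16
  expect_equal(bank$eigenvalues$class0[1], 4 / 16, tolerance = 1e-10)
})

test_that("xDAWN filters are invariant to global signal scaling", {
  cfg <- small_config()
  ep <- crop_epochs(simulate_epochs(cfg, seed = 5), 0, 0.5)
  b1 <- fit_xdawn(ep, 3)
  ep2 <- ep; ep2$data <- ep$data * 7.3
  b2 <- fit_xdawn(ep2, 3)
  # filters scale as 1/c under X -> cX (quotient invariant up to scale);
  # compare direction
  for (j in 1:3) {
    v1 <- b1$W0[, j] / sqrt(sum(b1$W0[, j]^2))
    v2 <- b2$W0[, j] / sqrt(sum(b2$W0[, j]^2))
    expect_equal(v1, v2, tolerance = 1e-8)
  }
  expect_equal(b1$eigenvalues$class0, b2$eigenvalues$class0,
               tolerance = 1e-8)
})

test_that("top filter beats random vectors on the Rayleigh quotient", {
  set.seed(99)
  for (rep_ in 1:5) {
    trials <- replicate(8, matrix(rnorm(6 * 20), 6, 20),
                        simplify = FALSE)
    ep <- epochs_from_trials(trials, rep(c(0, 1), each = 4))
    bank <- fit_xdawn(ep, 1)
    cp <- tcrossprod(class_average(ep, 0)$matrix)
    cx <- Reduce(`+`, lapply(trials, tcrossprod))
    best <- rayleigh_quotient(bank$W0[, 1], cp, cx)
    v <- matrix(rnorm(6 * 2e4), 6)
    q <- colSums((cp %*% v) * v) / colSums((cx %*% v) * v)
    expect_gte(best, max(q) - 1e-9)
  }
})

test_that("xDAWN eigenvalues decrease and lie in [0, 1]", {
  cfg <- small_config()
  ep <- crop_epochs(simulate_epochs(cfg, seed = 6), 0, 0.5)
  bank <- fit_xdawn(ep, 5)
  for (k in c("class0", "class1")) {
    ev <- bank$eigenvalues[[k]]
    expect_true(all(diff(ev) <= 1e-12))
    expect_true(all(ev >= -1e-12 & ev <= 1 + 1e-12))
  }
  expect_error(fit_xdawn(ep, 13), "n_filters")
  expect_error(fit_xdawn(subset_trials(ep, which(ep$labels == 0)), 3),
               "both classes")
})

test_that("augment_trial stacks filtered prototypes over the trial", {
  # F = channels with identity-like filters reproduces [P0; P1; X]
  trials <- list(diag(3) %*% matrix(1:12, 3, 4),
                 matrix(rnorm(12), 3, 4),
                 matrix(rnorm(12), 3, 4),
                 matrix(rnorm(12), 3, 4))
  ep <- epochs_from_trials(trials, c(0, 0, 1, 1))
  bank <- fit_xdawn(ep, 3)
  z <- augment_trial(trials[[2]], bank)
  expect_equal(dim(z), c(12L, 4L))
  expect_equal(unclass(z),
               rbind(crossprod(bank$W0, class_average(ep, 0)$matrix),
                     crossprod(bank$W1, class_average(ep, 1)$matrix),
                     crossprod(bank$W, trials[[2]])),
               ignore_attr = TRUE)

  # 2-channel, F = 1: explicit multiplication oracle
  tr2 <- list(matrix(c(1, 0, 2, 1), 2, 2), matrix(c(0, 1, 1, 2), 2, 2))
  ep2 <- epochs_from_trials(tr2, c(0, 1))
  b2 <- fit_xdawn(ep2, 1)
  z2 <- augment_trial(tr2[[1]], b2)
  w0 <- b2$W0[, 1]; w1 <- b2$W1[, 1]
  p0 <- tr2[[1]]; p1 <- tr2[[2]]
  oracle <- rbind(c(sum(w0 * p0[, 1]), sum(w0 * p0[, 2])),
                  c(sum(w1 * p1[, 1]), sum(w1 * p1[, 2])),
                  c(sum(w0 * p0[, 1]), sum(w0 * p0[, 2])),
                  c(sum(w1 * p0[, 1]), sum(w1 * p0[, 2])))
  expect_equal(unclass(z2), oracle, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(augment_trial(matrix(0, 5, 4), bank), "channels")
})

test_that("augmented covariance has side 4F and constant prototype block", {
  cfg <- small_config()
  ep <- crop_epochs(simulate_epochs(cfg, seed = 8), 0, 0.5)
  bank <- fit_xdawn(ep, 3)
  covs <- lapply(1:4, function(i)
    trial_covariance(augment_trial(ep$data[i, , ], bank),
                     "empirical")$sigma)
  expect_true(all(vapply(covs, function(s) all(dim(s) == 12L),
                         logical(1))))
  # top-left 2F x 2F block (prototype rows) identical across trials
  for (i in 2:4)
    expect_equal(covs[[i]][1:6, 1:6], covs[[1]][1:6, 1:6],
                 tolerance = 1e-10)
  # shrinkage estimators still give 12 x 12 SPD matrices
  s_oas <- trial_covariance(augment_trial(ep$data[1, , ], bank), "oas")
  expect_equal(dim(s_oas$sigma), c(12L, 12L))
  expect_gt(min(eigen(s_oas$sigma, symmetric = TRUE)$values), 0)
})

test_that("covariance estimators match their defining formulas", {
  # orthonormal impulse rows, empirical -> identity / n
  z <- diag(4)
  emp <- trial_covariance(z, "empirical")
  expect_equal(emp$sigma, diag(4) / 4)
  expect_equal(emp$shrinkage, 0)

  # Ledoit-Wolf against an independently coded textbook formula
  set.seed(3)
  z <- matrix(rnorm(4 * 50), 4, 50)
  lw <- trial_covariance(z, "ledoit_wolf")
  # oracle, written as explicit sums
  t_n <- ncol(z); n <- nrow(z)
  s <- matrix(0, n, n)
  for (t in seq_len(t_n)) s <- s + z[, t] %o% z[, t]
  s <- s / t_n
  mu <- mean(diag(s))
  d2 <- sum((s - mu * diag(n))^2)
  b2 <- 0
  for (t in seq_len(t_n)) b2 <- b2 + sum((z[, t] %o% z[, t] - s)^2)
  b2 <- min(b2 / t_n^2, d2)
  rho <- b2 / d2
  oracle <- (1 - rho) * s + rho * mu * diag(n)
  expect_equal(lw$sigma, oracle, tolerance = 1e-10)
  expect_equal(lw$shrinkage, rho, tolerance = 1e-10)

  # OAS stays SPD and preserves the trace
  oas <- trial_covariance(z, "oas")
  expect_equal(sum(diag(oas$sigma)), sum(diag(s)), tolerance = 1e-10)
  expect_gt(min(eigen(oas$sigma, symmetric = TRUE)$values), 0)

  # degenerate input
  expect_error(trial_covariance(matrix(1, 3, 1)), "2 time samples")
})

test_that("channel permutation permutes filters consistently", {
  cfg <- small_config()
  ep <- crop_epochs(simulate_epochs(cfg, seed = 10), 0, 0.5)
  set.seed(21)
  perm <- sample(seq_along(ep$channel_names))
  ep_p <- select_channels(ep, ep$channel_names[perm])
  b <- fit_xdawn(ep, 3)
  b_p <- fit_xdawn(ep_p, 3)
  expect_equal(b_p$W0, b$W0[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(b_p$eigenvalues$class0, b$eigenvalues$class0,
               tolerance = 1e-10)
})
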
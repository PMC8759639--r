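make_cv_data <- function(seed = 20, subjects = 3L) {
  cfg <- sim_config(n_subjects = subjects, trials_per_class = c(8L, 8L),
                    sampling_rate = 64)
  crop_epochs(simulate_epochs(cfg, seed = seed), 0, 0.5)
}

test_that("pipeline_spec validates names and stage structure", {
  sp <- pipeline_spec("xdawn_cov_ts_lr")
  expect_equal(sp$stages, c("xdawn", "covariance", "tangent_space",
                            "logistic_regression"))
  expect_equal(utils::tail(sp$stages, 1), "logistic_regression")
  expect_error(pipeline_spec("nope"))
})

test_that("LOSO folds are per-subject, disjoint and exhaustive", {
  ep <- make_cv_data()
  rep_ <- run_loso(ep, pipeline_spec("csp_lr"))
  expect_equal(length(rep_$folds), 3L)
  all_idx <- sort(unlist(lapply(rep_$folds, `[[`, "test_idx"), use.names = FALSE))
  expect_equal(all_idx, seq_len(n_trials(ep)))
  for (f in rep_$folds)
    expect_equal(unique(ep$subject_ids[f$test_idx]), f$subject)
  # single subject is redirected to the k-fold scheme
  solo <- subset_trials(ep, which(ep$subject_ids == 1))
  expect_error(run_loso(solo, pipeline_spec("csp_lr")),
               "run_kfold_per_subject")
})

test_that("per-subject k-fold is stratified, seeded and exhaustive", {
  ep <- make_cv_data()
  rep_ <- run_kfold_per_subject(ep, pipeline_spec("csp_lr"), k = 4,
                                seed = 3)
  expect_equal(length(rep_$folds), 12L)     # 3 subjects x 4 folds
  # each fold holds 2 + 2 test trials (8 + 8 per subject, k = 4)
  for (f in rep_$folds) {
    expect_equal(length(f$test_idx), 4L)
    expect_equal(sum(ep$labels[f$test_idx] == 0), 2L)
  }
  all_idx <- sort(unlist(lapply(rep_$folds, `[[`, "test_idx"), use.names = FALSE))
  expect_equal(all_idx, seq_len(n_trials(ep)))
  # same seed -> identical fold assignment and accuracies
  rep2 <- run_kfold_per_subject(ep, pipeline_spec("csp_lr"), k = 4,
                                seed = 3)
  expect_identical(lapply(rep_$folds, `[[`, "test_idx"),
                   lapply(rep2$folds, `[[`, "test_idx"))
  expect_equal(rep_$fold_accuracies, rep2$fold_accuracies)
  # insufficient trials are reported with the subject named
  expect_error(run_kfold_per_subject(ep, pipeline_spec("csp_lr"),
                                     k = 10),
               "subject 1")
})

test_that("training-stage parameters ignore test-fold trials (no leakage)", {
  ep <- make_cv_data(seed = 21)
  train_idx <- which(ep$subject_ids != 1)
  train <- subset_trials(ep, train_idx)
  m1 <- fit_pipeline(pipeline_spec("xdawn_cov_ts_lr"), train)
  # deleting a test-fold (subject-1) trial changes nothing in the fit
  pruned <- subset_trials(ep, setdiff(seq_len(n_trials(ep)),
                                      which(ep$subject_ids == 1)[1]))
  train2 <- subset_trials(pruned, which(pruned$subject_ids != 1))
  m2 <- fit_pipeline(pipeline_spec("xdawn_cov_ts_lr"), train2)
  expect_equal(m1$fitted$bank$W, m2$fitted$bank$W)
  expect_equal(m1$fitted$reference$sigma, m2$fitted$reference$sigma)
  expect_equal(as.numeric(stats::coef(m1$classifier)),
               as.numeric(stats::coef(m2$classifier)))
})

test_that("all pipelines are perfect in the separable noise-free limit", {
  cfg <- sim_config(n_subjects = 2L, trials_per_class = c(8L, 8L),
                    sampling_rate = 64,
                    noise = list(spectral_exponent = 1,
                                 background_sd_uv = 0, sensor_sd_uv = 0),
                    subject_var = list(gain_sdlog = 0, mixing_sd = 0,
                                       amp_sdlog = 0, latency_sd_ms = 0),
                    trial_var = list(amp_sdlog = 0.05, latency_sd_ms = 2))
  ep <- crop_epochs(simulate_epochs(cfg, seed = 22), 0, 0.5)
  for (pn in c("vec_lr", "cov_lr", "cov_ts_lr", "xdawn_cov_lr",
               "csp_lr", "xdawn_cov_ts_lr")) {
    rep_ <- run_loso(ep, pipeline_spec(pn))
    expect_equal(rep_$mean_accuracy, 1,
                 info = paste("pipeline", pn))
  }
})

test_that("end-to-end runs are bit-reproducible with fixed seeds", {
  ep <- make_cv_data(seed = 23)
  r1 <- run_loso(ep, pipeline_spec("xdawn_cov_ts_lr"))
  r2 <- run_loso(ep, pipeline_spec("xdawn_cov_ts_lr"))
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$pooled$auc, r2$pooled$auc)
})

test_that("downstream classification is invariant to channel permutation", {
  ep <- make_cv_data(seed = 24)
  set.seed(30)
  perm <- sample(seq_along(ep$channel_names))
  ep_p <- select_channels(ep, ep$channel_names[perm])
  r <- run_loso(ep, pipeline_spec("xdawn_cov_ts_lr"))
  r_p <- run_loso(ep_p, pipeline_spec("xdawn_cov_ts_lr"))
  expect_equal(r$fold_accuracies, r_p$fold_accuracies, tolerance = 1e-6)
})

test_that("CSP recovers a planted variance difference", {
  # classes differ only in channel-1 variance
  set.seed(31)
  trials <- c(lapply(1:10, function(i)
                rbind(rnorm(50, sd = 3), rnorm(50, sd = 1),
                      rnorm(50, sd = 1))),
              lapply(1:10, function(i)
                rbind(rnorm(50, sd = 1), rnorm(50, sd = 1),
                      rnorm(50, sd = 1))))
  ep <- epochs_from_trials(trials, rep(c(0, 1), each = 10))
  model <- fit_csp(ep, 2)
  w1 <- abs(model$filters[, 1]) / sqrt(sum(model$filters[, 1]^2))
  expect_gt(w1[1], 0.95)
  # log-variance features shift by an additive constant under scaling
  f1 <- csp_features(ep, model)
  ep_s <- ep; ep_s$data <- ep$data * 5
  f2 <- csp_features(ep_s, model)
  expect_equal(f2, f1 + 2 * log(5), tolerance = 1e-10)
  expect_error(fit_csp(ep, 10), "channel count")
})

test_that("CSP filters match a generalized-eigenproblem oracle", {
  set.seed(32)
  trials <- replicate(12, matrix(rnorm(3 * 30), 3, 30), simplify = FALSE)
  ep <- epochs_from_trials(trials, rep(c(0, 1), each = 6))
  model <- fit_csp(ep, 2)
  cov_of <- function(k) {
    idx <- which(ep$labels == k)
    Reduce(`+`, lapply(idx, function(i)
      tcrossprod(trials[[i]]) / 30)) / length(idx)
  }
  c0 <- cov_of(0); c1 <- cov_of(1)
  # oracle: eigenvectors of solve(c0 + c1) %*% c0
  ee <- eigen(solve(c0 + c1) %*% c0)
  for (j in 1:2) {
    v_o <- Re(ee$vectors[, c(1, 3)[j]])
    v_o <- v_o / sqrt(sum(v_o^2)) * sign(v_o[which.max(abs(v_o))])
    v_m <- model$filters[, j] / sqrt(sum(model$filters[, j]^2))
    expect_equal(v_m, v_o, tolerance = 1e-6)
  }
})

test_that("the comparison suite runs all pipelines with shared folds", {
  ep <- make_cv_data(seed = 25)
  suite <- run_comparison_suite(ep, schemes = "loso",
                                pipelines = c("vec_lr", "csp_lr",
                                              "xdawn_cov_ts_lr"))
  expect_equal(nrow(suite$table), 3L)
  expect_true(all(c("pipeline", "scheme", "space", "mean_accuracy")
                  %in% names(suite$table)))
  idx <- lapply(suite$reports, function(r)
    lapply(r$folds, `[[`, "test_idx"))
  expect_identical(idx[[1]], idx[[2]])
  expect_identical(idx[[1]], idx[[3]])
})

test_that("forward selection finds a planted single-channel signal", {
  # signal confined to Oz: only Oz separates the classes
  cfg <- sim_config(n_subjects = 2L, trials_per_class = c(8L, 8L),
                    sampling_rate = 64,
                    channels = c("F3", "Cz", "Oz", "P3"),
                    topography = c(F3 = 0, Cz = 0, Oz = 1, P3 = 0),
                    noise = list(spectral_exponent = 1,
                                 background_sd_uv = 1, sensor_sd_uv = 0.5),
                    subject_var = list(gain_sdlog = 0.05, mixing_sd = 0,
                                       amp_sdlog = 0.05, latency_sd_ms = 2),
                    trial_var = list(amp_sdlog = 0.05, latency_sd_ms = 2))
  ep <- crop_epochs(simulate_epochs(cfg, seed = 26), 0, 0.5)
  sel <- forward_electrode_selection(ep, pipeline_spec("cov_ts_lr"),
                                     max_k = 3)
  expect_equal(sel$order[1], "Oz")
  expect_equal(length(sel$accuracy), 3L)
  expect_false(anyDuplicated(sel$order) > 0)
})

test_that("greedy selection matches exhaustive search on a small toy", {
  ep <- make_cv_data(seed = 27)
  ep <- select_channels(ep, c("Oz", "Pz", "Cz", "Fz"))
  spec <- pipeline_spec("cov_ts_lr")
  sel <- forward_electrode_selection(ep, spec, max_k = 2)
  # exhaustive oracle over subsets of size 1 and 2 containing the path
  accs1 <- vapply(ep$channel_names, function(ch)
    run_loso(select_channels(ep, ch),
             riemerp:::shrink_spec(spec, 1))$mean_accuracy, numeric(1))
  expect_equal(sel$order[1], names(which.max(accs1)))
  expect_equal(sel$accuracy[1], max(accs1))
  rest <- setdiff(ep$channel_names, sel$order[1])
  accs2 <- vapply(rest, function(ch)
    run_loso(select_channels(ep, c(sel$order[1], ch)),
             riemerp:::shrink_spec(spec, 2))$mean_accuracy, numeric(1))
  expect_equal(sel$accuracy[2], max(accs2))
})

test_that("triad analysis is deterministic and localizes the signal", {
  ep <- make_cv_data(seed = 28)
  tri <- region_triad_analysis(ep, pipeline_spec("xdawn_cov_ts_lr"))
  expect_equal(tri$region, c("occipital", "parietal", "central",
                             "frontal"))
  tri2 <- region_triad_analysis(ep, pipeline_spec("xdawn_cov_ts_lr"))
  expect_equal(tri$mean_accuracy, tri2$mean_accuracy)
})

test_that("label permutation keeps data but shuffles labels", {
  ep <- make_cv_data(seed = 29)
  pp <- permute_labels(ep, seed = 4)
  expect_identical(pp$data, ep$data)
  expect_equal(sort(pp$labels), sort(ep$labels))
  expect_false(identical(pp$labels, ep$labels))
  expect_identical(permute_labels(ep, seed = 4)$labels, pp$labels)
})
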
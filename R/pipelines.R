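#' Specify a classification pipeline
#'
#' A pipeline is an ordered stage list ending in a logistic-regression
#' classifier.  Six standard configurations are provided, mirroring the
#' usual ERP-decoding comparison set:
#' \describe{
#'   \item{`vec_lr`}{trials unrolled to 1-d vectors, logistic regression.}
#'   \item{`cov_lr`}{per-trial covariance, unrolled, logistic regression.}
#'   \item{`cov_ts_lr`}{per-trial covariance, tangent-space mapping,
#'     logistic regression.}
#'   \item{`xdawn_cov_lr`}{xDAWN augmented-trial covariance, unrolled,
#'     logistic regression.}
#'   \item{`csp_lr`}{CSP log-variance features, logistic regression.}
#'   \item{`xdawn_cov_ts_lr`}{xDAWN augmented-trial covariance,
#'     tangent-space mapping, logistic regression (the main pipeline).}
#' }
#'
#' @param name one of the six names above.
#' @param n_filters xDAWN filters per class (stages with xDAWN).
#' @param estimator covariance shrinkage estimator, see
#'   [trial_covariance()].
#' @param csp_components number of CSP components (even; largest/smallest
#'   eigenvalue pairs).
#' @param lambda L2 penalty of the ridge logistic regression; `NULL`
#'   means `1 / n_train` (the conventional unit-strength choice).
#' @return list of class `pipeline_spec` with a `stages` character
#'   vector and the parameters above.
#' @export
pipeline_spec <- function(name = c("xdawn_cov_ts_lr", "vec_lr", "cov_lr",
                                   "cov_ts_lr", "xdawn_cov_lr",
                                   "csp_lr"),
                          n_filters = 3L, estimator = "oas",
                          csp_components = 4L, lambda = NULL) {
  name <- match.arg(name)
  stages <- switch(name,
    vec_lr = c("vectorize", "logistic_regression"),
    cov_lr = c("covariance", "vectorize", "logistic_regression"),
    cov_ts_lr = c("covariance", "tangent_space", "logistic_regression"),
    xdawn_cov_lr = c("xdawn", "covariance", "vectorize",
                     "logistic_regression"),
    csp_lr = c("csp", "logistic_regression"),
    xdawn_cov_ts_lr = c("xdawn", "covariance", "tangent_space",
                        "logistic_regression"))
  structure(list(name = name, stages = stages,
                 n_filters = as.integer(n_filters),
                 estimator = estimator,
                 csp_components = as.integer(csp_components),
                 lambda = lambda),
            class = "pipeline_spec")
}

# ---- CSP --------------------------------------------------------------

#' Fit common spatial patterns filters
#'
#' CSP filters are the generalized eigenvectors of the class-0 mean
#' covariance against the pooled (class-0 + class-1) mean covariance;
#' the most discriminative components are the pairs with largest and
#' smallest eigenvalues.  Features are log-variances of the filtered
#' signals.
#'
#' @param epochs training [epoch_set()] with both classes.
#' @param n_components number of retained components (<= channels).
#' @return list of class `csp_model`: `filters` (channels x
#'   n_components), `eigenvalues` (full descending spectrum).
#' @export
fit_csp <- function(epochs, n_components = 4L) {
  stopifnot(inherits(epochs, "epoch_set"))
  e <- dim(epochs$data)[2L]
  if (n_components > e)
    stop("n_components must not exceed the channel count (", e, ")")
  if (length(unique(epochs$labels)) < 2L)
    stop("both classes must be present to fit CSP")
  mean_cov <- function(k) {
    idx <- which(epochs$labels == k)
    Reduce(`+`, lapply(idx, function(i)
      second_moment(trial_matrix(epochs, i)))) / length(idx)
  }
  c0 <- mean_cov(0L); c1 <- mean_cov(1L)
  ge <- gen_eigen_spd(c0, c0 + c1)
  n_top <- ceiling(n_components / 2)
  n_bot <- n_components - n_top
  pick <- c(seq_len(n_top), if (n_bot > 0) e - rev(seq_len(n_bot)) + 1L)
  structure(list(filters = fix_filter_signs(
                   ge$vectors[, pick, drop = FALSE]),
                 eigenvalues = ge$values),
            class = "csp_model")
}

#' CSP log-variance features
#' @param epochs an [epoch_set()].
#' @param model a [fit_csp()] model.
#' @return matrix, trials x components, of log-variances.
#' @export
csp_features <- function(epochs, model) {
  stopifnot(inherits(model, "csp_model"))
  t(vapply(seq_len(n_trials(epochs)), function(i) {
    y <- crossprod(model$filters, trial_matrix(epochs, i))
    log(apply(y, 1L, stats::var))
  }, numeric(ncol(model$filters))))
}

# ---- fit / predict ----------------------------------------------------

trial_covariances <- function(epochs, estimator) {
  lapply(seq_len(n_trials(epochs)), function(i)
    trial_covariance(trial_matrix(epochs, i), estimator))
}

augmented_covariances <- function(epochs, bank, estimator) {
  lapply(seq_len(n_trials(epochs)), function(i)
    trial_covariance(augment_trial(trial_matrix(epochs, i), bank),
                     estimator))
}

unroll <- function(mats) {
  d <- length(as_spd(mats[[1L]]))
  v <- vapply(mats, function(m) as.vector(as_spd(m)), numeric(d))
  if (d == 1L) matrix(v, ncol = 1L) else t(v)
}

# glmnet needs >= 2 predictor columns; pad degenerate feature matrices
# with a constant zero column (no effect on the fit).
pad_features <- function(feats) {
  if (ncol(feats) < 2L) cbind(feats, 0) else feats
}

#' Fit a classification pipeline on training epochs
#'
#' All supervised stages (xDAWN filters and prototypes, CSP filters, the
#' tangent-space reference point, and the classifier) are estimated from
#' `epochs` only, so the fitted model can be applied to held-out data
#' without leakage.
#'
#' @param spec a [pipeline_spec()].
#' @param epochs training [epoch_set()].
#' @return list of class `fitted_pipeline`.
#' @export
fit_pipeline <- function(spec, epochs) {
  stopifnot(inherits(spec, "pipeline_spec"),
            inherits(epochs, "epoch_set"))
  fitted <- list()
  if ("xdawn" %in% spec$stages)
    fitted$bank <- fit_xdawn(epochs, spec$n_filters)
  if ("csp" %in% spec$stages)
    fitted$csp <- fit_csp(epochs, spec$csp_components)
  feats <- pipeline_features(spec, epochs, fitted, fit_reference = TRUE)
  fitted$reference <- attr(feats, "reference")
  lambda <- if (is.null(spec$lambda)) 1 / nrow(feats) else spec$lambda
  fit <- withCallingHandlers(
    glmnet::glmnet(pad_features(feats),
                   factor(epochs$labels, levels = c(0L, 1L)),
                   family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE, thresh = 1e-10),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(spec = spec, fitted = fitted, classifier = fit,
                 lambda = lambda),
            class = "fitted_pipeline")
}

# feature matrix of a (possibly partially fitted) pipeline
pipeline_features <- function(spec, epochs, fitted,
                              fit_reference = FALSE) {
  ref <- NULL
  feats <-
    if ("csp" %in% spec$stages) {
      csp_features(epochs, fitted$csp)
    } else if ("covariance" %in% spec$stages) {
      covs <- if ("xdawn" %in% spec$stages)
        augmented_covariances(epochs, fitted$bank, spec$estimator)
      else trial_covariances(epochs, spec$estimator)
      if ("tangent_space" %in% spec$stages) {
        pr <- tangent_project(covs, ref = if (fit_reference) "fit"
                                          else fitted$reference)
        ref <- pr$reference
        pr$vectors
      } else unroll(covs)
    } else {
      t(vapply(seq_len(n_trials(epochs)),
               function(i) as.vector(trial_matrix(epochs, i)),
               numeric(prod(dim(epochs$data)[2:3]))))
    }
  attr(feats, "reference") <- ref
  feats
}

#' Predict with a fitted pipeline
#' @param model a [fit_pipeline()] result.
#' @param epochs held-out [epoch_set()].
#' @return list: `scores` (linear decision values, > 0 favours class 1),
#'   `predictions` (integer 0/1).
#' @export
predict_pipeline <- function(model, epochs) {
  stopifnot(inherits(model, "fitted_pipeline"))
  feats <- pipeline_features(model$spec, epochs, model$fitted)
  scores <- drop(stats::predict(model$classifier,
                                newx = pad_features(feats),
                                type = "link"))
  list(scores = unname(scores),
       predictions = as.integer(scores > 0))
}

# ---- cross-validation harnesses --------------------------------------

make_report <- function(scheme, folds, labels_all, scores_all,
                        preds_all, spec) {
  fold_acc <- vapply(folds, `[[`, numeric(1L), "accuracy")
  structure(list(scheme = scheme, folds = folds,
                 fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 sd_accuracy = stats::sd(fold_acc),
                 pooled = evaluate_metrics(labels_all, scores_all,
                                           preds_all),
                 pipeline = spec$name),
            class = "cv_report")
}

#' @export
#' @method print cv_report
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s | %s | %d folds\n", x$pipeline, x$scheme,
              length(x$folds)))
  cat(sprintf("  accuracy %.3f +/- %.3f | MCC %.3f | AUC %.3f | AP %.3f\n",
              x$mean_accuracy, x$sd_accuracy, x$pooled$mcc,
              x$pooled$auc, x$pooled$ap))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the pipeline is fitted on all other subjects'
#' trials and evaluated on the held-out subject.  This measures
#' inter-subject generalization.
#'
#' @param epochs an [epoch_set()] with at least 2 subjects.
#' @param spec a [pipeline_spec()].
#' @return list of class `cv_report`: `scheme`, per-fold results
#'   (`subject`, `test_idx`, `accuracy`, `scores`, `predictions`,
#'   `confusion`), `fold_accuracies`, `mean_accuracy`, `sd_accuracy`,
#'   and `pooled` metrics over all held-out trials.
#' @export
run_loso <- function(epochs, spec) {
  stopifnot(inherits(epochs, "epoch_set"))
  subjects <- sort(unique(epochs$subject_ids))
  if (length(subjects) < 2L)
    stop("LOSO needs >= 2 subjects; use run_kfold_per_subject() for ",
         "single-subject data")
  folds <- list()
  lab_all <- integer(0); sco_all <- numeric(0); pred_all <- integer(0)
  for (s in subjects) {
    test_idx <- which(epochs$subject_ids == s)
    train <- subset_trials(epochs, which(epochs$subject_ids != s))
    test <- subset_trials(epochs, test_idx)
    model <- fit_pipeline(spec, train)
    pr <- predict_pipeline(model, test)
    folds[[as.character(s)]] <- list(
      subject = s, test_idx = test_idx,
      accuracy = mean(pr$predictions == test$labels),
      scores = pr$scores, predictions = pr$predictions,
      confusion = confusion_matrix(test$labels, pr$predictions))
    lab_all <- c(lab_all, test$labels)
    sco_all <- c(sco_all, pr$scores)
    pred_all <- c(pred_all, pr$predictions)
  }
  make_report("loso", folds, lab_all, sco_all, pred_all, spec)
}

# stratified fold assignment for one subject's trial indices
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("fewer than ", k, " trials of class ", cl)
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Per-subject stratified k-fold cross-validation
#'
#' For each subject independently, runs seeded stratified k-fold
#' cross-validation of the pipeline on that subject's trials, measuring
#' intra-subject decoding.  Fold-level accuracies (one per subject x
#' fold) are retained for distributional comparisons.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [pipeline_spec()].
#' @param k number of folds (default 4).
#' @param seed integer seed controlling fold assignment.
#' @return `cv_report` as in [run_loso()], scheme `"kfold"`; fold names
#'   are `"<subject>.<fold>"`.
#' @export
run_kfold_per_subject <- function(epochs, spec, k = 4L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  subjects <- sort(unique(epochs$subject_ids))
  folds <- list()
  lab_all <- integer(0); sco_all <- numeric(0); pred_all <- integer(0)
  assignments <- with_seed(seed, {
    lapply(subjects, function(s) {
      idx <- which(epochs$subject_ids == s)
      tryCatch(stratified_folds(epochs$labels[idx], k),
               error = function(err)
                 stop("subject ", s, ": ", conditionMessage(err)))
    })
  })
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    idx <- which(epochs$subject_ids == s)
    fold_of <- assignments[[si]]
    for (f in seq_len(k)) {
      test_idx <- idx[fold_of == f]
      train <- subset_trials(epochs, idx[fold_of != f])
      test <- subset_trials(epochs, test_idx)
      model <- fit_pipeline(spec, train)
      pr <- predict_pipeline(model, test)
      folds[[paste0(s, ".", f)]] <- list(
        subject = s, fold = f, test_idx = test_idx,
        accuracy = mean(pr$predictions == test$labels),
        scores = pr$scores, predictions = pr$predictions,
        confusion = confusion_matrix(test$labels, pr$predictions))
      lab_all <- c(lab_all, test$labels)
      sco_all <- c(sco_all, pr$scores)
      pred_all <- c(pred_all, pr$predictions)
    }
  }
  make_report("kfold", folds, lab_all, sco_all, pred_all, spec)
}

#' Permute class labels (chance-level control)
#'
#' Returns a copy of the epochs with labels randomly permuted across all
#' trials, for building permutation null distributions of accuracy.
#'
#' @param epochs an [epoch_set()].
#' @param seed integer seed.
#' @return [epoch_set()] with permuted labels.
#' @export
permute_labels <- function(epochs, seed) {
  epochs$labels <- with_seed(seed, sample(epochs$labels))
  epochs
}

# ---- higher-level analyses -------------------------------------------

#' Run the standard six-pipeline comparison
#'
#' Evaluates the six [pipeline_spec()] configurations under the selected
#' cross-validation schemes, in sensor space and (if a source simulation
#' is supplied) on region-averaged source activations.
#'
#' @param epochs sensor-space [epoch_set()].
#' @param source_sim optional [simulate_source_epochs()] result; its
#'   epochs are projected through the standardized inverse and averaged
#'   by region before classification.
#' @param schemes subset of `c("loso", "kfold")`.
#' @param pipelines character vector of pipeline names.
#' @param k,seed per-subject k-fold parameters.
#' @param n_filters xDAWN filters per class.
#' @param alpha inverse regularization for the source space.
#' @return list: `table` (data.frame with pipeline, scheme, space,
#'   mean_accuracy, sd_accuracy, mcc, auc, ap), `reports` (named list of
#'   `cv_report`s, names `<pipeline>.<scheme>.<space>`).
#' @export
run_comparison_suite <- function(epochs, source_sim = NULL,
                                 schemes = c("loso", "kfold"),
                                 pipelines = c("vec_lr", "cov_lr",
                                               "cov_ts_lr",
                                               "xdawn_cov_lr", "csp_lr",
                                               "xdawn_cov_ts_lr"),
                                 k = 4L, seed = 1L, n_filters = 3L,
                                 alpha = NULL) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  spaces <- list(sensor = epochs)
  if (!is.null(source_sim))
    spaces$source <- project_to_regions(source_sim$epochs,
                                        source_sim$leadfield, alpha)
  reports <- list()
  rows <- list()
  for (space in names(spaces)) {
    for (pn in pipelines) {
      spec <- pipeline_spec(pn, n_filters = n_filters)
      for (sch in schemes) {
        rep_ <- if (sch == "loso") run_loso(spaces[[space]], spec)
                else run_kfold_per_subject(spaces[[space]], spec, k, seed)
        key <- paste(pn, sch, space, sep = ".")
        reports[[key]] <- rep_
        rows[[key]] <- data.frame(
          pipeline = pn, scheme = sch, space = space,
          mean_accuracy = rep_$mean_accuracy,
          sd_accuracy = rep_$sd_accuracy,
          mcc = rep_$pooled$mcc, auc = rep_$pooled$auc,
          ap = rep_$pooled$ap, stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}

#' Greedy forward electrode selection
#'
#' At each step, adds the electrode that maximizes the LOSO accuracy of
#' the pipeline restricted to the selected set (first-index tie-break),
#' up to `max_k` electrodes.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [pipeline_spec()].  With a single selected channel,
#'   xDAWN/CSP stages are fitted with 1 filter/component.
#' @param max_k maximum number of electrodes to select.
#' @return list: `order` (character, selection order), `accuracy`
#'   (numeric, LOSO accuracy after each addition).
#' @export
forward_electrode_selection <- function(epochs, spec,
                                        max_k = length(epochs$channel_names)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (max_k > length(epochs$channel_names))
    stop("max_k exceeds the channel count")
  selected <- character(0)
  acc <- numeric(0)
  for (step in seq_len(max_k)) {
    cand <- setdiff(epochs$channel_names, selected)
    cand_acc <- vapply(cand, function(ch) {
      sub <- select_channels(epochs, c(selected, ch))
      run_loso(sub, shrink_spec(spec, length(selected) + 1L))$mean_accuracy
    }, numeric(1L))
    best <- which.max(cand_acc)
    selected <- c(selected, cand[best])
    acc <- c(acc, cand_acc[best])
  }
  list(order = selected, accuracy = unname(acc))
}

# cap filter/component counts at the current channel count
shrink_spec <- function(spec, n_channels) {
  spec$n_filters <- min(spec$n_filters, n_channels)
  spec$csp_components <- min(spec$csp_components, n_channels)
  spec
}

#' LOSO accuracy per scalp-region electrode triad
#'
#' Runs the pipeline restricted to each named electrode triad (occipital,
#' parietal, central, frontal by default) and reports the LOSO accuracy,
#' localizing where the discriminative signal lies on the scalp.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [pipeline_spec()].
#' @param triads named list of channel-name vectors.
#' @return data.frame: `region`, `mean_accuracy`, `sd_accuracy`.
#' @export
region_triad_analysis <- function(epochs, spec,
                                  triads = list(
                                    occipital = c("O1", "O2", "Oz"),
                                    parietal = c("P3", "P4", "Pz"),
                                    central = c("C3", "C4", "Cz"),
                                    frontal = c("F3", "F4", "Fz"))) {
  rows <- lapply(names(triads), function(rg) {
    sub <- select_channels(epochs, triads[[rg]])
    rep_ <- run_loso(sub, shrink_spec(spec, length(triads[[rg]])))
    data.frame(region = rg, mean_accuracy = rep_$mean_accuracy,
               sd_accuracy = rep_$sd_accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
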
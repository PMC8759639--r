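#' Write / read the canonical epoch container
#'
#' The canonical on-disk interchange for an [epoch_set()] is a directory
#' with a documented hierarchical layout:
#' \describe{
#'   \item{`meta.json`}{schema version, array dimensions, sampling_rate,
#'     t0_offset, storage conventions.}
#'   \item{`data.bin`}{the trial tensor as little-endian float64 in R
#'     column-major order of (trials, channels, samples).}
#'   \item{`channels.txt`}{channel names, one per line, in order.}
#'   \item{`labels.txt`}{per-trial class labels (0/1), one per line.}
#'   \item{`subject_ids.txt`}{per-trial subject indices, one per line.}
#' }
#' The round trip is bit-exact and writes are deterministic given equal
#' input.
#'
#' @param epochs an [epoch_set()].
#' @param path directory to create/populate (for `write_epochs`) or read
#'   (for `read_epochs`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs`
#'   returns the reconstructed [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = "1.0",
               container = "epoch_set",
               dims = dim(epochs$data),
               sampling_rate = epochs$sampling_rate,
               t0_offset = epochs$t0_offset,
               storage = "float64 little-endian, column-major (trials, channels, samples)")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "meta.json"))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  writeLines(epochs$channel_names, file.path(path, "channels.txt"))
  writeLines(as.character(epochs$labels), file.path(path, "labels.txt"))
  writeLines(as.character(epochs$subject_ids),
             file.path(path, "subject_ids.txt"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  need <- c("meta.json", "data.bin", "channels.txt", "labels.txt",
            "subject_ids.txt")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0L)
    stop("malformed epoch container ", path, ": missing member(s) ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  dims <- as.integer(meta$dims)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = prod(dims), size = 8L,
                 endian = "little")
  epoch_set(array(raw, dim = dims),
            labels = as.integer(readLines(file.path(path, "labels.txt"))),
            subject_ids = as.integer(readLines(file.path(path,
                                                         "subject_ids.txt"))),
            channel_names = readLines(file.path(path, "channels.txt")),
            sampling_rate = meta$sampling_rate,
            t0_offset = meta$t0_offset)
}

#' Write / read a cross-validation report as JSON
#'
#' Serializes a `cv_report` (see [run_loso()]) to a schema-versioned
#' JSON file with stable key order and full numeric precision; the
#' report can be re-loaded to an equal object, and ROC/PR curves are
#' stored as coordinate-pair lists from which AUC/AP can be recomputed.
#'
#' @param report a `cv_report`.
#' @param path file path to write / read.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   reconstructed `cv_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  payload <- list(
    schema_version = "1.0",
    scheme = report$scheme,
    pipeline = report$pipeline,
    mean_accuracy = report$mean_accuracy,
    sd_accuracy = report$sd_accuracy,
    fold_accuracies = as.list(report$fold_accuracies),
    folds = lapply(report$folds, function(f) {
      f$confusion <- as.vector(f$confusion)  # tn, fn, fp, tp (col-major)
      f
    }),
    pooled = list(
      confusion = as.vector(report$pooled$confusion),
      accuracy = report$pooled$accuracy,
      mcc = report$pooled$mcc,
      auc = report$pooled$auc,
      ap = report$pooled$ap,
      roc = report$pooled$roc,
      pr = report$pooled$pr))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", pretty = TRUE),
             path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(p$schema_version))
    stop("not a cv_report file: missing schema_version")
  conf <- function(v) matrix(as.integer(v), 2L, 2L,
                             dimnames = list(truth = c("0", "1"),
                                             predicted = c("0", "1")))
  folds <- lapply(p$folds, function(f) {
    f$confusion <- conf(f$confusion)
    f$test_idx <- as.integer(f$test_idx)
    f$predictions <- as.integer(f$predictions)
    f
  })
  pooled <- structure(list(
    confusion = conf(p$pooled$confusion),
    accuracy = p$pooled$accuracy, mcc = p$pooled$mcc,
    auc = p$pooled$auc, ap = p$pooled$ap,
    roc = as.data.frame(p$pooled$roc),
    pr = as.data.frame(p$pooled$pr)), class = "metric_bundle")
  structure(list(scheme = p$scheme, folds = folds,
                 fold_accuracies = unlist(p$fold_accuracies),
                 mean_accuracy = p$mean_accuracy,
                 sd_accuracy = p$sd_accuracy,
                 pooled = pooled, pipeline = p$pipeline),
            class = "cv_report")
}
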
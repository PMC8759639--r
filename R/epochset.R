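#' Labelled multi-subject epoched EEG container
#'
#' An `epoch_set` bundles a trial tensor with its class labels, subject
#' identifiers and sampling metadata.  It is the raw material of every
#' pipeline in the package: preprocessing, spatial filtering and
#' cross-validation all consume and return `epoch_set` objects.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param labels integer vector of per-trial class labels, `0` or `1`
#'   (convention: 0 = Checkerboard-like class, 1 = Tunnel-like class).
#' @param subject_ids integer vector of per-trial subject indices.
#' @param channel_names character vector naming the channel axis.
#' @param sampling_rate sampling rate in Hz, positive scalar.
#' @param t0_offset time of the first sample relative to the stimulus, in
#'   seconds (negative values mean pre-stimulus samples are present).
#'
#' @return An object of class `epoch_set`: a list with the fields above.
#' @examples
#' x <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
#' ep <- epoch_set(x, labels = c(0L, 1L), subject_ids = c(1L, 1L),
#'                 channel_names = c("C3", "Cz", "C4"),
#'                 sampling_rate = 100, t0_offset = 0)
#' ep
#' @export
epoch_set <- function(data, labels, subject_ids, channel_names,
                      sampling_rate, t0_offset = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  subject_ids <- as.integer(subject_ids)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials")
  if (length(subject_ids) != dim(data)[1L])
    stop("length(subject_ids) must equal the number of trials")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  if (length(channel_names) != dim(data)[2L])
    stop("length(channel_names) must equal the number of channels")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar")
  structure(
    list(data = data, labels = labels, subject_ids = subject_ids,
         channel_names = as.character(channel_names),
         sampling_rate = as.numeric(sampling_rate),
         t0_offset = as.numeric(t0_offset)),
    class = "epoch_set")
}

#' @export
#' @method print epoch_set
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$sampling_rate))
  cat(sprintf("  time span: [%.3f, %.3f) s relative to stimulus\n",
              x$t0_offset, x$t0_offset + d[3L] / x$sampling_rate))
  tab <- table(factor(x$labels, levels = c(0L, 1L)))
  cat(sprintf("  classes: %d / %d (0/1); subjects: %d\n",
              tab[[1L]], tab[[2L]], length(unique(x$subject_ids))))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Number of trials in an epoch set
#' @param x an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Time axis of an epoch set
#' @param x an `epoch_set`.
#' @return numeric vector of sample times in seconds relative to stimulus.
#' @export
epoch_times <- function(x) {
  x$t0_offset + (seq_len(dim(x$data)[3L]) - 1L) / x$sampling_rate
}

#' Subset trials of an epoch set
#'
#' @param x an `epoch_set`.
#' @param idx integer vector of trial indices to keep (order preserved).
#' @return `epoch_set` restricted to the selected trials.
#' @export
subset_trials <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("cannot select zero trials")
  if (any(idx < 1L | idx > n_trials(x))) stop("trial index out of range")
  epoch_set(x$data[idx, , , drop = FALSE], x$labels[idx],
            x$subject_ids[idx], x$channel_names, x$sampling_rate,
            x$t0_offset)
}

# single trial as a channels x samples matrix
trial_matrix <- function(x, i) {
  m <- x$data[i, , ]
  dim(m) <- dim(x$data)[2:3]
  m
}
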
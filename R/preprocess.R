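#' Zero-phase band-pass filtering of epoched EEG
#'
#' Applies a 4th-order Butterworth band-pass filter forward and backward
#' (zero phase) along the time axis of every trial and channel.  The
#' classical conditioning for visual-ERP work uses a 1-45 Hz band.
#'
#' @param epochs an [epoch_set()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sampling_rate / 2`.
#' @param order filter order of the underlying Butterworth design
#'   (applied twice by the forward-backward pass).
#' @return the filtered [epoch_set()], shape and metadata unchanged.
#' @export
bandpass_filter <- function(epochs, low_hz = 1, high_hz = 45, order = 4L) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sampling_rate / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (",
         nyq, " Hz)")
  bt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  d <- epochs$data
  dd <- dim(d)
  for (i in seq_len(dd[1L]))
    for (ch in seq_len(dd[2L]))
      d[i, ch, ] <- signal::filtfilt(bt, d[i, ch, ])
  epochs$data <- d
  epochs
}

#' Baseline correction of epoched EEG
#'
#' For every trial and channel, subtracts the mean over the given
#' (typically pre-stimulus) window from the whole trace.
#'
#' @param epochs an [epoch_set()].
#' @param window length-2 numeric, baseline window in seconds relative to
#'   the stimulus; must lie inside the epoch's time span.  Defaults to the
#'   full pre-stimulus interval.
#' @return baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(epochs$t0_offset, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  tt <- epoch_times(epochs)
  idx <- which(tt >= window[1L] & tt < window[2L])
  if (length(idx) == 0L)
    stop("baseline window [", window[1L], ", ", window[2L],
         ") contains no samples of the epoch span")
  mu <- apply(epochs$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - as.vector(mu)  # recycles over time axis
  epochs
}

#' Crop the time axis of epoched EEG
#'
#' Restricts every trial to the half-open interval `[t_start, t_end)`;
#' a sample at time `t` is kept iff `t_start <= t < t_end`.
#'
#' @param epochs an [epoch_set()].
#' @param t_start,t_end crop interval in seconds relative to the stimulus.
#' @return cropped [epoch_set()] with `t0_offset` updated.
#' @export
crop_epochs <- function(epochs, t_start, t_end) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!(t_start < t_end)) stop("t_start must be < t_end")
  tt <- epoch_times(epochs)
  idx <- which(tt >= t_start - 1e-12 & tt < t_end - 1e-12)
  if (length(idx) == 0L)
    stop("crop interval [", t_start, ", ", t_end,
         ") contains no samples")
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$t0_offset <- tt[idx[1L]]
  epochs
}

#' Select and reorder channels
#'
#' @param epochs an [epoch_set()].
#' @param names channel names to keep, in the desired output order.
#' @return [epoch_set()] restricted to `names`, rows reordered to match.
#' @export
select_channels <- function(epochs, names) {
  stopifnot(inherits(epochs, "epoch_set"))
  pos <- match(names, epochs$channel_names)
  if (anyNA(pos))
    stop("unknown channel name(s): ",
         paste(names[is.na(pos)], collapse = ", "))
  epochs$data <- epochs$data[, pos, , drop = FALSE]
  epochs$channel_names <- epochs$channel_names[pos]
  epochs
}

#' Balance class counts by randomized undersampling
#'
#' Independently for each subject, randomly removes trials from the
#' majority class until both classes have equal counts.  Minority-class
#' trials are never touched and the within-class trial order is
#' preserved.  Deterministic for a fixed seed.
#'
#' @param epochs an [epoch_set()].
#' @param seed integer seed controlling which majority trials are kept.
#' @return balanced [epoch_set()].
#' @export
balance_classes <- function(epochs, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- with_seed(seed, {
    out <- integer(0)
    for (s in sort(unique(epochs$subject_ids))) {
      si <- which(epochs$subject_ids == s)
      i0 <- si[epochs$labels[si] == 0L]
      i1 <- si[epochs$labels[si] == 1L]
      if (length(i0) == 0L || length(i1) == 0L)
        stop("subject ", s, " lacks one of the two classes")
      n <- min(length(i0), length(i1))
      out <- c(out,
               if (length(i0) > n) sort(sample(i0, n)) else i0,
               if (length(i1) > n) sort(sample(i1, n)) else i1)
    }
    sort(out)
  })
  subset_trials(epochs, keep)
}
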
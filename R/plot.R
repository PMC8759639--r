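#' Plot class-average evoked potentials of one channel
#'
#' Draws the two class-average (grand-average) waveforms of the chosen
#' channel, optionally over a spaghetti background of single trials --
#' the classical picture contrasting trial-level variability with the
#' averaged evoked response.
#'
#' @param epochs an [epoch_set()].
#' @param channel channel name to display (default `"Oz"` if present,
#'   else the first channel).
#' @param n_single number of randomly chosen single trials per class to
#'   draw in the background (0 for none).
#' @param seed seed for the single-trial subsample.
#' @return invisibly, a list with the two class-average traces.
#' @export
plot_erp <- function(epochs, channel = NULL, n_single = 0L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(channel))
    channel <- if ("Oz" %in% epochs$channel_names) "Oz"
               else epochs$channel_names[1L]
  ch <- match(channel, epochs$channel_names)
  if (is.na(ch)) stop("unknown channel: ", channel)
  tt <- epoch_times(epochs) * 1000
  avg <- lapply(0:1, function(k)
    class_average(epochs, k)$matrix[ch, ])
  ylim <- range(unlist(avg))
  cols <- c("#2166ac", "#b2182b")
  if (n_single > 0L) {
    sel <- with_seed(seed, lapply(0:1, function(k) {
      idx <- which(epochs$labels == k)
      sample(idx, min(n_single, length(idx)))
    }))
    ylim <- range(epochs$data[unlist(sel), ch, ])
  }
  graphics::plot(tt, avg[[1L]], type = "n", ylim = ylim,
                 xlab = "time (ms)", ylab = "amplitude (µV)",
                 main = paste0(channel, ": class averages"))
  if (n_single > 0L)
    for (k in 1:2)
      for (i in sel[[k]])
        graphics::lines(tt, epochs$data[i, ch, ],
                        col = grDevices::adjustcolor(cols[k], 0.15))
  graphics::lines(tt, avg[[1L]], col = cols[1L], lwd = 2)
  graphics::lines(tt, avg[[2L]], col = cols[2L], lwd = 2)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = c("class 0", "class 1"),
                   col = cols, lwd = 2, bty = "n")
  invisible(list(class0 = avg[[1L]], class1 = avg[[2L]]))
}
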
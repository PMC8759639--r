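#' Configuration for the synthetic visual-ERP generator
#'
#' Builds the parameter set describing a simulated two-class visual-ERP
#' experiment: per-class ERP templates (sums of Gaussian-windowed bumps),
#' a scalp topography profile, background and sensor noise, and the
#' between-subject / between-trial variability that makes pooled single
#' trials hard to separate while within-subject trials remain easy.
#'
#' The defaults emulate a passive visual paradigm with 15 subjects, 96
#' trials of a checkerboard-like stimulus and 192 trials of a
#' navigation-tunnel-like stimulus per subject, 12 standard 10-20
#' electrodes, and 1-second epochs spanning -500 ms to +500 ms around the
#' stimulus.  Class 0 carries a large monophasic P100 followed by a P220;
#' class 1 carries a smaller biphasic 100/140 ms complex followed by a
#' P220.  Both are occipitally dominant.
#'
#' @param n_subjects number of simulated subjects.
#' @param trials_per_class length-2 integer vector: trials per subject for
#'   class 0 and class 1.
#' @param channels ordered character vector of channel names.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window length-2 numeric, epoch span in seconds relative to
#'   the stimulus; must straddle 0 so baseline correction is exercisable.
#' @param templates list with elements `class0` and `class1`, each a
#'   data.frame with columns `latency_ms`, `width_ms` (Gaussian SD) and
#'   `amplitude_uv`.  Latencies must fall inside the post-stimulus window.
#' @param topography named numeric vector of per-channel gains applied to
#'   every template bump (occipital >> parietal > central/frontal by
#'   default).  Names must match `channels`.
#' @param noise list: `spectral_exponent` (gamma of the 1/f^gamma
#'   background), `background_sd_uv` (per-channel background SD),
#'   `sensor_sd_uv` (white sensor noise SD).
#' @param subject_var list of between-subject variability parameters:
#'   `gain_sdlog` (log-SD of per-channel lognormal gains),
#'   `mixing_sd` (scale of the random orthogonal perturbation of the
#'   spatial mixing), `amp_sdlog` (log-SD of a per-subject global
#'   amplitude gain), `latency_sd_ms` (SD of a per-subject latency
#'   offset).
#' @param trial_var list of per-trial variability parameters:
#'   `amp_sdlog` (log-SD of the per-trial amplitude gain),
#'   `latency_sd_ms` (SD of per-trial latency jitter).
#' @param seed integer seed used by [simulate_epochs()] by default.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_epochs()], [simulate_source_epochs()]
#' @export
sim_config <- function(n_subjects = 15L,
                       trials_per_class = c(96L, 192L),
                       channels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                    "P3", "Pz", "P4", "O1", "Oz", "O2"),
                       sampling_rate = 512,
                       epoch_window = c(-0.5, 0.5),
                       templates = default_templates(),
                       topography = default_topography(channels),
                       noise = list(spectral_exponent = 1,
                                    background_sd_uv = 4,
                                    sensor_sd_uv = 1),
                       subject_var = list(gain_sdlog = 0.4,
                                          mixing_sd = 0.25,
                                          amp_sdlog = 0.3,
                                          latency_sd_ms = 25),
                       trial_var = list(amp_sdlog = 0.25,
                                        latency_sd_ms = 10),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_class = as.integer(trials_per_class),
              channels = as.character(channels),
              sampling_rate = as.numeric(sampling_rate),
              epoch_window = as.numeric(epoch_window),
              templates = templates, topography = topography,
              noise = noise, subject_var = subject_var,
              trial_var = trial_var, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default two-class ERP bump templates
#'
#' Class 0: large monophasic positive deflection at 100 ms plus a 220 ms
#' bump.  Class 1: smaller negative/positive biphasic pair at 100/140 ms
#' plus a 220 ms bump.  Widths are Gaussian SDs in ms.
#' @return list with data.frames `class0` and `class1`.
#' @export
default_templates <- function() {
  list(
    class0 = data.frame(latency_ms = c(100, 220),
                        width_ms = c(15, 25),
                        amplitude_uv = c(8, 3)),
    class1 = data.frame(latency_ms = c(100, 140, 220),
                        width_ms = c(12, 12, 25),
                        amplitude_uv = c(-3, 3.5, 3)))
}

#' Default occipitally dominant topography profile
#' @param channels channel names; gains are assigned by 10-20 prefix
#'   (O: 1.0, P: 0.55, C: 0.3, F: 0.15; unknown prefixes get 0.3).
#' @return named numeric gain vector.
#' @export
default_topography <- function(channels) {
  pre <- substr(channels, 1L, 1L)
  g <- c(O = 1.0, P = 0.55, C = 0.3, F = 0.15)[pre]
  g[is.na(g)] <- 0.3
  names(g) <- channels
  g
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (length(cfg$trials_per_class) != 2L || any(cfg$trials_per_class < 1L))
    stop("trials_per_class must be two positive counts")
  if (length(cfg$channels) < 1L || anyDuplicated(cfg$channels))
    stop("channels must be a non-empty set of unique names")
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be positive")
  w <- cfg$epoch_window
  if (length(w) != 2L || !(w[1L] < 0 && 0 < w[2L]))
    stop("epoch_window must satisfy start < 0 < end")
  for (k in c("class0", "class1")) {
    tp <- cfg$templates[[k]]
    if (is.null(tp) || !all(c("latency_ms", "width_ms", "amplitude_uv")
                            %in% names(tp)))
      stop("templates$", k,
           " must have latency_ms, width_ms, amplitude_uv")
    if (any(tp$latency_ms / 1000 <= 0 | tp$latency_ms / 1000 >= w[2L]))
      stop("template latencies must lie inside the post-stimulus window")
    if (any(tp$width_ms <= 0)) stop("template widths must be positive")
  }
  if (length(cfg$topography) != length(cfg$channels))
    stop("topography length must equal channel count")
  sds <- c(cfg$noise$background_sd_uv, cfg$noise$sensor_sd_uv,
           cfg$subject_var$gain_sdlog, cfg$subject_var$mixing_sd,
           cfg$subject_var$amp_sdlog, cfg$subject_var$latency_sd_ms,
           cfg$trial_var$amp_sdlog, cfg$trial_var$latency_sd_ms)
  if (any(sds < 0)) stop("all SD-like parameters must be >= 0")
  invisible(cfg)
}

# Evaluate a bump template as channels x samples, with a latency shift (s)
# and a multiplicative amplitude gain applied to all bumps.
template_matrix <- function(bumps, topography, times, lat_shift = 0,
                            amp_gain = 1) {
  out <- matrix(0, nrow = length(topography), ncol = length(times))
  for (b in seq_len(nrow(bumps))) {
    lat <- bumps$latency_ms[b] / 1000 + lat_shift
    sd_s <- bumps$width_ms[b] / 1000
    wave <- exp(-0.5 * ((times - lat) / sd_s)^2)
    out <- out + (amp_gain * bumps$amplitude_uv[b]) *
      outer(unname(topography), wave)
  }
  out
}

# 1/f^gamma background noise, one channel, length n.  Spectral weights are
# normalized so the marginal variance equals sd^2.
pink_noise <- function(n, sd, gamma) {
  if (sd == 0) return(numeric(n))
  x <- stats::rnorm(n)
  if (gamma == 0) return(sd * x)
  j <- seq_len(n) - 1L
  f <- pmin(j, n - j)                   # folded (two-sided) frequency bin
  w <- ifelse(f == 0, 0, f^(-gamma / 2))
  w <- w / sqrt(mean(w^2))              # marginal variance ~ sd^2
  y <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
  sd * y
}

# Random orthogonal matrix near identity: QR of I + scale * N(0,1), with
# positive diagonal sign fix so scale = 0 gives the identity exactly.
near_identity_rotation <- function(n, scale) {
  if (scale == 0) return(diag(n))
  qr_ <- qr(diag(n) + scale * matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), n)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate synthetic multi-subject two-class epoched EEG
#'
#' Each trial is built as `A_s %*% S + noise`, where `S` is the class
#' template evaluated with per-subject and per-trial latency/amplitude
#' jitter, and `A_s = R_s %*% diag(g_s)` is a per-subject spatial mixing:
#' lognormal channel gains `g_s` composed with a random orthogonal
#' perturbation `R_s`.  Background noise is per-channel 1/f^gamma
#' filtered Gaussian noise plus white sensor noise.  With all variability
#' and noise parameters at zero every trial equals its class template
#' exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.  Identical
#'   config + seed gives bit-identical output.
#' @return An [epoch_set()].  Trials are ordered by subject, class 0
#'   first within subject.
#' @examples
#' cfg <- sim_config(n_subjects = 2, trials_per_class = c(8, 16),
#'                   sampling_rate = 128)
#' ep <- simulate_epochs(cfg, seed = 7)
#' ep
#' @export
simulate_epochs <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    fs <- config$sampling_rate
    times <- seq(config$epoch_window[1L],
                 config$epoch_window[2L] - 1 / fs, by = 1 / fs)
    nt <- length(times)
    e <- length(config$channels)
    sv <- config$subject_var
    tv <- config$trial_var
    per_subj <- sum(config$trials_per_class)
    n_all <- config$n_subjects * per_subj

    # subject-level parameters drawn first, in subject order
    subj <- lapply(seq_len(config$n_subjects), function(s) {
      gains <- exp(stats::rnorm(e, 0, sv$gain_sdlog))
      rot <- near_identity_rotation(e, sv$mixing_sd)
      list(mix = rot %*% diag(gains, e),
           amp = exp(stats::rnorm(1, 0, sv$amp_sdlog)),
           lat = stats::rnorm(1, 0, sv$latency_sd_ms) / 1000)
    })

    data <- array(0, dim = c(n_all, e, nt))
    labels <- integer(n_all)
    subject_ids <- integer(n_all)
    i <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (k in 0:1) {
        bumps <- config$templates[[paste0("class", k)]]
        for (tr in seq_len(config$trials_per_class[k + 1L])) {
          i <- i + 1L
          amp <- subj[[s]]$amp * exp(stats::rnorm(1, 0, tv$amp_sdlog))
          lat <- subj[[s]]$lat + stats::rnorm(1, 0, tv$latency_sd_ms) / 1000
          sig <- subj[[s]]$mix %*%
            template_matrix(bumps, config$topography, times, lat, amp)
          bg <- t(vapply(seq_len(e), function(ch)
            pink_noise(nt, config$noise$background_sd_uv,
                       config$noise$spectral_exponent),
            numeric(nt)))
          wn <- if (config$noise$sensor_sd_uv > 0)
            matrix(stats::rnorm(e * nt, 0, config$noise$sensor_sd_uv),
                   e, nt) else 0
          data[i, , ] <- sig + bg + wn
          labels[i] <- k
          subject_ids[i] <- s
        }
      }
    }
    epoch_set(data, labels, subject_ids, config$channels, fs, times[1L])
  })
}

#' Generate a source-space simulation with known ground truth
#'
#' Builds a random well-conditioned lead field `K` (channels x 3*n_voxels,
#' three orthogonal dipole orientations per voxel), places the two class
#' templates' time courses on one designated voxel per class (with the
#' same per-trial jitter model as [simulate_epochs()]), projects to the
#' sensors and adds white sensor noise.  The returned object carries both
#' spaces plus the ground-truth active voxels, so inverse solutions can be
#' validated exactly.
#'
#' @param config a [sim_config()]; its channel list, window, templates and
#'   trial variability are reused.  Background (1/f) noise is not added in
#'   source space; only `noise$sensor_sd_uv` white noise is applied at the
#'   sensors.
#' @param n_voxels number of source voxels (>= 2).
#' @param n_regions number of atlas-like regions the voxels are divided
#'   into (contiguous blocks).
#' @param active_voxels length-2 integer vector: the active voxel for
#'   class 0 and class 1.  Defaults to the first and last voxel.
#' @param max_condition maximum accepted 2-norm condition number of `K`.
#' @param max_retries attempts at drawing a well-conditioned `K`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list of class `source_sim` with elements `epochs`
#'   ([epoch_set()]), `sources` (trials x 3M x samples array), `leadfield`
#'   (see [lead_field()]) and `active_voxels`.
#' @export
simulate_source_epochs <- function(config, n_voxels, n_regions = 2L,
                                   active_voxels = c(1L, n_voxels),
                                   max_condition = 1e4, max_retries = 20L,
                                   seed = config$seed) {
  validate_sim_config(config)
  if (n_voxels < 2L) stop("n_voxels must be >= 2")
  e <- length(config$channels)
  if (e < 3L) stop("at least 3 channels are required")
  if (any(active_voxels < 1L | active_voxels > n_voxels))
    stop("active_voxels out of range")
  with_seed(seed, {
    k_mat <- NULL
    for (att in seq_len(max_retries)) {
      cand <- matrix(stats::rnorm(e * 3L * n_voxels), e, 3L * n_voxels)
      if (kappa(cand, exact = TRUE) <= max_condition) { k_mat <- cand; break }
    }
    if (is.null(k_mat))
      stop("could not draw a lead field with condition number <= ",
           max_condition, " in ", max_retries, " attempts")
    lf <- lead_field(k_mat,
                     voxel_positions = matrix(stats::rnorm(3L * n_voxels),
                                              n_voxels, 3L),
                     region_labels = sort(rep(seq_len(n_regions),
                                              length.out = n_voxels)))

    fs <- config$sampling_rate
    times <- seq(config$epoch_window[1L],
                 config$epoch_window[2L] - 1 / fs, by = 1 / fs)
    nt <- length(times)
    tv <- config$trial_var
    per_subj <- sum(config$trials_per_class)
    n_all <- config$n_subjects * per_subj
    # fixed unit orientation per active voxel
    orient <- lapply(1:2, function(k) {
      v <- stats::rnorm(3L); v / sqrt(sum(v^2))
    })

    sources <- array(0, dim = c(n_all, 3L * n_voxels, nt))
    data <- array(0, dim = c(n_all, e, nt))
    labels <- integer(n_all); subject_ids <- integer(n_all)
    i <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (k in 0:1) {
        bumps <- config$templates[[paste0("class", k)]]
        vox <- active_voxels[k + 1L]
        rows <- (3L * (vox - 1L) + 1L):(3L * vox)
        for (tr in seq_len(config$trials_per_class[k + 1L])) {
          i <- i + 1L
          amp <- exp(stats::rnorm(1, 0, tv$amp_sdlog))
          lat <- stats::rnorm(1, 0, tv$latency_sd_ms) / 1000
          wave <- colSums(template_matrix(bumps, 1, times, lat, amp))
          sources[i, rows, ] <- outer(orient[[k + 1L]], wave)
          src <- matrix(sources[i, , ], 3L * n_voxels, nt)
          wn <- if (config$noise$sensor_sd_uv > 0)
            matrix(stats::rnorm(e * nt, 0, config$noise$sensor_sd_uv),
                   e, nt) else 0
          data[i, , ] <- k_mat %*% src + wn
          labels[i] <- k
          subject_ids[i] <- s
        }
      }
    }
    structure(list(
      epochs = epoch_set(data, labels, subject_ids, config$channels,
                         fs, times[1L]),
      sources = sources, leadfield = lf,
      active_voxels = as.integer(active_voxels)),
      class = "source_sim")
  })
}
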
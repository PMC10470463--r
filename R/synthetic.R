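#' Specification of the synthetic two-class EEG task
#'
#' Seeded generator of EEG-like samples with implanted, mask-annotated
#' class-discriminative features on a 1/f (pink-noise) background. The
#' default task contrasts an "alert-like" class carrying broadband EMG-style
#' high-frequency bursts (25-45 Hz) with a "drowsy-like" class carrying alpha
#' spindles (~10 Hz carrier under a raised-cosine, waxing-and-waning
#' envelope). A `blink_pulse` feature kind (low-frequency transient on
#' frontal channels) is also available. Every feature's support is recorded
#' in a binary ground-truth mask, enabling localization scoring of
#' attribution maps.
#'
#' @param n_channels number of EEG channels.
#' @param n_timepoints sample length in points.
#' @param sampling_rate sampling rate in Hz.
#' @param feature_kinds character vector, one feature kind per class, each of
#'   `"alpha_spindle"`, `"blink_pulse"`, `"emg_noise"`.
#' @param feature_channels list of integer channel sets, one per class.
#' @param snr amplitude ratio of feature to background standard deviation
#'   (>= 0; 0 yields pure background).
#' @param background_sd background standard deviation in microvolts.
#' @param class_balance proportion of samples assigned to class 1.
#' @param seed master RNG seed; per-sample seeds are derived from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 8L, n_timepoints = 256L,
                           sampling_rate = 128,
                           feature_kinds = c("emg_noise", "alpha_spindle"),
                           feature_channels = list(c(1L, 2L, 7L, 8L),
                                                   c(3L, 6L)),
                           snr = 2, background_sd = 10,
                           class_balance = 0.5, seed = 1L) {
  kinds <- c("alpha_spindle", "blink_pulse", "emg_noise")
  stopifnot(n_channels >= 1, n_timepoints >= 8, sampling_rate > 0,
            length(feature_kinds) >= 2,
            all(feature_kinds %in% kinds),
            length(feature_channels) == length(feature_kinds),
            snr >= 0, background_sd > 0,
            class_balance > 0, class_balance < 1)
  for (chs in feature_channels) {
    if (any(chs < 1L | chs > n_channels)) {
      stop("configuration error: feature_channels outside 1..n_channels",
           call. = FALSE)
    }
  }
  structure(list(n_channels = as.integer(n_channels),
                 n_timepoints = as.integer(n_timepoints),
                 sampling_rate = as.numeric(sampling_rate),
                 feature_kinds = feature_kinds,
                 feature_channels = lapply(feature_channels, as.integer),
                 snr = snr, background_sd = background_sd,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 1/f-amplitude (pink) noise of length T with standard deviation sd, drawn
# from the current RNG stream via spectral shaping of white noise.
.pink_noise <- function(T, sd = 1) {
  w <- stats::rnorm(T)
  W <- stats::fft(w)
  k <- c(0, seq_len(T - 1))
  f <- pmin(k, T - k)                 # symmetric frequency index
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / T
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

.raised_cosine <- function(L) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
}

# Band-limit white noise to [lo, hi] Hz via FFT masking.
.band_noise <- function(L, fs, lo, hi) {
  w <- stats::rnorm(L)
  W <- stats::fft(w)
  k <- c(0, seq_len(L - 1))
  f <- pmin(k, L - k) * fs / L
  W[f < lo | f > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / L
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

#' Generate one synthetic EEG sample with its ground-truth mask
#'
#' @param spec a [synthetic_spec()].
#' @param class_label 1-based class index.
#' @param seed RNG seed for this sample.
#' @return list with elements `sample` (an [eeg_sample], label set), `mask`
#'   (binary N x T matrix marking the implanted feature support) and
#'   `background` (the pure pink-noise draw, for residual checks).
#' @export
generate_sample <- function(spec, class_label, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  class_label <- as.integer(class_label)
  if (class_label < 1L || class_label > length(spec$feature_kinds)) {
    stop("configuration error: class_label out of range", call. = FALSE)
  }
  N <- spec$n_channels; T <- spec$n_timepoints; fs <- spec$sampling_rate
  old <- .seed_push(seed)
  on.exit(.seed_pop(old), add = TRUE)

  bg <- t(vapply(seq_len(N), function(i) .pink_noise(T, spec$background_sd),
                 numeric(T)))
  values <- bg
  mask <- matrix(0L, N, T)
  kind <- spec$feature_kinds[class_label]
  chans <- spec$feature_channels[[class_label]]
  amp <- spec$snr * spec$background_sd

  dur_range <- switch(kind,
    alpha_spindle = c(0.5, 1.5),
    emg_noise = c(0.5, 1.5),
    blink_pulse = c(0.2, 0.4))
  L <- round(stats::runif(1, dur_range[1], dur_range[2]) * fs)
  L <- min(max(L, 8L), T)
  if (L > T) stop("configuration error: feature longer than sample", call. = FALSE)
  onset <- sample.int(T - L + 1L, 1L)
  span <- onset:(onset + L - 1L)
  env <- .raised_cosine(L)

  wave <- switch(kind,
    alpha_spindle = {
      f0 <- stats::runif(1, 9, 11)
      phase <- stats::runif(1, 0, 2 * pi)
      sin(2 * pi * f0 * (span - 1) / fs + phase) * env * amp
    },
    emg_noise = .band_noise(L, fs, 25, min(45, fs / 2 * 0.95)) * env * amp,
    blink_pulse = env * amp * 2)      # monophasic low-frequency deflection

  for (ch in chans) {
    values[ch, span] <- values[ch, span] + wave
    mask[ch, span] <- 1L
  }
  frac <- sum(mask) / (N * T)
  if (spec$snr > 0 && (frac <= 0 || frac >= 0.5)) {
    stop("configuration error: mask area fraction ", round(frac, 3),
         " outside (0, 0.5)", call. = FALSE)
  }
  s <- eeg_sample(values, sampling_rate = fs, label = class_label)
  list(sample = s, mask = mask, background = bg)
}

#' Generate a labelled synthetic dataset
#'
#' Class proportions follow `class_balance` with any rounding surplus
#' assigned to class 1; per-sample seeds are derived deterministically from
#' `spec$seed`, so regeneration is bitwise stable and no two samples are
#' identical.
#'
#' @param spec a [synthetic_spec()].
#' @param n_samples number of samples (>= 2).
#' @return list with `samples` (list of [eeg_sample]), `labels` (integer
#'   vector) and `masks` (list of binary matrices).
#' @export
generate_dataset <- function(spec, n_samples) {
  stopifnot(inherits(spec, "synthetic_spec"), n_samples >= 2)
  n1 <- ceiling(n_samples * spec$class_balance)
  labels <- c(rep(1L, n1), rep(2L, n_samples - n1))
  old <- .seed_push(.derive_seed(spec$seed, 0L))
  labels <- sample(labels)
  .seed_pop(old)
  out <- lapply(seq_len(n_samples), function(i) {
    generate_sample(spec, labels[i], .derive_seed(spec$seed, i))
  })
  list(samples = lapply(out, `[[`, "sample"),
       labels = labels,
       masks = lapply(out, `[[`, "mask"))
}

#' Localization score of an attribution map against the ground-truth mask
#'
#' Ranks all sampling points by attribution score (descending; ties broken by
#' channel then time index) and measures what fraction of the top
#' `top_fraction` points fall inside the implanted feature mask, divided by
#' the mask's area fraction. A ratio of 1 is chance level; larger is
#' better-than-chance localization.
#'
#' @param cmap a [contribution_map] (or plain matrix).
#' @param mask binary N x T ground-truth mask.
#' @param top_fraction fraction of points considered, in (0, 1].
#' @return the precision-over-chance ratio (single number).
#' @export
localization_score <- function(cmap, mask, top_fraction = 0.1) {
  scores <- if (inherits(cmap, "contribution_map")) cmap$scores else as.matrix(cmap)
  mask <- as.matrix(mask)
  stopifnot(all(dim(scores) == dim(mask)), top_fraction > 0, top_fraction <= 1)
  area <- sum(mask != 0)
  if (area == 0) stop("input error: empty ground-truth mask", call. = FALSE)
  np <- length(scores)
  k <- max(1L, floor(top_fraction * np))
  ord <- .rank_points(scores)
  hits <- sum(mask[ord[seq_len(k)]] != 0)
  (hits / k) / (area / np)
}
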
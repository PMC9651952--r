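# Preprocessing and Morlet time-frequency decomposition.
#
# Features for decoding are instantaneous band power (delta..gamma) at each
# of 20 electrodes, z-scored across electrodes within band, giving 100
# features per trial and time point.

.conjrsa_bands <- list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 12),
                       beta = c(13, 30), gamma = c(31, 35))

#' Morlet wavelet specification
#'
#' 35 frequencies logarithmically spaced on 1-35 Hz; the number of cycles
#' `n` rises (log-spaced, mirroring the frequency spacing) from 3 to 10 so
#' the spectral bandwidth stays approximately constant across frequencies.
#' The Gaussian envelope SD is `sigma = n / (2 * pi * f)` seconds.
#'
#' @param n_freqs number of frequencies.
#' @param f_range frequency range, Hz.
#' @param cycles range of wavelet cycles.
#' @param cycle_spacing `"log"` (default) or `"linear"` progression of the
#'   cycle counts over frequencies.
#' @return a `wavelet_spec` list with `freqs`, `n_cycles`, `sigma` (s).
#' @export
wavelet_spec <- function(n_freqs = 35L, f_range = c(1, 35), cycles = c(3, 10),
                         cycle_spacing = c("log", "linear")) {
  cycle_spacing <- match.arg(cycle_spacing)
  freqs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freqs))
  n_cycles <- switch(cycle_spacing,
    log = exp(seq(log(cycles[1]), log(cycles[2]), length.out = n_freqs)),
    linear = seq(cycles[1], cycles[2], length.out = n_freqs))
  structure(list(freqs = freqs, n_cycles = n_cycles,
                 sigma = n_cycles / (2 * pi * freqs)),
            class = "wavelet_spec")
}

#' Canonical frequency bands
#'
#' delta 1-3, theta 4-7, alpha 8-12, beta 13-30, gamma 31-35 Hz.
#' @return named list of `c(low, high)` band edges in Hz.
#' @export
frequency_bands <- function() .conjrsa_bands

#' Artifact-rejection criteria
#'
#' Sliding-window criteria applied to trial epochs: blinks (peak-to-peak
#' above `blink_uv` on vertical EOG; 200 ms windows stepped by 50 ms), eye
#' movements (above `eyemove_deg` degrees, converted by `uv_per_deg`, on
#' horizontal EOG; 200 ms windows stepped by 10 ms) and amplifier blocking
#' (peak-to-peak below `blocking_uv` over 200 ms on any channel).
#'
#' @param blink_uv blink threshold in microvolts.
#' @param eyemove_deg eye-movement threshold in degrees.
#' @param uv_per_deg HEOG conversion factor, microvolts per degree.
#' @param blocking_uv flat-signal range threshold in microvolts.
#' @param window_ms window length for all criteria.
#' @param blink_step_ms,eyemove_step_ms window steps.
#' @return an `artifact_criteria` list.
#' @export
artifact_criteria <- function(blink_uv = 250, eyemove_deg = 1, uv_per_deg = 16,
                              blocking_uv = 0.02, window_ms = 200,
                              blink_step_ms = 50, eyemove_step_ms = 10) {
  stopifnot(blink_uv > 0, eyemove_deg > 0, uv_per_deg > 0, blocking_uv > 0)
  structure(list(blink_uv = blink_uv, eyemove_deg = eyemove_deg,
                 uv_per_deg = uv_per_deg, blocking_uv = blocking_uv,
                 window_ms = window_ms, blink_step_ms = blink_step_ms,
                 eyemove_step_ms = eyemove_step_ms),
            class = "artifact_criteria")
}

# sliding-window peak-to-peak over one vector
window_ptp <- function(x, win, step) {
  starts <- seq(1L, max(1L, length(x) - win + 1L), by = step)
  vapply(starts, function(s) {
    seg <- x[s:min(length(x), s + win - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
}

#' Reject artifact-contaminated trials
#'
#' A trial is rejected if any sliding window violates a criterion: blink
#' peak-to-peak on the vertical EOG, eye-movement peak-to-peak on the
#' horizontal EOG, or blocking (flat signal) on any channel.
#'
#' @param eeg an `epoched_eeg`.
#' @param eog_channels named list/vector identifying the EOG channels, e.g.
#'   `c(veog = "VEOG", heog = "HEOG")`; channel names or indices.
#' @param criteria an [artifact_criteria()].
#' @return logical keep mask of length `n_trials`, with attribute
#'   `"reasons"` (character, "" for kept trials).
#' @export
reject_artifacts <- function(eeg, eog_channels, criteria = artifact_criteria()) {
  stopifnot(inherits(eeg, "epoched_eeg"), inherits(criteria, "artifact_criteria"))
  if (missing(eog_channels) || is.null(eog_channels) || length(eog_channels) < 1L)
    stop_conjrsa("EOG channels must be identified for artifact rejection",
                 "conjrsa_config_error")
  chan_index <- function(ch) {
    if (is.numeric(ch)) return(as.integer(ch))
    i <- match(ch, eeg$channels)
    if (is.na(i)) stop_conjrsa(sprintf("EOG channel '%s' not found", ch),
                               "conjrsa_config_error")
    i
  }
  veog <- if (!is.null(eog_channels[["veog"]])) chan_index(eog_channels[["veog"]])
  heog <- if (!is.null(eog_channels[["heog"]])) chan_index(eog_channels[["heog"]])
  samp <- function(ms) max(1L, round(ms / 1000 * eeg$fs))
  win <- samp(criteria$window_ms)
  n_trials <- dim(eeg$data)[1]
  keep <- rep(TRUE, n_trials)
  reasons <- character(n_trials)
  eyemove_uv <- criteria$eyemove_deg * criteria$uv_per_deg
  for (i in seq_len(n_trials)) {
    why <- character(0)
    if (!is.null(veog) &&
        any(window_ptp(eeg$data[i, veog, ], win, samp(criteria$blink_step_ms)) >
            criteria$blink_uv)) why <- c(why, "blink")
    if (!is.null(heog) &&
        any(window_ptp(eeg$data[i, heog, ], win, samp(criteria$eyemove_step_ms)) >
            eyemove_uv)) why <- c(why, "eyemove")
    for (ch in seq_len(dim(eeg$data)[2])) {
      if (any(window_ptp(eeg$data[i, ch, ], win, win) < criteria$blocking_uv)) {
        why <- c(why, "blocking"); break
      }
    }
    if (length(why)) { keep[i] <- FALSE; reasons[i] <- paste(why, collapse = "+") }
  }
  structure(keep, reasons = reasons)
}

# complex Morlet kernel at frequency f (Hz): exp(i 2 pi f t) * gaussian(sigma),
# unit-energy normalized, truncated at +/- 4 sigma
morlet_kernel <- function(f, sigma, fs) {
  half <- ceiling(4 * sigma * fs)
  t <- seq(-half, half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
  w / sqrt(sum(Mod(w)^2))
}

# FFT linear convolution of each row of X (n x T) with complex kernel,
# returning the "same"-aligned n x T complex result
fft_conv_rows <- function(X, kern) {
  n_samp <- ncol(X)
  kl <- length(kern)
  nfft <- stats::nextn(n_samp + kl - 1L, c(2L, 3L))
  K <- stats::fft(c(kern, rep(0, nfft - kl)))
  half <- (kl - 1L) %/% 2L
  out <- matrix(0i, nrow = nrow(X), ncol = n_samp)
  for (r in seq_len(nrow(X))) {
    xf <- stats::fft(c(X[r, ], rep(0, nfft - n_samp)))
    full <- stats::fft(xf * K, inverse = TRUE) / nfft
    out[r, ] <- full[(half + 1L):(half + n_samp)]
  }
  out
}

# one trial's Morlet power for all kernels and channels at once.
# xmat: padded-signal matrix (len x n_ch); returns list of n_samp x n_ch
# power matrices, one per kernel. np = offset of sample 1 in the padding.
morlet_trial_power <- function(xmat, kern_ffts, kern_lens, nfft, np, n_samp) {
  X <- rbind(xmat, matrix(0, nrow = nfft - nrow(xmat), ncol = ncol(xmat)))
  XF <- stats::mvfft(X)
  lapply(seq_along(kern_ffts), function(k) {
    full <- stats::mvfft(XF * kern_ffts[[k]], inverse = TRUE) / nfft
    half <- (kern_lens[k] - 1L) %/% 2L
    seg <- full[(half + np + 1L):(half + np + n_samp), , drop = FALSE]
    Re(seg)^2 + Im(seg)^2
  })
}

# reflect-pad a vector by n samples on both sides
reflect_pad <- function(x, n) {
  n <- min(n, length(x) - 1L)
  if (n < 1L) return(x)
  c(rev(x[2:(n + 1L)]), x, rev(x[(length(x) - n):(length(x) - 1L)]))
}

#' Morlet wavelet power
#'
#' Convolves each trial and channel with complex Morlet wavelets (frequency-
#' domain implementation) and returns instantaneous power, the squared
#' magnitude of the convolved signal. Epochs are reflect-padded by `pad_s`
#' seconds before decomposition to avoid edge artifacts in the analysis
#' window (use long segments upstream when available).
#'
#' Memory note: the full trials x freqs x channels x samples array is large;
#' for feature extraction prefer [band_power()], which averages into the
#' five canonical bands on the fly.
#'
#' @param eeg an `epoched_eeg` (any list with `data` trials x channels x
#'   samples, `fs` and optionally `scalp` works).
#' @param spec a [wavelet_spec()].
#' @param pad_s reflect padding in seconds.
#' @param channels channel indices to decompose (default: scalp channels).
#' @return array trials x n_freqs x channels x samples of power, with
#'   `freqs` attribute.
#' @export
morlet_power <- function(eeg, spec = wavelet_spec(), pad_s = 1,
                         channels = NULL) {
  stopifnot(inherits(spec, "wavelet_spec"))
  dat <- eeg$data; fs <- eeg$fs
  if (fs < 2 * max(spec$freqs))
    stop_conjrsa("sampling rate below twice the maximum analysis frequency",
                 "conjrsa_config_error")
  channels <- channels %||% (eeg$scalp %||% seq_len(dim(dat)[2]))
  n_trials <- dim(dat)[1]; n_samp <- dim(dat)[3]
  npad <- round(pad_s * fs)
  out <- array(0, dim = c(n_trials, length(spec$freqs), length(channels), n_samp))
  kerns <- mapply(morlet_kernel, spec$freqs, spec$sigma,
                  MoreArgs = list(fs = fs), SIMPLIFY = FALSE)
  kern_lens <- lengths(kerns)
  padded_len <- n_samp + 2L * min(npad, n_samp - 1L)
  nfft <- stats::nextn(padded_len + max(kern_lens) - 1L, c(2L, 3L))
  kern_ffts <- lapply(kerns, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  for (i in seq_len(n_trials)) {
    xmat <- vapply(channels, function(ch) reflect_pad(dat[i, ch, ], npad),
                   numeric(padded_len))
    np <- (padded_len - n_samp) %/% 2L
    pw <- morlet_trial_power(xmat, kern_ffts, kern_lens, nfft, np, n_samp)
    for (k in seq_along(pw)) out[i, k, , ] <- t(pw[[k]])
  }
  attr(out, "freqs") <- spec$freqs
  out
}

#' Average a time-frequency decomposition into bands
#'
#' Each band averages the frequency bins whose centre lies inside the band's
#' closed interval. With the canonical log-spaced 1-35 Hz grid, bins falling
#' between the printed integer band edges belong to no band and are unused.
#'
#' @param tfr a [morlet_power()] array (with `freqs` attribute) or any
#'   trials x freqs x channels x samples array plus `freqs`.
#' @param bands named list of band edges, see [frequency_bands()].
#' @param freqs bin centre frequencies (default from the `freqs` attribute).
#' @return a `band_power` array trials x bands x channels x samples.
#' @export
band_average <- function(tfr, bands = frequency_bands(), freqs = NULL) {
  freqs <- freqs %||% attr(tfr, "freqs")
  stopifnot(!is.null(freqs), length(dim(tfr)) == 4L, dim(tfr)[2] == length(freqs))
  out <- array(0, dim = c(dim(tfr)[1], length(bands), dim(tfr)[3], dim(tfr)[4]),
               dimnames = list(NULL, names(bands), NULL, NULL))
  for (b in seq_along(bands)) {
    sel <- which(freqs >= bands[[b]][1] & freqs <= bands[[b]][2])
    if (!length(sel)) stop_conjrsa(sprintf("band %s contains no frequency bins",
                                           names(bands)[b]), "conjrsa_config_error")
    out[, b, , ] <- if (length(sel) == 1L) tfr[, sel, , ]
                    else apply(tfr[, sel, , , drop = FALSE], c(1, 3, 4), mean)
  }
  class(out) <- c("band_power", class(out))
  out
}

#' Band power, computed band-by-band
#'
#' Equivalent to `band_average(morlet_power(...))` but accumulates band
#' means on the fly so the full 35-frequency array is never materialised.
#'
#' @inheritParams morlet_power
#' @inheritParams band_average
#' @return a `band_power` array trials x bands x channels x samples.
#' @export
band_power <- function(eeg, spec = wavelet_spec(), bands = frequency_bands(),
                       pad_s = 1, channels = NULL) {
  stopifnot(inherits(spec, "wavelet_spec"))
  dat <- eeg$data; fs <- eeg$fs
  if (fs < 2 * max(spec$freqs))
    stop_conjrsa("sampling rate below twice the maximum analysis frequency",
                 "conjrsa_config_error")
  channels <- channels %||% (eeg$scalp %||% seq_len(dim(dat)[2]))
  n_trials <- dim(dat)[1]; n_samp <- dim(dat)[3]
  npad <- round(pad_s * fs)
  band_sel <- lapply(bands, function(be) which(spec$freqs >= be[1] & spec$freqs <= be[2]))
  if (any(!lengths(band_sel)))
    stop_conjrsa("a band contains no frequency bins", "conjrsa_config_error")
  kerns <- mapply(morlet_kernel, spec$freqs, spec$sigma,
                  MoreArgs = list(fs = fs), SIMPLIFY = FALSE)
  kern_lens <- lengths(kerns)
  padded_len <- n_samp + 2L * min(npad, n_samp - 1L)
  np <- (padded_len - n_samp) %/% 2L
  nfft <- stats::nextn(padded_len + max(kern_lens) - 1L, c(2L, 3L))
  kern_ffts <- lapply(kerns, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  out <- array(0, dim = c(n_trials, length(bands), length(channels), n_samp),
               dimnames = list(NULL, names(bands), NULL, NULL))
  for (i in seq_len(n_trials)) {
    xmat <- vapply(channels, function(ch) reflect_pad(dat[i, ch, ], npad),
                   numeric(padded_len))
    pw <- morlet_trial_power(xmat, kern_ffts, kern_lens, nfft, np, n_samp)
    for (b in seq_along(bands)) {
      acc <- 0
      for (k in band_sel[[b]]) acc <- acc + pw[[k]]
      out[i, b, , ] <- t(acc / length(band_sel[[b]]))
    }
  }
  class(out) <- c("band_power", class(out))
  out
}

#' Build the decoding feature matrix at one time sample
#'
#' Extracts the 5 bands x 20 electrodes power values at a sample and
#' z-scores across electrodes within each (trial, band) group, removing
#' effects that uniformly influence all electrodes. A zero-variance group is
#' set to 0 (no NaNs).
#'
#' @param bp a `band_power` array.
#' @param t_idx sample index.
#' @return trials x (bands*channels) numeric matrix.
#' @export
build_features <- function(bp, t_idx) {
  stopifnot(length(dim(bp)) == 4L, t_idx >= 1, t_idx <= dim(bp)[4])
  n_trials <- dim(bp)[1]; n_bands <- dim(bp)[2]; n_ch <- dim(bp)[3]
  out <- matrix(0, nrow = n_trials, ncol = n_bands * n_ch)
  for (b in seq_len(n_bands)) {
    m <- bp[, b, , t_idx]
    if (is.null(dim(m))) m <- matrix(m, nrow = n_trials)
    mu <- rowMeans(m)
    sd <- sqrt(pmax(rowSums((m - mu)^2) / (n_ch - 1L), 0))
    z <- (m - mu) / ifelse(sd > 0, sd, Inf)  # zero-variance group -> 0
    out[, (b - 1L) * n_ch + seq_len(n_ch)] <- z
  }
  out
}
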
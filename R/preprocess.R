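#' Remove power-line interference
#'
#' Zero-phase narrow band-stop (order-3 Butterworth, stop band
#' `line_freq` +/- 2 Hz, applied forward-backward) attenuating the mains
#' component by more than 30 dB while leaving frequencies 3 Hz away within
#' 1 dB.
#'
#' @param rec an [eeg_recording()].
#' @param line_freq mains frequency in Hz (50 in the recordings this
#'   workflow targets); must be below Nyquist.
#' @return the recording with filtered data; markers, labels and mask are
#'   untouched.
#' @export
remove_powerline <- function(rec, line_freq = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (line_freq >= rec$fs / 2)
    stop_config("line_freq %g Hz is not below Nyquist (%g Hz)",
                line_freq, rec$fs / 2)
  nyq <- rec$fs / 2
  bf <- signal::butter(3, c(line_freq - 2, line_freq + 2) / nyq, type = "stop")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec
}

# --- Daubechies-4 discrete wavelet transform (periodized) ----------------
# 8-tap db4 scaling filter; the wavelet filter is its quadrature mirror.
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)
DB4_G <- rev(DB4_H) * c(1, -1)

dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n / 2
  idx <- outer((seq_len(half) - 1) * 2, seq_along(h) - 1, "+") %% n + 1
  xm <- matrix(x[idx], half, length(h))
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  pos <- outer((seq_len(half) - 1) * 2, seq_along(h) - 1, "+") %% n + 1
  for (k in seq_along(h)) {
    x[pos[, k]] <- x[pos[, k]] + h[k] * a + g[k] * d
  }
  x
}

dwt_db4 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, DB4_H, DB4_G)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_db4 <- function(w) {
  a <- w$approx
  for (l in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[l]], DB4_H, DB4_G)
  a
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
hard_threshold <- function(x, thr) x * (abs(x) > thr)

#' Wavelet denoising
#'
#' Per-channel general-purpose denoiser: Daubechies-4 pyramid transform
#' (`levels` decomposition levels, periodized; the trace is reflection-
#' padded to a multiple of `2^levels` and cropped after reconstruction),
#' noise scale estimated from the finest detail coefficients as
#' `mad(d1)/0.6745`, and the universal threshold `sigma * sqrt(2 log n)`
#' applied to all detail levels. Hard thresholding is the default: it
#' leaves strong oscillatory coefficients unbiased, whereas soft
#' shrinkage visibly attenuates high-SNR rhythms like the ones this
#' workflow feeds into phase estimation (available via
#' `rule = "soft"`).
#'
#' @param rec an [eeg_recording()].
#' @param levels decomposition depth (default 4).
#' @param rule thresholding rule, `"hard"` (default) or `"soft"`.
#' @return the denoised recording, same length and metadata.
#' @export
wavelet_denoise <- function(rec, levels = 4, rule = c("hard", "soft")) {
  rule <- match.arg(rule)
  threshold_fun <- if (rule == "hard") hard_threshold else soft_threshold
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  block <- 2^levels
  if (n < block)
    stop_config("recording too short for %d decomposition levels", levels)
  npad <- ceiling(n / block) * block
  rec$data <- t(apply(rec$data, 1, function(x) {
    xp <- if (npad > n) c(x, rev(x)[seq_len(npad - n)]) else x
    w <- dwt_db4(xp, levels)
    sigma <- mad(w$details[[1]], center = 0)
    thr <- sigma * sqrt(2 * log(npad))
    w$details <- lapply(w$details, threshold_fun, thr = thr)
    idwt_db4(w)[seq_len(n)]
  }))
  rec
}

#' Amplitude artifact rejection
#'
#' Flags every sample whose absolute amplitude exceeds `limit_uV`
#' (8000 microvolts by default) as invalid in the recording's validity
#' mask. Samples are never deleted, so window timestamps stay aligned with
#' the seizure markers; downstream network construction skips any analysis
#' window that covers an invalid sample on any channel.
#'
#' @param rec an [eeg_recording()].
#' @param limit_uV rejection threshold in microvolts (> 0).
#' @return the recording with an updated `mask` field.
#' @export
reject_amplitude_artifacts <- function(rec, limit_uV = 8000) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(limit_uV > 0)) stop_config("limit_uV must be positive")
  rec$mask <- rec$mask & (abs(rec$data) <= limit_uV)
  rec
}

#' Subband decomposition
#'
#' Splits the recording into band-limited copies, one per frequency band,
#' using zero-phase (forward-backward) order-4 Butterworth band-pass
#' filters. Zero-phase filtering is mandatory here: phase-locking values
#' compare instantaneous phase across channels, so the decomposition must
#' introduce no group delay.
#'
#' @param rec an [eeg_recording()].
#' @param bands list of [band_definition()]s; defaults to the five
#'   canonical subbands.
#' @return named list of band-limited [eeg_recording()]s.
#' @export
bandpass_decompose <- function(rec, bands = canonical_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  out <- lapply(bands, function(b) {
    if (b$high >= nyq)
      stop_config("band %s (%g-%g Hz) exceeds Nyquist %g Hz",
                  b$name, b$low, b$high, nyq)
    bf <- signal::butter(4, c(b$low, b$high) / nyq, type = "pass")
    br <- rec
    br$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
    attr(br, "band") <- b
    br
  })
  names(out) <- vapply(bands, function(b) b$name, "")
  out
}

#' Segment a recording into preictal / ictal / postictal conditions
#'
#' For each seizure marker, the preictal interval covers `pre_s` seconds
#' before onset, the ictal interval runs from onset to offset, and the
#' postictal interval covers `post_s` seconds after cessation (both margins
#' default to 3 minutes). Intervals are half-open in samples and clipped to
#' the record bounds.
#'
#' @param rec an [eeg_recording()] with at least one seizure marker.
#' @param pre_s,post_s margins in seconds.
#' @return data.frame with columns `seizure`, `condition`, `start`, `end`
#'   (1-based half-open sample intervals), class `condition_segmentation`.
#' @export
segment_conditions <- function(rec, pre_s = 180, post_s = 180) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!nrow(rec$seizures))
    stop_config("recording carries no seizure markers; cannot segment")
  n <- ncol(rec$data)
  segs <- do.call(rbind, lapply(seq_len(nrow(rec$seizures)), function(i) {
    onset <- rec$seizures$onset[i]
    offset <- rec$seizures$offset[i]
    data.frame(
      seizure = i,
      condition = c("preictal", "ictal", "postictal"),
      start = c(max(1, onset - round(pre_s * rec$fs)), onset, offset),
      end = c(onset, offset, min(n + 1, offset + round(post_s * rec$fs))))
  }))
  segs <- segs[segs$end > segs$start, ]
  rownames(segs) <- NULL
  class(segs) <- c("condition_segmentation", "data.frame")
  segs
}
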
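#' Configuration for the coupled phase-oscillator EEG simulator
#'
#' The simulator emulates the one property of ictal intracranial EEG the
#' downstream analysis depends on: controllable phase hypersynchrony
#' concentrated on the intrafocus channels during the ictal epoch. Each
#' frequency band has a sinusoidal driver; each channel's phase deviation
#' from the driver follows a noisy Kuramoto step
#' \deqn{\delta_{t+1} = \delta_t + (1-\kappa)\,\Delta\omega
#'   - \kappa g \sin\delta_t + \sigma\varepsilon_t,}
#' where \eqn{\Delta\omega} is a fixed per-channel natural-frequency
#' offset, \eqn{\kappa} the coupling, \eqn{g} the coupling gain
#' (rad/sample) and \eqn{\sigma} per-sample phase jitter. The sine term
#' gives the model a genuine locking threshold: channels with
#' \eqn{\kappa g > (1-\kappa)|\Delta\omega|} entrain to the driver (high
#' pairwise PLV), the rest drift at their own frequency (low PLV).
#' Coupling 1 entrains exactly (and with zero jitter reproduces the driver
#' phase sample for sample); coupling 0 leaves a free drifting random
#' walk. The channel signal is the sum of band carriers (amplitude
#' `amplitude_uV` each) plus additive Gaussian sensor noise.
#'
#' @param n_channels number of channels (default 6: sites 1..3 intrafocus,
#'   4..6 extrafocus).
#' @param n_intrafocus how many leading channels are intrafocus.
#' @param fs sampling rate, Hz.
#' @param base_coupling phase coupling in `[0, 1]` for all channels outside
#'   the ictal epoch and for extrafocus channels throughout.
#' @param ictal_coupling coupling of intrafocus channels during ictal
#'   epochs; must satisfy `base_coupling <= ictal_coupling <= 1`.
#' @param band_targets list of `c(low, high)` Hz pairs; one carrier per
#'   band at the midpoint frequency. Defaults to the five canonical bands.
#' @param amplitude_uV carrier amplitude per band, microvolts.
#' @param noise_sd additive sensor-noise standard deviation, microvolts.
#' @param phase_jitter_sd per-sample phase jitter, radians.
#' @param freq_jitter per-channel natural-frequency offset, as a fraction
#'   of the carrier frequency (sd of a Gaussian draw).
#' @param coupling_gain maximum phase pull per sample, radians; sets the
#'   locking threshold together with the coupling and frequency offsets.
#' @param init `"random"` draws independent initial phase deviations;
#'   `"common"` starts all channels at the driver phase.
#' @param seed RNG seed, or NULL.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_channels = 6, n_intrafocus = 3, fs = 256,
                              base_coupling = 0.25, ictal_coupling = 0.95,
                              band_targets = NULL, amplitude_uV = 40,
                              noise_sd = 5, phase_jitter_sd = 0.1,
                              freq_jitter = 0.08, coupling_gain = 0.1,
                              init = c("random", "common"), seed = NULL) {
  if (is.null(band_targets))
    band_targets <- lapply(canonical_bands(), function(b) c(b$low, b$high))
  if (!(base_coupling >= 0 && base_coupling <= ictal_coupling && ictal_coupling <= 1))
    stop_config("need 0 <= base_coupling <= ictal_coupling <= 1")
  hi <- max(vapply(band_targets, max, 0))
  if (fs <= 2 * hi)
    stop_config("fs = %g too low for band edge %g Hz (need fs > 2*edge)", fs, hi)
  if (n_intrafocus < 1 || n_intrafocus >= n_channels)
    stop_config("n_intrafocus must be in [1, n_channels - 1]")
  structure(list(n_channels = n_channels, n_intrafocus = n_intrafocus,
                 fs = fs, base_coupling = base_coupling,
                 ictal_coupling = ictal_coupling, band_targets = band_targets,
                 amplitude_uV = amplitude_uV, noise_sd = noise_sd,
                 phase_jitter_sd = phase_jitter_sd, freq_jitter = freq_jitter,
                 coupling_gain = coupling_gain,
                 init = match.arg(init), seed = seed),
            class = "simulation_config")
}

#' Simulate a multichannel EEG recording with a seizure epoch
#'
#' Runs the phase-oscillator model of [simulation_config()] over an ordered
#' segment plan. During segments labeled `"ictal"` the intrafocus channels
#' are coupled at `ictal_coupling`; all other channel/segment combinations
#' use `base_coupling`. Seizure onset/offset sample indices are recorded
#' exactly in the returned recording, and the true segment table is
#' attached as attribute `"segments"`.
#'
#' @param config a [simulation_config()].
#' @param segment_plan data.frame with columns `label` (one of `preictal`,
#'   `ictal`, `postictal`) and `duration_s`, in temporal order; must
#'   contain at least one ictal segment. Default: 60 s preictal, 40 s
#'   ictal, 60 s postictal.
#' @return an [eeg_recording()].
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1)
#' rec <- simulate_seizure_eeg(cfg)
#' rec
simulate_seizure_eeg <- function(config,
                                 segment_plan = data.frame(
                                   label = c("preictal", "ictal", "postictal"),
                                   duration_s = c(60, 40, 60))) {
  stopifnot(inherits(config, "simulation_config"))
  segment_plan <- as.data.frame(segment_plan)
  if (!nrow(segment_plan)) stop_config("segment_plan is empty")
  if (!all(segment_plan$label %in% c("preictal", "ictal", "postictal")))
    stop_config("segment labels must be preictal/ictal/postictal")
  if (!any(segment_plan$label == "ictal"))
    stop_config("segment_plan must contain at least one ictal segment")
  maybe_set_seed(config$seed)

  fs <- config$fs
  nch <- config$n_channels
  seg_len <- as.integer(round(segment_plan$duration_s * fs))
  n <- sum(seg_len)
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L
  # per-sample ictal indicator; intrafocus channels switch coupling there
  ictal_mask <- logical(n)
  for (s in which(segment_plan$label == "ictal"))
    ictal_mask[seg_start[s]:seg_end[s]] <- TRUE
  is_intra <- seq_len(nch) <= config$n_intrafocus
  kap_base <- rep(config$base_coupling, nch)
  kap_ict <- ifelse(is_intra, config$ictal_coupling, config$base_coupling)
  g <- config$coupling_gain

  t_idx <- seq_len(n) - 1L
  x <- matrix(0, nch, n)
  for (band in config$band_targets) {
    f0 <- mean(band)
    psi <- 2 * pi * f0 * t_idx / fs     # driver phase
    # per-channel natural-frequency offsets (rad/sample)
    domega <- 2 * pi * f0 * config$freq_jitter * rnorm(nch) / fs
    d <- if (config$init == "common") numeric(nch) else runif(nch, -pi, pi)
    jitter <- matrix(rnorm(nch * n, sd = config$phase_jitter_sd), nch, n)
    drift_base <- (1 - kap_base) * domega
    drift_ict <- (1 - kap_ict) * domega
    pull_base <- g * kap_base
    pull_ict <- g * kap_ict
    delta <- matrix(0, nch, n)
    for (t in seq_len(n)) {
      if (ictal_mask[t]) {
        d <- d + drift_ict - pull_ict * sin(d) + jitter[, t]
      } else {
        d <- d + drift_base - pull_base * sin(d) + jitter[, t]
      }
      delta[, t] <- d
    }
    ph <- sweep(delta, 2, psi, "+")
    x <- x + config$amplitude_uV * cos(ph)
  }
  if (config$noise_sd > 0)
    x <- x + matrix(rnorm(nch * n, sd = config$noise_sd), nch, n)

  ict <- which(segment_plan$label == "ictal")
  seizures <- data.frame(onset = seg_start[ict], offset = seg_end[ict] + 1L)
  rec <- eeg_recording(x, fs = fs,
                       channel_labels = paste0("site", seq_len(nch)),
                       focus = rep(c("intrafocus", "extrafocus"),
                                   c(config$n_intrafocus,
                                     nch - config$n_intrafocus)),
                       seizures = seizures)
  attr(rec, "segments") <- data.frame(label = segment_plan$label,
                                      start = seg_start, end = seg_end + 1L)
  rec
}
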
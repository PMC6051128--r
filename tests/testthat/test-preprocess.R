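test_that("notch removes the mains component and spares the passband", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))

  # long record so start-up transients of the forward-backward pass are
  # negligible against the steady-state attenuation being asserted
  tl <- seq(0, 30 - 1 / fs, by = 1 / fs)
  r50 <- eeg_recording(rbind(sin(2 * pi * 50 * tl)), fs)
  out50 <- remove_powerline(r50, 50)
  expect_lt(rms(out50$data) / rms(r50$data), 0.05)

  r10 <- eeg_recording(rbind(sin(2 * pi * 10 * t)), fs)
  out10 <- remove_powerline(r10, 50)
  expect_lt(abs(rms(out10$data) / rms(r10$data) - 1), 0.05)

  # mixture: only the 10 Hz peak survives, with > 20 dB margin
  mix <- eeg_recording(rbind(sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t)), fs)
  y <- remove_powerline(mix, 50)$data[1, ]
  spec <- Mod(fft(y))[1:(length(y) / 2)]
  f <- (seq_along(spec) - 1) * fs / length(y)
  p10 <- max(spec[abs(f - 10) < 1])
  p50 <- max(spec[abs(f - 50) < 1])
  expect_gt(20 * log10(p10 / p50), 20)

  expect_error(remove_powerline(r10, 200), "Nyquist")
})

test_that("notch is idempotent in the passband", {
  rec <- make_test_recording(freqs = c(6, 10, 22))
  once <- remove_powerline(rec)
  twice <- remove_powerline(once)
  r1 <- sqrt(mean(once$data^2)); r2 <- sqrt(mean(twice$data^2))
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("wavelet denoising preserves clean structure and reduces noise", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)

  zero <- eeg_recording(matrix(0, 2, length(t)), fs)
  expect_equal(wavelet_denoise(zero)$data, zero$data)

  clean <- eeg_recording(rbind(50 * sin(2 * pi * 8 * t)), fs)
  den <- wavelet_denoise(clean)
  expect_equal(ncol(den$data), ncol(clean$data))
  rel <- sqrt(mean((den$data - clean$data)^2)) / sqrt(mean(clean$data^2))
  expect_lt(rel, 0.02)

  # residual after denoising a noisy sinusoid beats the injected noise
  sigma <- 10
  wins <- vapply(1:25, function(s) {
    set.seed(s)
    noisy <- eeg_recording(rbind(50 * sin(2 * pi * 8 * t) +
                                   rnorm(length(t), sd = sigma)), fs)
    resid <- wavelet_denoise(noisy)$data[1, ] - 50 * sin(2 * pi * 8 * t)
    var(resid) < sigma^2
  }, logical(1))
  expect_true(all(wins))

  expect_error(wavelet_denoise(eeg_recording(matrix(1, 1, 8), 256)), "short")
})

test_that("amplitude rejection masks exactly the offending samples", {
  rec <- make_test_recording()
  ok <- reject_amplitude_artifacts(rec)
  expect_true(all(ok$mask))

  spiked <- rec
  spiked$data[2, 100] <- 9000
  m <- reject_amplitude_artifacts(spiked)$mask
  expect_false(m[2, 100])
  expect_equal(sum(!m), 1)

  expect_error(reject_amplitude_artifacts(rec, limit_uV = 0), "positive")
})

test_that("band decomposition isolates tones with zero phase shift", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t)), fs)
  bands <- bandpass_decompose(rec)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(bands$alpha$data) / rms(rec$data), 0.90)
  expect_lt(rms(bands$gamma$data) / rms(rec$data), 0.05)

  # white noise: subband powers cannot exceed the total power
  set.seed(1)
  wn <- eeg_recording(rbind(rnorm(length(t))), fs)
  bp <- vapply(bandpass_decompose(wn), function(b) mean(b$data^2), 0)
  expect_lt(sum(bp), mean(wn$data^2))

  # impulse train: zero-phase filtering peaks the cross-correlation at lag 0
  imp <- numeric(length(t)); imp[seq(128, length(t), by = 256)] <- 1
  ai <- bandpass_decompose(eeg_recording(rbind(imp), fs),
                           list(band_definition("alpha", 8, 13)))$alpha$data[1, ]
  cc <- ccf(imp, ai, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)

  expect_error(
    bandpass_decompose(rec, list(band_definition("hf", 100, 140))), "Nyquist")
})

test_that("preprocessing preserves channels, focus labels and markers", {
  cfg <- simulation_config(band_targets = list(c(8, 13)), seed = 2)
  rec <- simulate_seizure_eeg(cfg, data.frame(
    label = c("preictal", "ictal"), duration_s = c(4, 4)))
  out <- reject_amplitude_artifacts(remove_powerline(wavelet_denoise(rec)))
  expect_equal(out$channel_labels, rec$channel_labels)
  expect_equal(out$focus, rec$focus)
  expect_identical(out$seizures, rec$seizures)
  expect_equal(dim(out$data), dim(rec$data))
})

test_that("condition segmentation follows the 3-minute margins and clips", {
  fs <- 256
  n <- 500 * fs
  rec <- eeg_recording(matrix(0, 1, n), fs,
                       seizures = data.frame(onset = 200 * fs + 1,
                                             offset = 260 * fs + 1))
  seg <- segment_conditions(rec)
  pre <- seg[seg$condition == "preictal", ]
  # 0-based half-open equivalent: [5120, 51200) for onset 200 s, 180 s margin
  expect_equal(pre$start - 1, 20 * fs)
  expect_equal(pre$end - 1, 200 * fs)
  ict <- seg[seg$condition == "ictal", ]
  expect_equal(c(ict$start, ict$end), c(200 * fs + 1, 260 * fs + 1))
  post <- seg[seg$condition == "postictal", ]
  expect_equal(post$end - post$start, 180 * fs)

  # early onset: preictal clipped to the record start
  rec2 <- eeg_recording(matrix(0, 1, n), fs,
                        seizures = data.frame(onset = 60 * fs + 1,
                                              offset = 90 * fs + 1))
  pre2 <- segment_conditions(rec2)
  pre2 <- pre2[pre2$condition == "preictal", ]
  expect_equal(c(pre2$start, pre2$end), c(1, 60 * fs + 1))

  # two seizures 10 minutes apart give non-overlapping segmentations
  rec3 <- eeg_recording(matrix(0, 1, 1500 * fs), fs,
                        seizures = data.frame(
                          onset = c(400, 1000) * fs + 1,
                          offset = c(430, 1030) * fs + 1))
  seg3 <- segment_conditions(rec3)
  expect_equal(nrow(seg3), 6)
  seg3 <- seg3[order(seg3$start), ]
  expect_true(all(diff(seg3$start) >= 0))
  expect_true(all(seg3$end[-nrow(seg3)] <= seg3$start[-1] + 1))

  expect_error(segment_conditions(make_test_recording()), "no seizure markers")
})
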
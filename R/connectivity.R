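#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert-transform analytic signal of each band-limited
#' channel by FFT and returns its argument. Phases lie in `(-pi, pi]` and
#' are invariant to positive amplitude scaling of a channel. An all-zero
#' channel has no defined phase; its row is returned as `NA` and reported
#' in the `"invalid_channels"` attribute.
#'
#' @param band_signal channels x samples numeric matrix (band-limited).
#' @return channels x samples matrix of phases in radians.
#' @export
instantaneous_phase <- function(band_signal) {
  band_signal <- unname(as.matrix(band_signal))
  ph <- t(apply(band_signal, 1, function(x) {
    if (all(x == 0)) return(rep(NA_real_, length(x)))
    Arg(analytic_signal(x))
  }))
  invalid <- unname(which(apply(band_signal, 1, function(x) all(x == 0))))
  if (length(invalid)) attr(ph, "invalid_channels") <- invalid
  ph
}

# Analytic signal x + i*H(x) by one-sided spectrum doubling.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value matrix
#'
#' `PLV_ij = |mean_t exp(i (phi_i(t) - phi_j(t)))|` over the window: the
#' modulus of the time-averaged unit phasor of the phase difference, 1 for
#' perfect locking and near 0 for unrelated phases. The matrix is symmetric
#' with the diagonal forced to 0 (self-connections are excluded from the
#' networks).
#'
#' @param phases channels x samples phase matrix (radians).
#' @param window `c(start, end)` 1-based inclusive sample range, or NULL
#'   for the whole matrix.
#' @return N x N symmetric PLV matrix, entries in `[0, 1]`, zero diagonal.
#' @export
plv_matrix <- function(phases, window = NULL) {
  phases <- unname(as.matrix(phases))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[2] >= window[1])
    phases <- phases[, window[1]:window[2], drop = FALSE]
  }
  if (ncol(phases) < 2) stop_config("PLV window must cover >= 2 samples")
  z <- exp(1i * phases)
  plv <- Mod(z %*% Conj(t(z))) / ncol(phases)
  plv <- pmin(plv, 1)
  diag(plv) <- 0
  plv
}

#' Non-overlapping frequency-dependent window plan
#'
#' Window length is `n_cycles` cycles of the band's lower edge frequency,
#' `ceil(n_cycles * fs / low)` samples; windows tile the record contiguously
#' without overlap and a trailing partial window is dropped.
#'
#' @param band a [band_definition()].
#' @param fs sampling rate, Hz.
#' @param n_total total number of samples available.
#' @param n_cycles cycles of the band's low edge per window (default 6).
#' @return data.frame with 1-based inclusive columns `start`, `end`.
#' @export
window_plan <- function(band, fs, n_total, n_cycles = 6) {
  width <- ceiling(n_cycles * fs / band$low)
  k <- floor(n_total / width)
  if (k < 1)
    stop_config("record (%d samples) shorter than one %s-band window (%d samples)",
                n_total, band$name, width)
  data.frame(start = (seq_len(k) - 1L) * width + 1L,
             end = seq_len(k) * width)
}

#' Build time-varying PLV network series per band
#'
#' For each band-limited recording: extract instantaneous phases, tile the
#' record with the band's non-overlapping windows, and compute one PLV
#' adjacency matrix per window. Windows covering any artifact-masked sample
#' are skipped (and listed in the series' `skipped` field). When a
#' segmentation is supplied each window is labeled with the condition at
#' its midpoint sample, `"unlabeled"` if the midpoint falls outside every
#' condition interval.
#'
#' @param banded named list of band-limited [eeg_recording()]s from
#'   [bandpass_decompose()].
#' @param segmentation optional [segment_conditions()] result.
#' @param n_cycles window length in cycles of each band's low edge.
#' @return named list of `plv_network_series` objects, each holding
#'   `band`, `windows` (data.frame start/end/condition), `adjacency`
#'   (list of matrices), `node_labels`, `fs`, `skipped`.
#' @export
build_network_series <- function(banded, segmentation = NULL, n_cycles = 6) {
  out <- lapply(banded, function(br) {
    band <- attr(br, "band")
    stopifnot(!is.null(band))
    plan <- window_plan(band, br$fs, ncol(br$data), n_cycles)
    ph <- instantaneous_phase(br$data)
    valid_col <- apply(br$mask, 2, all)
    ok <- vapply(seq_len(nrow(plan)),
                 function(i) all(valid_col[plan$start[i]:plan$end[i]]),
                 logical(1))
    skipped <- plan[!ok, , drop = FALSE]
    plan <- plan[ok, , drop = FALSE]
    adjacency <- lapply(seq_len(nrow(plan)), function(i)
      plv_matrix(ph, c(plan$start[i], plan$end[i])))
    plan$condition <- if (is.null(segmentation)) {
      rep("unlabeled", nrow(plan))
    } else {
      mid <- floor((plan$start + plan$end) / 2)
      vapply(mid, function(m) {
        hit <- which(segmentation$start <= m & m < segmentation$end)
        if (length(hit)) segmentation$condition[hit[1]] else "unlabeled"
      }, "")
    }
    structure(list(band = band, windows = plan, adjacency = adjacency,
                   node_labels = seq_len(nrow(br$data)), fs = br$fs,
                   skipped = skipped),
              class = "plv_network_series")
  })
  names(out) <- names(banded)
  out
}

#' @export
print.plv_network_series <- function(x, ...) {
  cat(sprintf("<plv_network_series> band %s (%g-%g Hz): %d windows x %d nodes",
              x$band$name, x$band$low, x$band$high,
              nrow(x$windows), length(x$node_labels)))
  if (nrow(x$skipped)) cat(sprintf(" (%d skipped)", nrow(x$skipped)))
  cat("\n")
  if (nrow(x$windows))
    cat("  conditions:", paste(sprintf("%s=%d", names(table(x$windows$condition)),
                                       table(x$windows$condition)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Binarize a weighted network series
#'
#' An edge is kept iff its weight is strictly greater than `threshold`
#' (default 0.3, the cut separating valid links from weak ties); ties at
#' exactly the threshold are excluded.
#'
#' @param series a `plv_network_series` (or a single adjacency matrix).
#' @param threshold numeric in `[0, 1)`.
#' @return the series with 0/1 adjacency matrices and a `threshold` field,
#'   class `binary_network_series`; or a 0/1 matrix for matrix input.
#' @export
binarize <- function(series, threshold = 0.3) {
  if (!(threshold >= 0 && threshold < 1))
    stop_config("threshold must lie in [0, 1)")
  if (is.matrix(series)) return((series > threshold) * 1)
  stopifnot(inherits(series, "plv_network_series"))
  series$adjacency <- lapply(series$adjacency, function(a) (a > threshold) * 1)
  series$threshold <- threshold
  class(series) <- c("binary_network_series", class(series))
  series
}

#' Weighted graph metrics
#'
#' Comparison metrics on a symmetric nonnegative adjacency with zero
#' diagonal: node strength (sum of incident weights), weighted clustering
#' coefficient by the geometric-mean triangle formula
#' `c_i = sum_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1))` (weights used
#' as-is since PLV is already bounded by 1; set `normalize = TRUE` to
#' rescale by the maximum weight first), and characteristic path length
#' over shortest paths with edge distance `1/w`, averaged across connected
#' node pairs. A disconnected graph is flagged and averaged over the
#' connected pairs only.
#'
#' @param adjacency symmetric nonnegative matrix, zero diagonal.
#' @param normalize divide weights by `max(w)` before the clustering
#'   computation.
#' @return list with `strength`, `clustering`, `path_length`,
#'   `disconnected`.
#' @export
weighted_metrics <- function(adjacency, normalize = FALSE) {
  a <- as.matrix(adjacency)
  stopifnot(isSymmetric(unname(a)), all(a >= 0), all(diag(a) == 0))
  strength <- rowSums(a)
  k <- rowSums(a > 0)
  w <- if (normalize && max(a) > 0) a / max(a) else a
  w3 <- w^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)  # sum over ordered (j,h) of (w_ij w_jh w_hi)^{1/3}
  clustering <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  off <- d[upper.tri(d)]
  disconnected <- any(!is.finite(off))
  path_length <- if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_
  list(strength = strength, clustering = clustering,
       path_length = path_length, disconnected = disconnected)
}
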
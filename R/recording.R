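#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples matrix (microvolts) with its sampling rate,
#' channel labels, the intrafocus/extrafocus classification of each recording
#' site, and seizure onset/offset markers. Intrafocus sites carry the lowest
#' node indices (channels 1..3 by default for a 6-channel montage); all
#' downstream node-sequence statistics rely on that encoding.
#'
#' Sample intervals throughout the package are half-open: `onset` is the
#' 1-based index of the first ictal sample and `offset` is one past the last.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param focus character vector, `"intrafocus"` or `"extrafocus"` per
#'   channel. Intrafocus channels must come first.
#' @param seizures data.frame with integer columns `onset`, `offset`
#'   (sample indices, half-open), one row per seizure. May have zero rows.
#' @param mask optional logical matrix of the same shape as `data`; `TRUE`
#'   marks a valid sample. Defaults to all-valid.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, focus = NULL,
                          seizures = NULL, mask = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  nch <- nrow(data)
  ns <- ncol(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_config("fs must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stop_config("channel_labels length (%d) != channel count (%d)",
                length(channel_labels), nch)
  if (is.null(focus)) {
    n_intra <- min(3L, nch)
    focus <- rep(c("intrafocus", "extrafocus"), c(n_intra, nch - n_intra))
  }
  focus <- match.arg(focus, c("intrafocus", "extrafocus"), several.ok = TRUE)
  if (length(focus) != nch)
    stop_config("focus length (%d) != channel count (%d)", length(focus), nch)
  if (is.unsorted(match(focus, c("intrafocus", "extrafocus"))))
    stop_config("intrafocus channels must carry the lowest channel indices")
  if (is.null(seizures))
    seizures <- data.frame(onset = integer(0), offset = integer(0))
  seizures <- as.data.frame(seizures)
  stopifnot(all(c("onset", "offset") %in% names(seizures)))
  if (nrow(seizures) && any(seizures$onset >= seizures$offset))
    stop_config("each seizure must satisfy onset < offset")
  if (nrow(seizures) && (any(seizures$onset < 1) || any(seizures$offset > ns + 1)))
    stop_config("seizure markers fall outside the recording")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nch, ns)
  } else {
    mask <- as.matrix(mask)
    stopifnot(identical(dim(mask), dim(data)), is.logical(mask))
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         focus = focus, seizures = seizures, mask = mask),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  focus: %d intrafocus, %d extrafocus | seizures: %d\n",
              sum(x$focus == "intrafocus"), sum(x$focus == "extrafocus"),
              nrow(x$seizures)))
  if (!all(x$mask))
    cat(sprintf("  %d samples flagged invalid by artifact mask\n", sum(!x$mask)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Number of samples in a recording
#' @param rec an [eeg_recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds the samples-by-channels matrix (one column per channel,
#' header = channel labels). The JSON sidecar records the sampling rate,
#' channel labels, focus classification and seizure markers in seconds:
#' `{fs, channel_labels, focus_class, seizures: [{onset_s, offset_s}]}`.
#'
#' @param rec an [eeg_recording()].
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` are written.
#' @return `write_recording` returns the two paths invisibly;
#'   `read_recording` returns an [eeg_recording()].
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  write.csv(m, csv, row.names = FALSE)
  side <- list(
    fs = rec$fs,
    channel_labels = rec$channel_labels,
    focus_class = rec$focus,
    seizures = data.frame(onset_s = (rec$seizures$onset - 1) / rec$fs,
                          offset_s = (rec$seizures$offset - 1) / rec$fs))
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  m <- as.matrix(read.csv(csv, check.names = FALSE))
  seiz <- side$seizures
  if (is.null(seiz) || NROW(seiz) == 0) {
    seizures <- NULL
  } else {
    seizures <- data.frame(
      onset = as.integer(round(seiz$onset_s * side$fs)) + 1L,
      offset = as.integer(round(seiz$offset_s * side$fs)) + 1L)
  }
  eeg_recording(t(m), fs = side$fs, channel_labels = side$channel_labels,
                focus = side$focus_class, seizures = seizures)
}

#' EEG frequency band definitions
#'
#' A band is a named low/high edge pair in Hz. [canonical_bands()] returns
#' the five standard subbands used throughout: delta (0.5-4), theta (4-8),
#' alpha (8-13), beta (13-30) and gamma (30-45 Hz).
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return `band_definition`: a list with class `band_definition`;
#'   `canonical_bands`: a named list of five such objects.
#' @export
band_definition <- function(name, low, high) {
  if (!(low > 0 && high > low))
    stop_config("band '%s' needs 0 < low < high (got %g, %g)", name, low, high)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
canonical_bands <- function() {
  list(delta = band_definition("delta", 0.5, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}
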
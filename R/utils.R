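#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft filter mad rnorm runif sd t.test median
#' @importFrom utils read.table write.table write.csv read.csv
NULL

# Set the RNG only when the caller supplied a seed; otherwise leave the
# current stream untouched so seeded harnesses can drive several calls
# from one stream.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Polynomial rolling hash (base 257, mod 2^31 - 1) over a character scalar;
# used for run-manifest config fingerprints.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
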
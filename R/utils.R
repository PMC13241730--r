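# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named random stream
#'
#' Every stochastic artifact in the package (genome, peaks, counts, motif
#' plants, background samples, ...) draws from its own named substream so that
#' regenerating one artifact never perturbs another. The sub-seed is a
#' deterministic 32-bit mix of the master seed and the stream name.
#'
#' @param seed master integer seed.
#' @param stream character stream name, e.g. `"genome"`.
#' @return a positive integer seed strictly below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 2166136261
  for (b in utf8ToInt(stream)) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% 2147483629) + 1L
}

# FNV-1a style hash of a character scalar, as 8 hex digits; used to fingerprint
# configurations in provenance records (content hash, no timestamps).
nr_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

nr_log <- function(fmt, ...) {
  if (isTRUE(getOption("nrocc.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

# stop() with a consistent header so callers can grep stage failures
nr_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
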
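# Internal helpers shared across the pipeline.

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Child seeds are keyed on stable identifiers (subject id, test name), so
#' adding a subject to a cohort never perturbs another subject's random
#' stream.  The hash is a small 32-bit FNV-1a over the key, folded into the
#' master seed and kept below 2^31 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param key character scalar identifying the consumer of the child stream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(key),
            length(key) == 1L)
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((as.numeric(master) + h) %% .Machine$integer.max)
}

# Convert a time in seconds to a 0-based sample offset by round-to-nearest.
sec_to_samp <- function(t_s, fs) as.integer(round(t_s * fs))

# Half-open sample index range [round(t0*fs), round(t1*fs)) as 0-based offsets.
samp_range <- function(t0_s, t1_s, fs) {
  a <- sec_to_samp(t0_s, fs)
  b <- sec_to_samp(t1_s, fs)
  if (b <= a) integer(0) else seq.int(a, b - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
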
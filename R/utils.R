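# Internal helpers: deterministic sub-stream seeding and random-field synthesis.

MERSENNE31 <- 2147483647

#' Derive a reproducible sub-stream seed from a master seed and a metadata tuple
#'
#' Hashes the string representation of the tuple with a 31-bit polynomial
#' rolling hash and mixes in the master seed, so that every image / patient
#' gets its own independent, regenerable RNG stream.
#'
#' @param seed master integer seed
#' @param ... tuple components (coerced to character)
#' @return an integer in `[0, 2^31 - 2]`
#' @keywords internal
#' @noRd
tuple_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% MERSENNE31
  # Knuth multiplicative mix of the master seed, kept exact in doubles
  as.integer((h + (seed %% MERSENNE31) * 48271) %% MERSENNE31)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Zero-mean, unit-variance Gaussian random field with approximate spatial
# correlation length `corr_len` (pixels), built by circular FFT convolution
# of white noise with a Gaussian kernel. Stationary, edge-free.
smooth_field <- function(h, w, corr_len) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (corr_len <= 0) return((z - mean(z)) / stats::sd(z))
  dr <- pmin(0:(h - 1), h - (0:(h - 1)))
  dc <- pmin(0:(w - 1), w - (0:(w - 1)))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * corr_len^2))
  kern <- kern / sum(kern)
  f <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (h * w)
  (f - mean(f)) / stats::sd(f)
}

clip8 <- function(x) pmin(pmax(round(x), 0), 255)

`%||%` <- function(a, b) if (is.null(a)) b else a
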
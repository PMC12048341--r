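#' Coerce to a bit vector
#'
#' Accepts a numeric/integer vector of 0s and 1s, a logical vector, or a
#' character string such as `"010110"`, and returns a plain integer vector
#' of 0/1 values.
#'
#' @param x Bits in any of the accepted representations.
#' @return Integer vector with values in `{0, 1}`.
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- as.integer(strsplit(x, "")[[1]])
  }
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("bit vectors may only contain 0 and 1", call. = FALSE)
  }
  x
}

#' Format a bit vector as a 0/1 string
#' @param bits Bit vector.
#' @return Single character string.
#' @export
bits_to_string <- function(bits) paste(as_bits(bits), collapse = "")

#' Convert a non-negative integer payload to a fixed-width bit vector
#'
#' Most-significant bit first. Payloads are held as doubles so that
#' information lengths up to 53 bits are exact (the largest code shipped
#' here uses k = 37).
#'
#' @param payload Non-negative number, strictly less than `2^k`.
#' @param k Number of bits.
#' @return Integer bit vector of length `k`.
#' @export
payload_to_bits <- function(payload, k) {
  payload <- as.numeric(payload)
  stopifnot(length(payload) == 1L, k >= 1)
  if (is.na(payload) || payload < 0 || payload != floor(payload)) {
    stop("payload must be a non-negative integer", call. = FALSE)
  }
  if (payload >= 2^k) {
    stop(sprintf("payload %s exceeds capacity 2^%d - 1", format(payload), k),
         call. = FALSE)
  }
  bits <- integer(k)
  for (i in k:1) {
    bits[i] <- payload %% 2
    payload <- payload %/% 2
  }
  bits
}

#' Convert a bit vector back to its integer payload
#' @param bits Bit vector, most-significant bit first.
#' @return Numeric scalar (exact for up to 53 bits).
#' @export
bits_to_payload <- function(bits) {
  bits <- as_bits(bits)
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

# Run code with a temporary, restorable RNG state so that seeded package
# samplers never disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive independent per-item seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}
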
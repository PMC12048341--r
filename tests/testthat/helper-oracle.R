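# Independent brute-force oracle for small Reed-Muller codes: enumerate
# every codeword and return the information bits of the nearest one.
# Stays deliberately independent of the majority-logic decoder it checks.

all_info_vectors <- function(k) {
  m <- matrix(0L, nrow = 2^k, ncol = k)
  for (j in seq_len(k)) {
    m[, j] <- rep(rep(c(0L, 1L), each = 2^(k - j)), length.out = 2^k)
  }
  m
}

codebook_cache <- new.env(parent = emptyenv())

all_codewords <- function(code) {
  key <- sprintf("rm_%d_%d", code$r, code$m)
  if (!is.null(codebook_cache[[key]])) return(codebook_cache[[key]])
  infos <- all_info_vectors(code$k)
  cws <- (infos %*% code$generator) %% 2L
  res <- list(infos = infos, codewords = cws)
  codebook_cache[[key]] <- res
  res
}

# Nearest-codeword decoding by exhaustive search.
brute_force_decode <- function(code, word) {
  cb <- all_codewords(code)
  dists <- rowSums(cb$codewords != rep(word, each = nrow(cb$codewords)))
  best <- which.min(dists)
  list(info = cb$infos[best, ],
       dist = dists[best],
       unique = sum(dists == dists[best]) == 1L)
}

# All bit-flip patterns of exactly weight w on n positions.
flip_patterns <- function(n, w) {
  if (w == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  t(utils::combn(n, w))
}

# Rotate an image matrix counter-clockwise by k * 90 degrees.
rot90_image <- function(m, k) {
  for (i in seq_len(k %% 4)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

random_payloads <- function(n, k, seed) {
  set.seed(seed)
  floor(runif(n) * 2^k)
}
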
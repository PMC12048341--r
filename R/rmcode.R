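#' Construct a Reed-Muller code RM(r, m)
#'
#' Builds the binary Reed-Muller code of order `r` and block length
#' `n = 2^m`. The generator matrix rows are the evaluations of all
#' monomials of degree at most `r` in the m boolean variables, over all
#' `2^m` evaluation points. Rows are ordered degree-ascending and, within
#' a degree, lexicographically by variable index; evaluation points run in
#' binary counting order with variable 1 as the most significant bit.
#'
#' The code encodes `k = sum(choose(m, 0:r))` information bits and has
#' minimum distance `d = 2^(m - r)`, so it is guaranteed to correct
#' `t = 2^(m - r - 1) - 1` arbitrary bit errors (for `r < m`). These are
#' the codes used to protect microneedle-patch bit patterns against
#' gradual bit loss in skin.
#'
#' @param r Order (maximum monomial degree), `0 <= r <= m`.
#' @param m Log2 of the block length, `m >= 1`.
#' @return An object of class `rm_code` with fields `r`, `m`, `n`, `k`,
#'   `d` (minimum distance), `t` (guaranteed correction radius),
#'   `generator` (k x n binary matrix), and `monomials` (list of variable
#'   index sets, one per generator row).
#' @examples
#' code <- rm_code(1, 6)
#' code$k  # 7 information bits
#' code$t  # corrects up to 15 bit errors
#' @export
rm_code <- function(r, m) {
  if (length(r) != 1L || length(m) != 1L || is.na(r) || is.na(m) ||
      r != floor(r) || m != floor(m) || m < 1 || r < 0 || r > m) {
    stop("require integers 0 <= r <= m and m >= 1", call. = FALSE)
  }
  r <- as.integer(r); m <- as.integer(m)
  n <- as.integer(2^m)

  # Variable value at each evaluation point: vars[i, j] = x_i at point j,
  # points in counting order 0 .. 2^m - 1, x_1 the most significant bit.
  pts <- 0:(n - 1)
  vars <- matrix(0L, nrow = m, ncol = n)
  for (i in seq_len(m)) {
    vars[i, ] <- (pts %/% 2L^(m - i)) %% 2L
  }

  monomials <- list(integer(0))
  if (r >= 1) {
    for (d in 1:r) {
      cmb <- utils::combn(m, d)
      monomials <- c(monomials, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    }
  }
  k <- length(monomials)

  generator <- matrix(1L, nrow = k, ncol = n)
  for (row in seq_len(k)) {
    for (v in monomials[[row]]) {
      generator[row, ] <- generator[row, ] * vars[v, ]
    }
  }

  d_min <- as.integer(2^(m - r))
  t_corr <- if (r < m) as.integer(2^(m - r - 1) - 1) else 0L

  structure(
    list(
      r = r, m = m, n = n, k = k, d = d_min, t = t_corr,
      generator = generator, monomials = monomials, vars = vars,
      cosets = rm_coset_index(m, monomials, vars)
    ),
    class = "rm_code"
  )
}

# Precompute, for every monomial, the partition of evaluation points into
# cosets used by Reed's majority-logic decoder. For a monomial on variable
# set S the points are grouped by the values of the complementary
# variables; each group (one row of the returned matrix) contributes one
# parity-check vote for the coefficient of S.
rm_coset_index <- function(m, monomials, vars) {
  n <- 2L^m
  lapply(monomials, function(S) {
    comp <- setdiff(seq_len(m), S)
    if (length(comp) == 0L) {
      matrix(seq_len(n), nrow = 1L)
    } else {
      key <- rep(0L, n)
      for (v in comp) key <- key * 2L + vars[v, ]
      idx <- order(key)
      matrix(idx, nrow = 2L^length(comp), byrow = TRUE)
    }
  })
}

#' @export
print.rm_code <- function(x, ...) {
  cat(sprintf("RM(%d, %d): n = %d, k = %d, d = %d, corrects up to %d errors\n",
              x$r, x$m, x$n, x$k, x$d, x$t))
  invisible(x)
}

#' Encode information bits with a Reed-Muller code
#'
#' Multiplies the information vector by the code's generator matrix over
#' GF(2). The map is linear: `rm_encode(code, xor(a, b))` equals the XOR
#' of the two codewords.
#'
#' @param code An [rm_code()] object.
#' @param info Bit vector of length `code$k`.
#' @return Integer codeword of length `code$n`.
#' @export
rm_encode <- function(code, info) {
  info <- as_bits(info)
  if (length(info) != code$k) {
    stop(sprintf("info must have length k = %d, got %d", code$k, length(info)),
         call. = FALSE)
  }
  as.integer((info %*% code$generator) %% 2L)
}

#' Decode a received word with Reed's majority-logic algorithm
#'
#' Recovers monomial coefficients order by order, from degree `r` down to
#' the constant term. The coefficient of each monomial is taken as the
#' majority over its coset parity sums; the decoded contribution of each
#' degree is peeled off (XOR-ed out) before the next lower degree is
#' processed. Because the cosets partition the evaluation points, each
#' corrupted bit can spoil at most one vote per monomial, which yields the
#' guaranteed radius `t = 2^(m-r-1) - 1`.
#'
#' For words beyond the guarantee the decoder still returns its best
#' effort; `low_confidence` is `TRUE` when any majority vote was tied
#' (ties resolve to 0) or when the residual distance to the decoded
#' codeword exceeds `t`.
#'
#' @param code An [rm_code()] object.
#' @param word Received bit vector of length `code$n`.
#' @return List with `info` (decoded bits, length k), `n_corrected`
#'   (Hamming distance between the word and the decoded codeword),
#'   `n_ties` (tied majority votes encountered), and `low_confidence`.
#' @export
rm_decode <- function(code, word) {
  word <- as_bits(word)
  if (length(word) != code$n) {
    stop(sprintf("word must have length n = %d, got %d", code$n, length(word)),
         call. = FALSE)
  }
  residual <- word
  info <- integer(code$k)
  ties <- 0L
  degrees <- vapply(code$monomials, length, integer(1))

  for (d in sort(unique(degrees), decreasing = TRUE)) {
    rows <- which(degrees == d)
    for (row in rows) {
      cs <- code$cosets[[row]]
      votes <- rowSums(matrix(residual[cs], nrow = nrow(cs))) %% 2L
      ones <- sum(votes)
      if (2L * ones > length(votes)) {
        info[row] <- 1L
      } else {
        if (2L * ones == length(votes)) ties <- ties + 1L
        info[row] <- 0L  # ties resolve to 0
      }
    }
    contrib <- (info[rows] %*% code$generator[rows, , drop = FALSE]) %% 2L
    residual <- as.integer(xor(residual, contrib))
  }

  n_corrected <- sum(residual)
  list(
    info = info,
    n_corrected = n_corrected,
    n_ties = ties,
    low_confidence = ties > 0L || n_corrected > code$t
  )
}

#' Information-capacity table for marker-bearing square bit arrays
#'
#' For each configuration `(N, r, m, orientation_bits)` reports the bit
#' accounting of an N x N patch: total bits, bits reserved for the corner
#' orientation markers, usable encoding bits `2^floor(log2(N^2))`, and the
#' derived capacity of the chosen RM(r, m) code (information units,
#' number of encodable patterns `2^k`, and guaranteed correctable errors).
#' All quantities are computed from the constructed code, not tabulated.
#'
#' @param specs Data frame (or list of lists) with columns/fields `N`,
#'   `r`, `m`, `orientation_bits`. Defaults to the five standard patch
#'   configurations (10x10, 12x12 at two orders, 17x17 at two orders).
#' @return Data frame with one row per configuration: `array_size`,
#'   `total_bits`, `orientation_bits`, `encoding_bits`, `code`,
#'   `information_units`, `encodable_count`, `correctable`.
#' @examples
#' capacity_table()
#' @export
capacity_table <- function(specs = default_capacity_specs()) {
  if (!is.data.frame(specs)) {
    specs <- do.call(rbind, lapply(specs, function(s) as.data.frame(s[c("N", "r", "m", "orientation_bits")])))
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    N <- specs$N[i]; r <- specs$r[i]; m <- specs$m[i]
    ob <- specs$orientation_bits[i]
    total <- N^2
    enc <- 2^floor(log2(total))
    if (ob + enc > total) {
      stop(sprintf("row %d: orientation (%d) + encoding (%d) bits exceed %d",
                   i, ob, enc, total), call. = FALSE)
    }
    code <- rm_code(r, m)
    if (code$n != enc) {
      stop(sprintf("row %d: code length 2^%d does not fill the %d encoding bits",
                   i, m, enc), call. = FALSE)
    }
    data.frame(
      array_size = as.numeric(N),
      total_bits = as.numeric(total),
      orientation_bits = as.integer(ob),
      encoding_bits = as.numeric(enc),
      code = sprintf("RM(%d, %d)", r, m),
      information_units = code$k,
      encodable_count = 2^code$k,
      correctable = code$t
    )
  })
  do.call(rbind, rows)
}

#' @rdname capacity_table
#' @export
default_capacity_specs <- function() {
  data.frame(
    N = c(10L, 12L, 12L, 17L, 17L),
    r = c(1L, 1L, 2L, 1L, 2L),
    m = c(6L, 7L, 7L, 8L, 8L),
    orientation_bits = c(36L, 16L, 16L, 33L, 33L)
  )
}
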
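test_that("code parameters follow the closed forms for all orders up to m = 8", {
  for (m in 1:8) {
    for (r in 0:m) {
      code <- rm_code(r, m)
      expect_identical(code$n, as.integer(2^m))
      expect_identical(code$k, as.integer(sum(choose(m, 0:r))))
      expect_identical(code$d, as.integer(2^(m - r)))
      if (r < m) expect_identical(code$t, as.integer(2^(m - r - 1) - 1))
    }
  }
  # the three standard patch codes
  c16 <- rm_code(1, 6)
  expect_equal(c(c16$n, c16$k, c16$t), c(64, 7, 15))
  c28 <- rm_code(2, 8)
  expect_equal(c(c28$n, c28$k, c28$t), c(256, 37, 31))
  rep8 <- rm_code(0, 3)  # order 0 is the repetition code
  expect_equal(c(rep8$n, rep8$k, rep8$d, rep8$t), c(8, 1, 8, 3))
})

test_that("invalid code parameters are rejected", {
  expect_error(rm_code(3, 2), "r <= m")
  expect_error(rm_code(1, 0), "r <= m")
  expect_error(rm_code(-1, 3), "r <= m")
})

test_that("generator matrices have full row rank over GF(2)", {
  gf2_rank <- function(M) {
    M <- M %% 2L; rank <- 0L
    for (col in seq_len(ncol(M))) {
      piv <- which(M[, col] == 1L & seq_len(nrow(M)) > rank)
      if (length(piv) == 0) next
      rank <- rank + 1L
      if (piv[1] != rank) M[c(rank, piv[1]), ] <- M[c(piv[1], rank), ]
      hit <- which(M[, col] == 1L & seq_len(nrow(M)) != rank)
      if (length(hit)) M[hit, ] <- (M[hit, , drop = FALSE] + rep(M[rank, ], each = length(hit))) %% 2L
      if (rank == nrow(M)) break
    }
    rank
  }
  for (cd in list(rm_code(1, 4), rm_code(2, 4), rm_code(1, 6), rm_code(2, 7))) {
    expect_identical(gf2_rank(cd$generator), cd$k)
  }
})

test_that("minimum distance equals 2^(m-r) by exhaustive enumeration (m <= 4)", {
  for (cd in list(rm_code(1, 3), rm_code(1, 4), rm_code(2, 4))) {
    cb <- all_codewords(cd)
    weights <- rowSums(cb$codewords)
    expect_identical(as.integer(min(weights[weights > 0])), cd$d)
  }
})

test_that("encoding is the linear generator-matrix map", {
  code <- rm_code(1, 3)
  expect_identical(rm_encode(code, integer(code$k)), integer(code$n))
  # constant monomial alone evaluates to 1 everywhere
  c12 <- rm_code(1, 2)
  expect_identical(rm_encode(c12, c(1L, 0L, 0L)), rep(1L, 4))
  # linearity on random pairs
  set.seed(42)
  for (i in 1:20) {
    a <- rbinom(code$k, 1, 0.5); b <- rbinom(code$k, 1, 0.5)
    expect_identical(rm_encode(code, (a + b) %% 2L),
                     as.integer(xor(rm_encode(code, a), rm_encode(code, b))))
  }
  expect_error(rm_encode(code, c(1L, 0L)), "length")
})

test_that("majority-logic decoding matches the brute-force oracle within the radius", {
  # RM(1,3): every codeword, every error of weight <= t = 1
  c13 <- rm_code(1, 3)
  cb <- all_codewords(c13)
  for (ci in seq_len(nrow(cb$codewords))) {
    for (w in 0:c13$t) {
      pats <- flip_patterns(c13$n, w)
      for (pi in seq_len(nrow(pats))) {
        word <- cb$codewords[ci, ]
        word[pats[pi, ]] <- 1L - word[pats[pi, ]]
        dec <- rm_decode(c13, word)
        expect_identical(dec$info, as.integer(cb$infos[ci, ]))
        expect_identical(dec$n_corrected, w)
        expect_false(dec$low_confidence)
      }
    }
  }
  # RM(1,4): sampled codewords against all 697 patterns of weight <= 3
  c14 <- rm_code(1, 4)
  set.seed(7)
  infos <- matrix(rbinom(4 * c14$k, 1, 0.5), nrow = 4)
  n_checked <- 0
  for (ci in seq_len(nrow(infos))) {
    cw <- rm_encode(c14, infos[ci, ])
    for (w in 0:c14$t) {
      pats <- flip_patterns(c14$n, w)
      for (pi in seq_len(nrow(pats))) {
        word <- cw
        if (w > 0) word[pats[pi, ]] <- 1L - word[pats[pi, ]]
        dec <- rm_decode(c14, word)
        oracle <- brute_force_decode(c14, word)
        expect_identical(dec$info, as.integer(oracle$info))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_identical(n_checked / nrow(infos), 697)  # 1 + 16 + 120 + 560
})

test_that("an RM(1,6) codeword with exactly 15 flipped bits is recovered", {
  code <- rm_code(1, 6)
  set.seed(11)
  for (i in 1:25) {
    info <- rbinom(code$k, 1, 0.5)
    word <- rm_encode(code, info)
    flips <- sample(code$n, 15)
    word[flips] <- 1L - word[flips]
    dec <- rm_decode(code, word)
    expect_identical(dec$info, as.integer(info))
    expect_identical(dec$n_corrected, 15L)
  }
})

test_that("uncorrupted codewords decode with zero corrections; lengths are checked", {
  code <- rm_code(2, 7)
  set.seed(5)
  info <- rbinom(code$k, 1, 0.5)
  dec <- rm_decode(code, rm_encode(code, info))
  expect_identical(dec$info, as.integer(info))
  expect_identical(dec$n_corrected, 0L)
  expect_error(rm_decode(code, c(0L, 1L)), "length")
})

test_that("even vote splits are flagged as ties and low confidence", {
  # repetition code with a balanced word: the single majority vote is tied
  rep8 <- rm_code(0, 3)
  dec <- rm_decode(rep8, c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(dec$info, 0L)       # ties resolve to 0
  expect_gt(dec$n_ties, 0L)
  expect_true(dec$low_confidence)
})

test_that("seeded random errors at the guaranteed radius are always corrected", {
  # 1,000 trials across the first-order 64-bit and second-order 128-bit codes
  for (spec in list(c(1, 6), c(2, 7))) {
    code <- rm_code(spec[1], spec[2])
    set.seed(2026)
    failures <- 0L
    for (i in 1:1000) {
      info <- rbinom(code$k, 1, 0.5)
      word <- rm_encode(code, info)
      w <- sample.int(code$t, 1)
      flips <- sample(code$n, w)
      word[flips] <- 1L - word[flips]
      if (!identical(rm_decode(code, word)$info, as.integer(info))) failures <- failures + 1L
    }
    expect_identical(failures, 0L)
  }
})

test_that("capacity table is computed from code construction", {
  tab <- capacity_table()
  expect_identical(tab$information_units, c(7L, 8L, 29L, 9L, 37L))
  expect_identical(tab$encodable_count, 2^c(7, 8, 29, 9, 37))
  expect_identical(tab$correctable, c(15L, 31L, 15L, 63L, 31L))
  expect_identical(tab$orientation_bits + tab$encoding_bits <= tab$total_bits,
                   rep(TRUE, 5))
  # custom single-row specs work and inconsistent ones fail
  row <- capacity_table(data.frame(N = 10, r = 1, m = 6, orientation_bits = 36))
  expect_identical(row$encodable_count, 128)
  expect_error(capacity_table(data.frame(N = 10, r = 1, m = 5, orientation_bits = 36)),
               "does not fill")
})
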
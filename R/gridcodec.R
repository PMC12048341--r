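#' Build an N x N patch template with corner orientation markers
#'
#' A template partitions the N x N needle grid into reserved orientation
#' marker cells, each with a fixed expected value, and the remaining data
#' cells ordered in a raster scan (top-left to bottom-right). Markers
#' occupy the four corners: three corners are fully ON and the
#' bottom-right corner is OFF, which makes the layout asymmetric under
#' all non-trivial 90-degree rotations so the patch orientation can be
#' recovered from an image. The usable encoding length is
#' `2^floor(log2(N^2))` bits; codeword bits fill the leading data cells
#' and any surplus data cells are fixed OFF.
#'
#' Corner block size: for general N, the side is the largest `s` with
#' `4 s^2 <= N^2 - 2^floor(log2(N^2))`, which yields the standard 3x3
#' blocks for N = 10 (36 marker cells, 64 data cells) and 2x2 blocks for
#' N = 12 (16 marker cells, 128 data cells). N = 17 uses a dedicated
#' layout: three 3x3 ON corner blocks plus a 3-row x 2-column OFF block
#' anchored at the bottom-right corner (33 marker cells, 256 data cells).
#'
#' @param N Grid side in cells, `N >= 6`.
#' @return Object of class `grid_template`: `N`, `encoding_bits`,
#'   `reserved` (data frame `row`, `col`, `value`), `expected` (N x N
#'   matrix, marker value or NA), `data_order` (two-column matrix of data
#'   cell coordinates in raster order).
#' @examples
#' tpl <- grid_template(10)
#' nrow(tpl$reserved)   # 36 orientation cells
#' tpl$encoding_bits    # 64
#' @export
grid_template <- function(N) {
  if (length(N) != 1L || is.na(N) || N != floor(N) || N < 6) {
    stop("N must be an integer >= 6", call. = FALSE)
  }
  N <- as.integer(N)
  enc <- as.integer(2^floor(log2(N^2)))

  corner_cells <- function(corner, h, w) {
    rows <- switch(corner, tl = 1:h, tr = 1:h, bl = (N - h + 1):N, br = (N - h + 1):N)
    cols <- switch(corner, tl = 1:w, bl = 1:w, tr = (N - w + 1):N, br = (N - w + 1):N)
    expand.grid(row = rows, col = cols)
  }

  if (N == 17L) {
    blocks <- list(
      cbind(corner_cells("tl", 3, 3), value = 1L),
      cbind(corner_cells("tr", 3, 3), value = 1L),
      cbind(corner_cells("bl", 3, 3), value = 1L),
      cbind(corner_cells("br", 3, 2), value = 0L)
    )
  } else {
    s <- floor(sqrt((N^2 - enc) / 4))
    if (s < 1) {
      stop(sprintf("N = %d cannot host corner markers plus %d data bits", N, enc),
           call. = FALSE)
    }
    blocks <- list(
      cbind(corner_cells("tl", s, s), value = 1L),
      cbind(corner_cells("tr", s, s), value = 1L),
      cbind(corner_cells("bl", s, s), value = 1L),
      cbind(corner_cells("br", s, s), value = 0L)
    )
  }
  reserved <- do.call(rbind, blocks)

  expected <- matrix(NA_integer_, N, N)
  expected[cbind(reserved$row, reserved$col)] <- reserved$value

  # raster order over non-reserved cells
  all_cells <- expand.grid(col = 1:N, row = 1:N)[, c("row", "col")]
  is_res <- !is.na(expected[cbind(all_cells$row, all_cells$col)])
  data_order <- as.matrix(all_cells[!is_res, , drop = FALSE])
  rownames(data_order) <- NULL

  if (nrow(data_order) < enc) {
    stop(sprintf("template has %d data cells, fewer than the %d encoding bits",
                 nrow(data_order), enc), call. = FALSE)
  }

  structure(
    list(N = N, encoding_bits = enc, reserved = reserved,
         expected = expected, data_order = data_order),
    class = "grid_template"
  )
}

#' @export
print.grid_template <- function(x, ...) {
  cat(sprintf("grid_template %dx%d: %d orientation cells, %d data cells, %d encoding bits\n",
              x$N, x$N, nrow(x$reserved), nrow(x$data_order), x$encoding_bits))
  invisible(x)
}

#' Place a codeword onto a patch grid
#'
#' Writes the orientation markers at their expected values and lays the
#' codeword bits over the data cells in raster order (top-left to
#' bottom-right, skipping marker cells). Surplus data cells beyond the
#' encoding length are set OFF. [extract_bits()] inverts this exactly.
#'
#' @param template A [grid_template()].
#' @param codeword Bit vector of length `template$encoding_bits`.
#' @return N x N integer 0/1 matrix (class `pattern_grid`).
#' @export
place_bits <- function(template, codeword) {
  codeword <- as_bits(codeword)
  if (length(codeword) != template$encoding_bits) {
    stop(sprintf("codeword must have length %d, got %d",
                 template$encoding_bits, length(codeword)), call. = FALSE)
  }
  g <- matrix(0L, template$N, template$N)
  g[cbind(template$reserved$row, template$reserved$col)] <- template$reserved$value
  g[template$data_order[seq_along(codeword), , drop = FALSE]] <- codeword
  as_pattern_grid(g)
}

#' Read the codeword back off a patch grid
#'
#' @param template A [grid_template()].
#' @param grid N x N 0/1 matrix in canonical orientation (markers at their
#'   template positions; see [detect_orientation()]).
#' @return Bit vector of length `template$encoding_bits`.
#' @export
extract_bits <- function(template, grid) {
  grid <- as_pattern_grid(grid)
  if (nrow(grid) != template$N) {
    stop("grid size does not match template", call. = FALSE)
  }
  as.integer(grid[template$data_order[seq_len(template$encoding_bits), , drop = FALSE]])
}

#' Validate and tag an N x N 0/1 matrix as a pattern grid
#' @param x Square matrix with values in `{0, 1}`.
#' @return The matrix with class `pattern_grid`.
#' @export
as_pattern_grid <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("pattern grid must be square", call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("pattern grid values must be 0 or 1", call. = FALSE)
  }
  class(x) <- c("pattern_grid", class(unclass(x)))
  x
}

#' Generate a reproducible XOR encryption mask
#'
#' The mask is a fixed, secret N x N half-ON/half-OFF bit pattern XOR-ed
#' onto the encoded grid so that fabricated patches carry roughly equal ON
#' and OFF counts regardless of payload, and so the payload cannot be read
#' without the mask (obfuscation, not cryptographic-strength encryption).
#' Marker cells are never masked: they must stay readable for orientation
#' recovery. Data-cell bits are drawn i.i.d. Bernoulli(1/2) and redrawn
#' until the ON fraction lies in [0.4, 0.6].
#'
#' @param N Grid side.
#' @param seed Integer seed; the mask is a pure function of `(N, seed)`.
#' @param template Template whose marker cells are excluded; defaults to
#'   `grid_template(N)`.
#' @return Object of class `mask_spec`: `N`, `seed`, `mask` (N x N 0/1).
#' @export
make_mask <- function(N, seed, template = grid_template(N)) {
  stopifnot(template$N == N)
  data_cells <- template$data_order
  nd <- nrow(data_cells)
  bits <- with_local_seed(seed, {
    repeat {
      b <- stats::rbinom(nd, 1L, 0.5)
      f <- mean(b)
      if (f >= 0.4 && f <= 0.6) break
    }
    b
  })
  mask <- matrix(0L, N, N)
  mask[data_cells] <- bits
  structure(list(N = N, seed = seed, mask = mask), class = "mask_spec")
}

#' Apply (or remove) an XOR encryption mask
#'
#' Cell-wise XOR of the grid with the mask. The operation is an
#' involution, so the same call encrypts an encoded pattern and decrypts
#' a recognized one.
#'
#' @param grid N x N `pattern_grid` (or 0/1 matrix).
#' @param mask A [make_mask()] object or bare 0/1 matrix of the same size.
#' @return Masked `pattern_grid`.
#' @export
apply_mask <- function(grid, mask) {
  grid <- as_pattern_grid(grid)
  m <- if (inherits(mask, "mask_spec")) mask$mask else as.matrix(mask)
  if (!all(dim(grid) == dim(m))) stop("grid and mask sizes differ", call. = FALSE)
  as_pattern_grid((unclass(grid) + m) %% 2L)
}

# Rotate a matrix counter-clockwise by k * 90 degrees.
rotate_grid <- function(g, k) {
  k <- k %% 4L
  for (i in seq_len(k)) g <- t(g)[rev(seq_len(ncol(g))), , drop = FALSE]
  g
}

#' Recover patch orientation from the corner markers
#'
#' Tries all four 90-degree rotations of the observed grid and scores each
#' by the number of mismatches between the rotated corner cells and the
#' template's expected marker values (three corners ON, bottom-right
#' distinct). The rotation with the fewest mismatches wins; an exact tie
#' between two rotations is an ambiguity error.
#'
#' @param grid Observed N x N 0/1 matrix, in any of the four orientations.
#' @param template The matching [grid_template()].
#' @return List: `rotation` (degrees counter-clockwise applied to
#'   normalize, one of 0/90/180/270), `grid` (normalized `pattern_grid`),
#'   `marker_errors` (residual marker mismatches).
#' @export
detect_orientation <- function(grid, template) {
  grid <- as_pattern_grid(grid)
  if (nrow(grid) != template$N) stop("grid size does not match template", call. = FALSE)
  res_idx <- cbind(template$reserved$row, template$reserved$col)
  expect <- template$reserved$value
  mism <- integer(4)
  rotated <- vector("list", 4)
  for (k in 0:3) {
    rotated[[k + 1]] <- rotate_grid(unclass(grid), k)
    mism[k + 1] <- sum(rotated[[k + 1]][res_idx] != expect)
  }
  best <- which.min(mism)
  if (sum(mism == mism[best]) > 1L) {
    stop("orientation ambiguous: two or more rotations fit the markers equally well",
         call. = FALSE)
  }
  list(rotation = (best - 1L) * 90L,
       grid = as_pattern_grid(rotated[[best]]),
       marker_errors = mism[best])
}

#' Write a pattern grid as CSV (one row per grid row)
#' @param grid `pattern_grid` or 0/1 matrix.
#' @param path Output file.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.table(unclass(as_pattern_grid(grid)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pattern grid from CSV
#' @param path CSV of 0/1 values, one grid row per line.
#' @return `pattern_grid`.
#' @export
read_grid_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  as_pattern_grid(m)
}

#' Export ON-cell coordinates for patch fabrication
#'
#' Lists the dye-loaded needle positions of an encoded grid as a
#' `row,col` table, the form used to drive mask-tape cutting or mould
#' loading.
#'
#' @param grid `pattern_grid`.
#' @return Data frame with columns `row`, `col` (1-based, top-left origin).
#' @export
fabrication_export <- function(grid) {
  grid <- as_pattern_grid(grid)
  on <- which(unclass(grid) == 1L, arr.ind = TRUE)
  df <- data.frame(row = on[, 1], col = on[, 2])
  df[order(df$row, df$col), , drop = FALSE]
}
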
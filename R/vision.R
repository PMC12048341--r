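#' Adaptive (local-mean) binarization
#'
#' A pixel is ON when its value exceeds the mean of its `window`-sided
#' neighbourhood by more than `offset`. This is the classical adaptive
#' threshold used for counting fluorescent bits on uneven skin
#' backgrounds; it requires no global threshold choice.
#'
#' @param image Greyscale matrix in [0, 1].
#' @param window Odd window side in pixels; must not exceed the image.
#'   Defaults to roughly two bit pitches for the standard render geometry.
#' @param offset Threshold margin above the local mean, default 2% of the
#'   dynamic range.
#' @return Integer 0/1 matrix of the same size.
#' @export
binarize_adaptive <- function(image, window = 41L, offset = 0.02) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > min(dim(image))) {
    stop("window larger than the image", call. = FALSE)
  }
  kern <- matrix(1 / window^2, window, window)
  local_mean <- EBImage::filter2(image, kern, boundary = "replicate")
  out <- (image - local_mean > offset) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Remove small connected components from a binary image
#'
#' Drops components below `min_px`, and additionally below a fraction of
#' the median size of the remaining components. Fluorescent spots at one
#' pitch are all of comparable area, so the adaptive rule separates them
#' cleanly from thresholded noise clumps without any absolute size
#' assumption.
#'
#' @param binary 0/1 matrix.
#' @param min_px Absolute minimum component area in pixels.
#' @param relative Relative minimum as a fraction of the median size of
#'   components that pass the absolute floor (0 disables).
#' @return 0/1 integer matrix.
#' @export
clean_binary <- function(binary, min_px = 9L, relative = 0.5) {
  lab <- EBImage::bwlabel(binary)
  if (max(lab) == 0) return(matrix(0L, nrow(binary), ncol(binary)))
  sizes <- tabulate(lab[lab > 0])
  thr <- min_px
  if (relative > 0 && any(sizes >= min_px)) {
    thr <- max(min_px, relative * stats::median(sizes[sizes >= min_px]))
  }
  keep <- which(sizes >= thr)
  out <- matrix(0L, nrow(binary), ncol(binary))
  out[lab %in% keep] <- 1L
  out
}

#' Count connected bright components (detected bits)
#' @inheritParams clean_binary
#' @return Integer component count after small-object removal.
#' @export
count_components <- function(binary, min_px = 9L) {
  as.integer(max(EBImage::bwlabel(clean_binary(binary, min_px))))
}

# Minimum-area enclosing rotated rectangle of a point set, by rotating
# calipers over the convex hull. Coordinates are (x, y). Returns centre,
# side lengths and the rectangle angle normalized to (-45, 45] degrees.
min_area_rect <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(hx)
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-9) next
    ux <- ex / len; uy <- ey / len        # edge direction
    vx <- -uy; vy <- ux                   # normal
    pu <- hx * ux + hy * uy
    pv <- hx * vx + hy * vy
    w <- max(pu) - min(pu); hgt <- max(pv) - min(pv)
    area <- w * hgt
    if (is.null(best) || area < best$area) {
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      best <- list(area = area,
                   cx = cu * ux + cv * vx, cy = cu * uy + cv * vy,
                   w = w, h = hgt,
                   angle = atan2(uy, ux) * 180 / pi)
    }
  }
  # fold the angle into (-45, 45]: the rectangle is invariant under 90-deg
  # steps, and the residual tilt is what rectification must undo
  a <- best$angle %% 90
  if (a > 45) a <- a - 90
  best$angle <- a
  best
}

#' Rectify a binarized patch image
#'
#' Finds the minimum-area rotated rectangle covering all ON pixels,
#' rotates the image so the rectangle is axis-aligned, crops a square
#' region 35% larger than the rectangle's long side while preserving the
#' rectangle centre, and resizes to `target_side`. A 90-degree rotation
#' ambiguity necessarily remains; it is resolved downstream from the
#' corner orientation markers, not here.
#'
#' @param binary 0/1 matrix (the binarized patch image). At least 3 ON
#'   pixels are required.
#' @param target_side Output side in pixels.
#' @param margin Crop enlargement factor relative to the rectangle's long
#'   side (default 1.35).
#' @param image Optional greyscale companion image warped with the same
#'   transform (returned as `$grey`).
#' @return Object of class `rectified_image`: `image` (target x target),
#'   `recovered_angle` (degrees, the residual tilt that was removed,
#'   in (-45, 45]), `crop_side` (px, before resize), `centre` (x, y),
#'   `rect` (the fitted rectangle), `margin`, and optionally `grey`.
#' @export
rectify <- function(binary, target_side = 256L, margin = 1.35, image = NULL) {
  on <- which(binary == 1L, arr.ind = TRUE)
  if (nrow(on) < 3) stop("no patch found: fewer than 3 foreground pixels", call. = FALSE)
  rect <- min_area_rect(x = on[, 2], y = on[, 1])
  crop_side <- margin * max(rect$w, rect$h)

  warp <- function(src) {
    th <- rect$angle * pi / 180
    sc <- crop_side / target_side
    off <- (seq_len(target_side) - (target_side + 1) / 2) * sc
    # inverse map: rotate output offsets by the recovered angle back into
    # the source frame around the rectangle centre
    dx <- outer(rep(1, target_side), off)        # along x
    dy <- outer(off, rep(1, target_side))        # along y
    sx <- rect$cx + dx * cos(th) - dy * sin(th)
    sy <- rect$cy + dx * sin(th) + dy * cos(th)
    bilinear_sample(src, sx, sy)
  }

  out <- list(image = warp(binary), recovered_angle = rect$angle,
              crop_side = crop_side, centre = c(x = rect$cx, y = rect$cy),
              rect = rect, margin = margin, target_side = as.integer(target_side))
  if (!is.null(image)) out$grey <- warp(image)
  structure(out, class = "rectified_image")
}

# Bilinear interpolation of src (matrix indexed [y, x]) at real-valued
# coordinate matrices sx, sy; points outside the image sample 0.
bilinear_sample <- function(src, sx, sy) {
  nr <- nrow(src); nc <- ncol(src)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get <- function(yy, xx) {
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    v <- numeric(length(yy))
    v[ok] <- src[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * ((1 - fx) * get(y0, x0) + fx * get(y0, x0 + 1)) +
    fy * ((1 - fx) * get(y0 + 1, x0) + fx * get(y0 + 1, x0 + 1))
  matrix(v, nrow(sx), ncol(sx))
}

#' Read an N x N bit grid off a rectified patch image
#'
#' Divides the rectified image into N x N cells (the patch occupies the
#' central `1/margin` of the frame after rectification), scores each cell
#' by its mean intensity over the central 50% of the cell, and labels
#' cells ON/OFF by a parameter-free two-class (2-means) split of the
#' scores. Ties and degenerate score distributions resolve to OFF.
#'
#' @param rectified A [rectify()] result, or a square image matrix.
#' @param N Grid side.
#' @param margin Crop enlargement factor used during rectification
#'   (taken from the `rectified_image` when available).
#' @return `pattern_grid` (orientation still ambiguous modulo 90 degrees).
#' @export
read_grid <- function(rectified, N, margin = 1.35) {
  if (inherits(rectified, "rectified_image")) {
    img <- rectified$image
    margin <- rectified$margin
  } else {
    img <- rectified
  }
  side <- nrow(img)
  cell <- side / margin / N
  ctr <- (side + 1) / 2
  half <- cell * 0.25   # central 50% of the cell
  scores <- matrix(0, N, N)
  for (i in 1:N) {
    for (j in 1:N) {
      cy <- ctr + (i - (N + 1) / 2) * cell
      cx <- ctr + (j - (N + 1) / 2) * cell
      ys <- max(1, round(cy - half)):min(side, round(cy + half))
      xs <- max(1, round(cx - half)):min(side, round(cx + half))
      scores[i, j] <- mean(img[ys, xs])
    }
  }
  if (max(scores) - min(scores) < 1e-6) {
    warning("degenerate cell intensity distribution; returning all-OFF grid")
    return(as_pattern_grid(matrix(0L, N, N)))
  }
  as_pattern_grid(two_means_split(scores))
}

# 1-D 2-means labelling of a score matrix: Lloyd iterations seeded at the
# extremes; scores closer to the high centre become ON, exact ties OFF.
two_means_split <- function(scores) {
  lo <- min(scores); hi <- max(scores)
  for (it in 1:50) {
    on <- (hi - scores) < (scores - lo)   # strict: ties -> OFF
    if (!any(on) || all(on)) break
    lo2 <- mean(scores[!on]); hi2 <- mean(scores[on])
    if (abs(lo2 - lo) < 1e-12 && abs(hi2 - hi) < 1e-12) break
    lo <- lo2; hi <- hi2
  }
  ((hi - scores) < (scores - lo)) * 1L
}

#' Signal retention over a longitudinal image series
#'
#' For each timepoint image, bits are detected by adaptive thresholding
#' plus small-object removal and connected-component counting; retention
#' is the percentage of detected bits out of the total transferred bits
#' at baseline.
#'
#' @param images List of greyscale matrices (one per timepoint), or a
#'   single matrix.
#' @param baseline_total Total transferred bits at baseline (> 0), e.g.
#'   96 for a 10x10 patch with four needles removed for orientation.
#' @param timepoints Optional labels (defaults to 1..T).
#' @param window,offset Passed to [binarize_adaptive()].
#' @param min_px Passed to [clean_binary()].
#' @return Data frame `timepoint`, `detected`, `total`, `retention_pct`.
#' @export
signal_retention <- function(images, baseline_total, timepoints = NULL,
                             window = 41L, offset = 0.02, min_px = 9L) {
  if (is.matrix(images)) images <- list(images)
  if (length(images) < 1) stop("need at least one timepoint", call. = FALSE)
  if (length(baseline_total) != 1L || baseline_total <= 0) {
    stop("baseline_total must be a positive count", call. = FALSE)
  }
  if (is.null(timepoints)) timepoints <- seq_along(images)
  detected <- vapply(images, function(im) {
    count_components(binarize_adaptive(im, window, offset), min_px)
  }, integer(1))
  data.frame(timepoint = timepoints, detected = detected,
             total = baseline_total,
             retention_pct = 100 * detected / baseline_total)
}

#' Per-bit maximum signal intensity
#'
#' Evaluates the maximum pixel value within each ON bit's cell region.
#' Intensities are only comparable between images acquired with identical
#' gain/exposure; the acquisition settings id is attached to the result
#' and [compare_intensity()] refuses to compare across different ids
#' unless overridden.
#'
#' @param image Greyscale matrix.
#' @param grid `pattern_grid` of ON bits to measure.
#' @param centres Data frame `row`, `col`, `x`, `y` mapping grid cells to
#'   image coordinates (e.g. `sample$transform$centres`).
#' @param cell_px Half-side of the square measurement region per bit, px.
#' @param settings Acquisition settings identifier (gain/exposure combo).
#' @return Data frame `row`, `col`, `max_intensity`, with attribute
#'   `acq_settings`.
#' @export
signal_intensity <- function(image, grid, centres, cell_px = 8L,
                             settings = "default") {
  grid <- as_pattern_grid(grid)
  on <- which(unclass(grid) == 1L, arr.ind = TRUE)
  vals <- apply(on, 1, function(rc) {
    ci <- centres[centres$row == rc[1] & centres$col == rc[2], ]
    ys <- max(1, round(ci$y - cell_px)):min(nrow(image), round(ci$y + cell_px))
    xs <- max(1, round(ci$x - cell_px)):min(ncol(image), round(ci$x + cell_px))
    max(image[ys, xs])
  })
  out <- data.frame(row = on[, 1], col = on[, 2], max_intensity = vals)
  attr(out, "acq_settings") <- settings
  out
}

#' Compare per-bit intensity tables across timepoints
#'
#' @param a,b Results of [signal_intensity()].
#' @param override Set `TRUE` to force comparison across different
#'   acquisition settings (normally an error).
#' @return Data frame of medians and their difference (`b - a`).
#' @export
compare_intensity <- function(a, b, override = FALSE) {
  sa <- attr(a, "acq_settings"); sb <- attr(b, "acq_settings")
  if (!identical(sa, sb) && !override) {
    stop("intensities acquired under different gain/exposure settings are not comparable",
         call. = FALSE)
  }
  data.frame(median_a = stats::median(a$max_intensity),
             median_b = stats::median(b$max_intensity),
             difference = stats::median(b$max_intensity) - stats::median(a$max_intensity))
}
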
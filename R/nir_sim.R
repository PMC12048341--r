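#' Rendering parameter space for synthetic NIR patch images
#'
#' Declares the variation space the simulator samples from when turning a
#' bit grid into a greyscale fluorescence image: spot geometry (pitch,
#' Gaussian spot width), per-spot peak intensity, additive skin-like
#' background with Gaussian noise, small in-plane rotations (default
#' -5 to +5 degrees), scale and translation jitter, defocus and motion
#' blur, and acquisition gain/exposure. Every range is sampled once per
#' rendered image, deterministically from the sample's seed.
#'
#' @param N Grid side the parameters are sized for.
#' @param image_size Output image side in pixels (default 256, the
#'   binarizer's input contract).
#' @param pitch Pixels between adjacent bit centres; default
#'   `max(8, floor(200 / N))` (20 px for a 10x10 grid).
#' @param spot_sigma Gaussian spot width in pixels; default `pitch / 6`.
#' @param intensity_range Per-spot peak brightness interval (0-1 scale).
#' @param background_level,background_noise_sigma Additive background
#'   mean and Gaussian noise s.d.
#' @param rotation_range In-plane rotation interval in degrees.
#' @param scale_jitter_range Relative grid-size factor interval.
#' @param translation_jitter Max absolute shift of the grid centre, px.
#' @param blur_sigma_range Defocus blur sigma interval, px.
#' @param motion_blur_len_range Motion blur kernel length interval, px
#'   (lengths below 2 disable motion blur).
#' @param gain_range,exposure_range Multiplicative acquisition factors;
#'   the rendered image is clipped to [0, 1] afterwards.
#' @return Object of class `render_params`.
#' @export
render_params <- function(N = 10,
                          image_size = 256L,
                          pitch = max(8L, floor(200 / N)),
                          spot_sigma = pitch / 6,
                          intensity_range = c(0.55, 0.95),
                          background_level = 0.08,
                          background_noise_sigma = 0.02,
                          rotation_range = c(-5, 5),
                          scale_jitter_range = c(0.95, 1.05),
                          translation_jitter = 4,
                          blur_sigma_range = c(0.3, 1.0),
                          motion_blur_len_range = c(0, 3),
                          gain_range = c(0.9, 1.1),
                          exposure_range = c(0.9, 1.1)) {
  structure(
    list(N = N, image_size = as.integer(image_size), pitch = pitch,
         spot_sigma = spot_sigma, intensity_range = intensity_range,
         background_level = background_level,
         background_noise_sigma = background_noise_sigma,
         rotation_range = rotation_range,
         scale_jitter_range = scale_jitter_range,
         translation_jitter = translation_jitter,
         blur_sigma_range = blur_sigma_range,
         motion_blur_len_range = motion_blur_len_range,
         gain_range = gain_range, exposure_range = exposure_range),
    class = "render_params"
  )
}

#' Low-variation rendering parameters
#'
#' Convenience preset with mid-range intensities, mild noise and no blur,
#' used for clean reference fixtures.
#' @inheritParams render_params
#' @param ... Overrides passed to [render_params()].
#' @export
render_params_clean <- function(N = 10, ...) {
  defaults <- list(N = N,
                   intensity_range = c(0.75, 0.85),
                   background_noise_sigma = 0.01,
                   blur_sigma_range = c(0, 0),
                   motion_blur_len_range = c(0, 0),
                   gain_range = c(1, 1), exposure_range = c(1, 1),
                   translation_jitter = 2)
  over <- list(...)
  do.call(render_params, utils::modifyList(defaults, over))
}

# Draw one concrete realization of every ranged parameter.
sample_render_draw <- function(params, seed) {
  with_local_seed(seed, {
    runif1 <- function(rg) stats::runif(1, rg[1], rg[2])
    list(
      rotation = runif1(params$rotation_range),
      scale = runif1(params$scale_jitter_range),
      tx = stats::runif(1, -params$translation_jitter, params$translation_jitter),
      ty = stats::runif(1, -params$translation_jitter, params$translation_jitter),
      blur_sigma = runif1(params$blur_sigma_range),
      motion_len = round(runif1(params$motion_blur_len_range)),
      motion_angle = stats::runif(1, 0, 180),
      gain = runif1(params$gain_range),
      exposure = runif1(params$exposure_range)
    )
  })
}

# Map grid cell coordinates to image pixel coordinates.
# Returns a data frame with columns row, col, x, y.
grid_cell_centres <- function(N, image_size, pitch, rotation_deg, scale, tx, ty) {
  cells <- expand.grid(col = 1:N, row = 1:N)[, c("row", "col")]
  u <- (cells$col - (N + 1) / 2) * pitch * scale
  v <- (cells$row - (N + 1) / 2) * pitch * scale
  th <- rotation_deg * pi / 180
  cx <- (image_size + 1) / 2 + tx
  cy <- (image_size + 1) / 2 + ty
  data.frame(row = cells$row, col = cells$col,
             x = cx + u * cos(th) - v * sin(th),
             y = cy + u * sin(th) + v * cos(th))
}

#' Render a bit grid as a synthetic NIR fluorescence image
#'
#' ON cells become isotropic Gaussian spots at their transformed centres
#' on a noisy skin-like background; the image then passes through defocus
#' blur, optional motion blur, and gain/exposure scaling, and is clipped
#' to [0, 1]. Rendering is a pure function of `(grid, params, seed)`.
#'
#' @param grid `pattern_grid` to render (typically already masked, and
#'   possibly degraded).
#' @param params A [render_params()] object.
#' @param seed Integer seed controlling every random draw of this render.
#' @param spot_attenuation Optional vector of per-ON-spot brightness
#'   multipliers (recycled), emulating partial dye fading.
#' @return Object of class `synthetic_sample`: `image` (matrix, rows =
#'   image y), `truth_grid`, `observed_grid`, `transform` (rotation,
#'   scale, translation, pitch, cell centres), `retention` (1 unless set
#'   by a caller that degraded the grid), `draw` (sampled parameters),
#'   `seed`.
#' @export
render_patch <- function(grid, params = render_params(nrow(grid)), seed = 1L,
                         spot_attenuation = 1) {
  grid <- as_pattern_grid(grid)
  N <- nrow(grid)
  size <- params$image_size
  draw <- sample_render_draw(params, seed)

  centres <- grid_cell_centres(N, size, params$pitch, draw$rotation,
                               draw$scale, draw$tx, draw$ty)
  margin <- 4 * params$spot_sigma + 1
  if (any(centres$x < margin | centres$x > size - margin |
          centres$y < margin | centres$y > size - margin)) {
    stop("grid does not fit in the image at this pitch/scale/translation",
         call. = FALSE)
  }

  on_idx <- which(grid[cbind(centres$row, centres$col)] == 1L)
  img <- with_local_seed(seed + 1L, {
    im <- matrix(params$background_level +
                   stats::rnorm(size * size, 0, params$background_noise_sigma),
                 size, size)
    peaks <- stats::runif(length(on_idx), params$intensity_range[1],
                          params$intensity_range[2]) *
      rep_len(spot_attenuation, length(on_idx))
    w <- ceiling(4 * params$spot_sigma)
    s2 <- 2 * params$spot_sigma^2
    for (ii in seq_along(on_idx)) {
      cx <- centres$x[on_idx[ii]]; cy <- centres$y[on_idx[ii]]
      xs <- max(1, floor(cx - w)):min(size, ceiling(cx + w))
      ys <- max(1, floor(cy - w)):min(size, ceiling(cy + w))
      spot <- peaks[ii] * outer(exp(-(ys - cy)^2 / s2), exp(-(xs - cx)^2 / s2))
      im[ys, xs] <- im[ys, xs] + spot
    }
    im
  })

  if (draw$blur_sigma > 0.05) img <- EBImage::gblur(img, draw$blur_sigma)
  if (draw$motion_len >= 2) {
    img <- motion_blur(img, draw$motion_len, draw$motion_angle)
  }
  img <- pmin(pmax(img * draw$gain * draw$exposure, 0), 1)

  structure(
    list(image = img, truth_grid = grid, observed_grid = grid,
         transform = list(rotation = draw$rotation, scale = draw$scale,
                          tx = draw$tx, ty = draw$ty, pitch = params$pitch,
                          centres = centres),
         retention = 1, draw = draw, params = params, seed = seed),
    class = "synthetic_sample"
  )
}

# Convolve with a normalized line kernel of given length/angle.
motion_blur <- function(img, len, angle_deg) {
  len <- max(2L, round(len))
  th <- angle_deg * pi / 180
  half <- (len - 1) / 2
  ts <- seq(-half, half, length.out = len)
  xs <- round(ts * cos(th)); ys <- round(ts * sin(th))
  side <- 2 * max(abs(c(xs, ys))) + 1
  kern <- matrix(0, side, side)
  kern[cbind(ys + (side + 1) / 2, xs + (side + 1) / 2)] <- 1
  kern <- kern / sum(kern)
  EBImage::filter2(img, kern, boundary = "replicate")
}

#' Longitudinal degradation tiers
#'
#' The dataset-level mix of bit-retention levels used when generating
#' training/evaluation imagery: fractions 1.00, 0.75, 0.50 and 0.25 of ON
#' bits surviving, mixed in proportions 5%, 15%, 60% and 20% of samples
#' respectively, emulating patches imaged at increasing ages.
#'
#' @param retention_levels Fractions of ON bits surviving.
#' @param portion_weights Mixing proportions (must sum to 1).
#' @param attenuation_range Per-surviving-spot brightness multiplier
#'   interval applied at render time.
#' @return Object of class `degradation_spec`.
#' @export
degradation_spec <- function(retention_levels = c(1.00, 0.75, 0.50, 0.25),
                             portion_weights = c(0.05, 0.15, 0.60, 0.20),
                             attenuation_range = c(0.6, 1.0)) {
  stopifnot(length(retention_levels) == length(portion_weights),
            all(retention_levels > 0), all(retention_levels <= 1))
  if (abs(sum(portion_weights) - 1) > 1e-8) {
    stop("portion weights must sum to 1", call. = FALSE)
  }
  structure(list(retention_levels = retention_levels,
                 portion_weights = portion_weights,
                 attenuation_range = attenuation_range),
            class = "degradation_spec")
}

#' Degrade a grid by random ON-bit dropout
#'
#' Each ON cell survives independently with probability `retention`; OFF
#' cells are never turned ON (degradation is strictly one-sided, as when
#' deposited dye fades or is cleared). Deterministic given the seed.
#'
#' @param grid `pattern_grid`.
#' @param retention Survival probability in (0, 1].
#' @param seed Integer seed.
#' @return Degraded `pattern_grid`.
#' @export
degrade_grid <- function(grid, retention, seed = 1L) {
  grid <- as_pattern_grid(grid)
  if (length(retention) != 1L || is.na(retention) ||
      retention <= 0 || retention > 1) {
    stop("retention must lie in (0, 1]", call. = FALSE)
  }
  if (retention == 1) return(grid)
  on <- which(unclass(grid) == 1L)
  keep <- with_local_seed(seed, stats::runif(length(on)) < retention)
  out <- unclass(grid)
  out[on[!keep]] <- 0L
  as_pattern_grid(out)
}

#' Generate a seeded synthetic dataset with ground truth
#'
#' Draws random payloads, encodes them with the configuration's code,
#' template and mask, assigns each sample a retention tier according to
#' the degradation spec's portion weights, applies one-sided bit dropout,
#' renders the degraded grid, and records everything in a manifest. A
#' 90/10 train/validation split is assigned. The whole dataset is a pure
#' function of `(n, config, seed)`.
#'
#' @param n Number of samples.
#' @param config A [codec_config()].
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param render If `FALSE`, only the manifest (payloads, tiers, seeds,
#'   splits) is produced — useful for large composition checks.
#' @param degradation A [degradation_spec()].
#' @return List with `manifest` (data frame: `id`, `seed`, `payload`,
#'   `retention`, `split`) and `samples` (list of `synthetic_sample`, or
#'   `NULL` when `render = FALSE`).
#' @export
sample_dataset <- function(n, config, seed = 1L, render = TRUE,
                           degradation = config$degradation) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n + 1L)
  k <- config$code$k
  meta <- with_local_seed(seeds[n + 1L], {
    tier <- sample(seq_along(degradation$retention_levels), n, replace = TRUE,
                   prob = degradation$portion_weights)
    payload <- floor(stats::runif(n) * 2^k)
    split <- ifelse(stats::runif(n) < 0.9, "train", "validation")
    data.frame(id = seq_len(n), seed = seeds[seq_len(n)], payload = payload,
               retention = degradation$retention_levels[tier], split = split)
  })
  samples <- NULL
  if (render) {
    samples <- lapply(seq_len(n), function(i) {
      enc <- encode_info(meta$payload[i], config)
      obs <- degrade_grid(enc$grid, meta$retention[i], seed = meta$seed[i])
      att <- with_local_seed(meta$seed[i] + 2L,
                             stats::runif(sum(obs == 1L),
                                          degradation$attenuation_range[1],
                                          degradation$attenuation_range[2]))
      s <- render_patch(obs, config$render, seed = meta$seed[i],
                        spot_attenuation = att)
      s$truth_grid <- enc$grid
      s$observed_grid <- obs
      s$retention <- meta$retention[i]
      s$payload <- meta$payload[i]
      s
    })
  }
  list(manifest = meta, samples = samples)
}

#' Impulse-noise augmentation
#'
#' Applies salt-and-pepper noise, erases small random rectangles (filled
#' with the background level), and optionally Gaussian-blurs the result —
#' the corruption family used to harden binarization against impulse
#' artefacts. Deterministic given the seed.
#'
#' @param image Matrix with values in [0, 1].
#' @param seed Integer seed.
#' @param density Fraction of pixels hit by salt (to 1) or pepper (to 0).
#' @param n_rect Number of rectangles to erase.
#' @param rect_side_range Rectangle side interval, px.
#' @param background Fill level for erased rectangles.
#' @param blur_sigma Gaussian blur sigma (0 disables).
#' @return Corrupted image matrix in [0, 1].
#' @export
augment_impulse <- function(image, seed = 1L, density = 0.02, n_rect = 2L,
                            rect_side_range = c(4L, 12L), background = 0.08,
                            blur_sigma = 0) {
  stopifnot(min(image) >= 0, max(image) <= 1)
  img <- with_local_seed(seed, {
    im <- image
    npix <- length(im)
    if (density > 0) {
      hit <- which(stats::runif(npix) < density)
      salt <- stats::runif(length(hit)) < 0.5
      im[hit[salt]] <- 1
      im[hit[!salt]] <- 0
    }
    if (n_rect > 0) {
      for (i in seq_len(n_rect)) {
        h <- sample(rect_side_range[1]:rect_side_range[2], 1)
        w <- sample(rect_side_range[1]:rect_side_range[2], 1)
        r0 <- sample(nrow(im) - h + 1, 1)
        c0 <- sample(ncol(im) - w + 1, 1)
        im[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- background
      }
    }
    im
  })
  if (blur_sigma > 0) img <- EBImage::gblur(img, blur_sigma)
  pmin(pmax(img, 0), 1)
}

#' Write a rendered sample (or plain matrix) as a greyscale PNG
#'
#' Images are kept as floats internally and quantized to 8 bits on
#' export; use a TIFF writer directly for 16-bit exports.
#'
#' @param image `synthetic_sample` or numeric matrix in [0, 1].
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  if (inherits(image, "synthetic_sample")) image <- image$image
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a greyscale image (PNG) into a [0, 1] matrix
#' @param path PNG file; RGB inputs are averaged to greyscale.
#' @return Numeric matrix.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
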
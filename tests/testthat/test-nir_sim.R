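test_that("an all-OFF grid renders as pure background", {
  g <- as_pattern_grid(matrix(0L, 10, 10))
  p <- render_params_clean(10)
  s <- render_patch(g, p, seed = 1)
  se <- p$background_noise_sigma / sqrt(length(s$image))
  expect_lt(abs(mean(s$image) - p$background_level), 3 * se + 1e-3)
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("sampled rotations always lie in the declared -5..+5 degree range", {
  p <- render_params(10)
  rots <- vapply(1:10000, function(s) sample_render_draw(p, s)$rotation, numeric(1))
  expect_gte(min(rots), -5)
  expect_lte(max(rots), 5)
  # and the draws cover the range rather than collapsing
  expect_lt(min(rots), -4.5)
  expect_gt(max(rots), 4.5)
})

test_that("rendering is deterministic and ON centres dominate the background", {
  set.seed(8)
  tpl <- grid_template(10)
  g <- place_bits(tpl, rbinom(64, 1, 0.5))
  p <- render_params_clean(10)
  s1 <- render_patch(g, p, seed = 99)
  s2 <- render_patch(g, p, seed = 99)
  expect_identical(s1$image, s2$image)
  # every ON-cell centre pixel exceeds the 99th percentile of background
  ctr <- s1$transform$centres
  on <- which(unclass(g)[cbind(ctr$row, ctr$col)] == 1L)
  centre_vals <- s1$image[cbind(round(ctr$y[on]), round(ctr$x[on]))]
  off_cells <- which(unclass(g)[cbind(ctr$row, ctr$col)] == 0L)
  bg_vals <- s1$image[cbind(round(ctr$y[off_cells]), round(ctr$x[off_cells]))]
  expect_true(all(centre_vals > quantile(bg_vals, 0.99)))
})

test_that("a grid that does not fit the frame is a geometry error", {
  g <- as_pattern_grid(matrix(1L, 17, 17))
  p <- render_params(17, pitch = 40)
  expect_error(render_patch(g, p, seed = 1), "does not fit")
})

test_that("inverting the stored transform maps spot centroids to cell centres", {
  set.seed(21)
  tpl <- grid_template(10)
  cfg_mask <- make_mask(10, 5)
  g <- apply_mask(place_bits(tpl, rbinom(64, 1, 0.5)), cfg_mask)
  p <- render_params_clean(10, background_noise_sigma = 0)
  s <- render_patch(g, p, seed = 17)
  bin <- clean_binary(binarize_adaptive(s$image, 41, 0.02), 9)
  lab <- EBImage::bwlabel(bin)
  tr <- s$transform
  th <- -tr$rotation * pi / 180
  cx <- (nrow(s$image) + 1) / 2 + tr$tx
  cy <- (nrow(s$image) + 1) / 2 + tr$ty
  for (comp in seq_len(max(lab))) {
    px <- which(lab == comp, arr.ind = TRUE)
    x <- mean(px[, 2]) - cx; y <- mean(px[, 1]) - cy
    u <- (x * cos(th) - y * sin(th)) / (tr$pitch * tr$scale)
    v <- (x * sin(th) + y * cos(th)) / (tr$pitch * tr$scale)
    col <- u + (10 + 1) / 2; row <- v + (10 + 1) / 2
    expect_lt(abs(col - round(col)), 0.3)
    expect_lt(abs(row - round(row)), 0.3)
    expect_identical(unclass(g)[round(row), round(col)], 1L)
  }
})

test_that("degradation is one-sided, seeded and binomially concentrated", {
  set.seed(4)
  tpl <- grid_template(10)
  g <- place_bits(tpl, rbinom(64, 1, 0.5))
  expect_identical(unclass(degrade_grid(g, 1, seed = 1)), unclass(g))
  expect_identical(unclass(degrade_grid(g, 0.5, seed = 3)),
                   unclass(degrade_grid(g, 0.5, seed = 3)))
  d <- degrade_grid(g, 0.5, seed = 3)
  expect_true(all(unclass(d) <= unclass(g)))  # never creates ON from OFF
  # survivor fraction over 10,000 ON cells
  big <- as_pattern_grid(matrix(1L, 100, 100))
  surv <- mean(unclass(degrade_grid(big, 0.25, seed = 8)))
  expect_lt(abs(surv - 0.25), 0.015)
  expect_error(degrade_grid(g, 0), "retention")
  expect_error(degrade_grid(g, 1.2), "retention")
})

test_that("dataset tier mix follows the 5/15/60/20 portions and is reproducible", {
  cfg <- codec_config(N = 10, r = 1)
  ds1 <- sample_dataset(2000, cfg, seed = 42, render = FALSE)
  ds2 <- sample_dataset(2000, cfg, seed = 42, render = FALSE)
  expect_identical(ds1$manifest, ds2$manifest)
  counts <- table(factor(ds1$manifest$retention, levels = c(1, 0.75, 0.5, 0.25)))
  expected <- 2000 * c(0.05, 0.15, 0.60, 0.20)
  sds <- sqrt(2000 * c(0.05, 0.15, 0.60, 0.20) * (1 - c(0.05, 0.15, 0.60, 0.20)))
  expect_true(all(abs(as.numeric(counts) - expected) <= 3 * sds))
  # payloads respect capacity and the split is roughly 90/10
  expect_true(all(ds1$manifest$payload >= 0 & ds1$manifest$payload < 128))
  expect_lt(abs(mean(ds1$manifest$split == "train") - 0.9), 0.03)
})

test_that("rendered samples keep truth and observed grids consistent", {
  cfg <- codec_config(N = 10, r = 1)
  ds <- sample_dataset(6, cfg, seed = 7, render = TRUE)
  for (s in ds$samples) {
    expect_true(all(unclass(s$observed_grid) <= unclass(s$truth_grid)))
    if (s$retention == 1) {
      expect_identical(unclass(s$observed_grid), unclass(s$truth_grid))
    }
    expect_s3_class(s, "synthetic_sample")
  }
  # bit-identical rerun
  ds2 <- sample_dataset(6, cfg, seed = 7, render = TRUE)
  expect_identical(ds$samples[[3]]$image, ds2$samples[[3]]$image)
})

test_that("impulse augmentation corrupts the declared pixel fraction", {
  img <- matrix(0.5, 256, 256)
  # zero-strength augmentation is the identity
  expect_identical(augment_impulse(img, seed = 1, density = 0, n_rect = 0), img)
  out <- augment_impulse(img, seed = 2, density = 0.02, n_rect = 0)
  frac <- mean(out != 0.5)
  expect_lt(abs(frac - 0.02), 0.005)
  expect_true(all(out %in% c(0, 0.5, 1)))
  # rectangles are erased to the background level, wholly inside the frame
  out2 <- augment_impulse(img, seed = 3, density = 0, n_rect = 3, background = 0.1)
  expect_true(all(out2 %in% c(0.5, 0.1)))
  expect_identical(augment_impulse(img, seed = 3, density = 0, n_rect = 3, background = 0.1), out2)
})

test_that("PNG export round-trips rendered images to 8-bit precision", {
  set.seed(5)
  tpl <- grid_template(10)
  s <- render_patch(place_bits(tpl, rbinom(64, 1, 0.5)), render_params_clean(10), seed = 3)
  f <- withr::local_tempfile(fileext = ".png")
  write_image_png(s, f)
  back <- read_image_png(f)
  expect_lt(max(abs(back - s$image)), 1 / 255)
})
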
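#' Configuration for an encode/decode pipeline
#'
#' Bundles everything a patch codec needs: grid side, RM code order,
#' template, encryption mask seed, rendering parameter space, degradation
#' tiers, classical reader settings, and an optional payload codebook.
#' The code length is tied to the template: `2^m` must equal the
#' template's encoding bits, so `m` is derived from `N` and only the
#' order `r` is chosen.
#'
#' @param N Grid side (10, 12 and 17 are the standard layouts).
#' @param r RM code order (1 gives maximum error correction among the
#'   standard choices; 2 gives maximum capacity).
#' @param mask_seed Seed of the fixed encryption mask (the decipher key).
#' @param render A [render_params()] object (defaults to the standard
#'   space for this N).
#' @param degradation A [degradation_spec()].
#' @param codebook Optional named list or JSON file path mapping payload
#'   integers (as names) to human-readable labels.
#' @param binarize_window,binarize_offset,min_component_px Classical
#'   reader settings; the window defaults to twice the render pitch plus
#'   one so it spans a spot and its surround.
#' @return Object of class `codec_config`.
#' @examples
#' cfg <- codec_config(N = 10, r = 1)
#' cfg$code$k   # 7 information bits -> 128 payloads
#' @export
codec_config <- function(N = 10, r = 1, mask_seed = 20260101L,
                         render = NULL, degradation = degradation_spec(),
                         codebook = NULL,
                         binarize_window = NULL, binarize_offset = 0.02,
                         min_component_px = 9L) {
  template <- grid_template(N)
  m <- as.integer(round(log2(template$encoding_bits)))
  code <- rm_code(r, m)
  if (code$n != template$encoding_bits) {
    stop("code length does not match the template's encoding bits", call. = FALSE)
  }
  if (is.null(render)) render <- render_params(N)
  if (is.character(codebook)) {
    codebook <- jsonlite::read_json(codebook, simplifyVector = FALSE)
  }
  if (is.null(binarize_window)) binarize_window <- 2L * ceiling(render$pitch) + 1L
  mask <- make_mask(N, mask_seed, template)
  structure(
    list(N = N, r = r, m = m, code = code, template = template,
         mask = mask, mask_seed = mask_seed, render = render,
         degradation = degradation, codebook = codebook,
         binarize_window = binarize_window,
         binarize_offset = binarize_offset,
         min_component_px = min_component_px),
    class = "codec_config"
  )
}

#' @export
print.codec_config <- function(x, ...) {
  cat(sprintf("codec_config: %dx%d grid, RM(%d, %d), k = %d (%s payloads), corrects %d bits\n",
              x$N, x$N, x$r, x$m, x$code$k,
              format(2^x$code$k, big.mark = ","), x$code$t))
  invisible(x)
}

#' Encode a payload into a fabricable patch pattern
#'
#' ECC-encodes the payload, lays the codeword on the grid template with
#' its orientation markers, and applies the fixed encryption mask. The
#' result is the bit pattern to fabricate, plus the ON-cell coordinate
#' list used for fabrication.
#'
#' @param payload Non-negative integer `< 2^k`, or a length-k bit vector.
#' @param config A [codec_config()].
#' @return List: `grid` (masked `pattern_grid`), `fabrication`
#'   (`row`,`col` data frame of ON cells), `info_bits`, `payload`.
#' @export
encode_info <- function(payload, config) {
  k <- config$code$k
  if (length(payload) == 1L && !is.character(payload)) {
    info <- payload_to_bits(payload, k)
  } else {
    info <- as_bits(payload)
    if (length(info) != k) {
      stop(sprintf("info bit vector must have length k = %d", k), call. = FALSE)
    }
  }
  codeword <- rm_encode(config$code, info)
  grid <- apply_mask(place_bits(config$template, codeword), config$mask)
  list(grid = grid, fabrication = fabrication_export(grid),
       info_bits = info, payload = bits_to_payload(info))
}

#' Decode a recognized bit grid (orientation, mask, ECC)
#'
#' The grid-level half of decoding: recover orientation from the corner
#' markers, remove the encryption mask, extract the codeword in raster
#' order, and run majority-logic error correction.
#'
#' @param grid Observed N x N 0/1 matrix in any 90-degree orientation.
#' @param config A [codec_config()].
#' @return Object of class `decode_result`: `payload`, `label` (codebook
#'   entry or `NA`), `info_bits`, `n_corrected`, `orientation`,
#'   `marker_errors`, `low_confidence`.
#' @export
decode_grid <- function(grid, config) {
  ori <- detect_orientation(grid, config$template)
  unmasked <- apply_mask(ori$grid, config$mask)
  codeword <- extract_bits(config$template, unmasked)
  dec <- rm_decode(config$code, codeword)
  payload <- bits_to_payload(dec$info)
  label <- NA_character_
  if (!is.null(config$codebook)) {
    hit <- config$codebook[[as.character(payload)]]
    if (!is.null(hit)) label <- as.character(hit)
  }
  structure(
    list(payload = payload, label = label, info_bits = dec$info,
         n_corrected = dec$n_corrected, orientation = ori$rotation,
         marker_errors = ori$marker_errors,
         low_confidence = dec$low_confidence),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decoded payload %s%s (corrected %d bits, rotation %d deg, %d marker errors%s)\n",
              format(x$payload),
              if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
              x$n_corrected, x$orientation, x$marker_errors,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Decode a raw patch image end to end
#'
#' Runs the full automatic chain with no per-image thresholds:
#' adaptive binarization, small-object removal, minimum-area-rectangle
#' rectification, grid bit recognition, orientation recovery from the
#' corner markers, mask removal, codeword extraction and majority-logic
#' error correction.
#'
#' @param image Greyscale matrix in [0, 1], a `synthetic_sample`, or a
#'   PNG file path.
#' @param config A [codec_config()].
#' @return `decode_result` (see [decode_grid()]), with the intermediate
#'   `read_grid` attached as attribute `"read_grid"`.
#' @export
decode_image <- function(image, config) {
  if (is.character(image)) image <- read_image_png(image)
  if (inherits(image, "synthetic_sample")) image <- image$image
  binary <- clean_binary(
    binarize_adaptive(image, config$binarize_window, config$binarize_offset),
    config$min_component_px
  )
  rect <- rectify(binary, target_side = 256L)
  grid <- read_grid(rect, config$N)
  res <- decode_grid(grid, config)
  attr(res, "read_grid") <- grid
  attr(res, "recovered_angle") <- rect$recovered_angle
  res
}

#' Evaluate decoding over a synthetic dataset
#'
#' Decodes every rendered sample and scores it against its ground truth:
#' exact payload match (the pattern decodability criterion), per-bit
#' detection and spurious-ON rates of the recognized grid against the
#' degraded truth, corrected-bit counts, and a per-retention-tier
#' breakdown.
#'
#' @param dataset Result of [sample_dataset()] (with rendered samples).
#' @param config The [codec_config()] used to generate it.
#' @return List with `per_sample` (data frame), `summary` (list:
#'   `success_rate`, `bit_detection_rate`, `spurious_on_rate`,
#'   `mean_corrected`), and `by_tier` (data frame).
#' @export
evaluate_dataset <- function(dataset, config) {
  if (is.null(dataset$samples)) stop("dataset has no rendered samples", call. = FALSE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    res <- tryCatch(decode_image(s$image, config), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(id = i, payload = s$payload, decoded = NA_real_,
                        success = FALSE, n_corrected = NA_integer_,
                        retention = s$retention, detected_on = NA_integer_,
                        missed_on = NA_integer_, spurious_on = NA_integer_))
    }
    rg <- attr(res, "read_grid")
    ori <- tryCatch(detect_orientation(rg, config$template), error = function(e) NULL)
    obs <- unclass(s$observed_grid)
    if (!is.null(ori)) {
      got <- unclass(ori$grid)
      detected <- sum(got == 1L & obs == 1L)
      missed <- sum(got == 0L & obs == 1L)
      spurious <- sum(got == 1L & obs == 0L)
    } else {
      detected <- missed <- spurious <- NA_integer_
    }
    data.frame(id = i, payload = s$payload, decoded = res$payload,
               success = identical(res$payload, s$payload),
               n_corrected = res$n_corrected, retention = s$retention,
               detected_on = detected, missed_on = missed,
               spurious_on = spurious)
  })
  per_sample <- do.call(rbind, rows)
  n_obs_on <- per_sample$detected_on + per_sample$missed_on
  n_obs_off <- config$N^2 - n_obs_on
  summary <- list(
    success_rate = mean(per_sample$success),
    bit_detection_rate = sum(per_sample$detected_on, na.rm = TRUE) /
      max(1, sum(n_obs_on, na.rm = TRUE)),
    spurious_on_rate = sum(per_sample$spurious_on, na.rm = TRUE) /
      max(1, sum(n_obs_off, na.rm = TRUE)),
    mean_corrected = mean(per_sample$n_corrected, na.rm = TRUE)
  )
  by_tier <- do.call(rbind, lapply(split(per_sample, per_sample$retention), function(d) {
    data.frame(retention = d$retention[1], n = nrow(d),
               success_rate = mean(d$success),
               mean_corrected = mean(d$n_corrected, na.rm = TRUE))
  }))
  rownames(by_tier) <- NULL
  list(per_sample = per_sample, summary = summary, by_tier = by_tier)
}

#' Write an evaluation report to CSV and JSON
#' @param report Result of [evaluate_dataset()].
#' @param csv,json Output paths (either may be `NULL`).
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$per_sample, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(summary = report$summary, by_tier = report$by_tier),
                         json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Generate a deterministic fixture tree on disk
#'
#' Writes small seeded fixture sets (clean renders, degraded tiers,
#' rotated copies, impulse-augmented copies) with PNG images, truth-grid
#' CSVs and a JSON manifest, for demos and external tooling. The `small`
#' scale finishes in well under two minutes on one CPU.
#'
#' @param dir Output directory (created if needed).
#' @param scale `"small"` (12 samples) or `"full"` (60 samples).
#' @param seed Master seed.
#' @param config A [codec_config()].
#' @return Invisibly, the manifest data frame.
#' @export
make_fixtures <- function(dir, scale = c("small", "full"), seed = 1L,
                          config = codec_config()) {
  scale <- match.arg(scale)
  n <- if (scale == "small") 12L else 60L
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sample_dataset(n, config, seed = seed)
  manifest <- ds$manifest
  manifest$image <- sprintf("sample_%03d.png", manifest$id)
  manifest$truth <- sprintf("truth_%03d.csv", manifest$id)
  for (i in seq_len(n)) {
    s <- ds$samples[[i]]
    img <- s$image
    if (i %% 4L == 0L) {   # every 4th sample also gets impulse corruption
      img <- augment_impulse(img, seed = manifest$seed[i])
      manifest$image[i] <- sprintf("sample_%03d_impulse.png", i)
    }
    write_image_png(img, file.path(dir, manifest$image[i]))
    write_grid_csv(s$truth_grid, file.path(dir, manifest$truth[i]))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
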
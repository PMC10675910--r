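#' Preprocessing configuration
#'
#' Bundles the tunables of the automatic cleaning pipeline. Stages run in the
#' fixed order: (1) quality filtering, (2) text removal, (3) inpainting-style
#' fill (applied as part of any region removal), (4) object removal,
#' (5) margin crop and resize.
#'
#' @param quality_threshold Minimum Laplacian-variance score an image must
#'   reach to be kept (default 100; uniform frames score 0, sharp frames with
#'   sensor noise score in the thousands).
#' @param margin_intensity_cutoff Luminance value (0-255) at or below which a
#'   pixel counts as black margin (default 10).
#' @param output_size `c(H, W)` of cleaned images (default 64 x 64).
#' @param stages Named logical flags enabling `quality`, `text_removal`,
#'   `object_removal`, `crop_resize`.
#' @param fill_strategy Fill used when regions are removed: `"mean_fill"` or
#'   `"diffusion"` (iterative harmonic fill).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(quality_threshold = 100,
                              margin_intensity_cutoff = 10L,
                              output_size = c(64L, 64L),
                              stages = c(quality = TRUE, text_removal = FALSE,
                                         object_removal = FALSE,
                                         crop_resize = TRUE),
                              fill_strategy = c("mean_fill", "diffusion")) {
  stopifnot(quality_threshold >= 0,
            margin_intensity_cutoff >= 0, margin_intensity_cutoff <= 255,
            length(output_size) == 2L, all(output_size >= 1))
  defaults <- c(quality = TRUE, text_removal = FALSE,
                object_removal = FALSE, crop_resize = TRUE)
  defaults[names(stages)] <- stages
  structure(
    list(quality_threshold = quality_threshold,
         margin_intensity_cutoff = as.integer(margin_intensity_cutoff),
         output_size = as.integer(output_size),
         stages = defaults,
         fill_strategy = match.arg(fill_strategy)),
    class = "preprocess_config")
}

#' Laplacian-variance quality score
#'
#' The sharpness score used to weed out uninformative frames (solid-colour or
#' heavily blurred snapshots): the variance of the 3x3 discrete Laplacian
#' `[[0,1,0],[1,-4,1],[0,1,0]]` applied to the luminance channel. The response
#' is computed on interior pixels only (no padding), so the score is invariant
#' to adding a constant to all pixels and scales quadratically when
#' intensities are scaled. Uniform images score exactly 0.
#'
#' @param image An [image_record()] or an `H x W x 3` pixel array.
#' @return Non-negative scalar; 0 (with a warning) when the image has no
#'   interior pixel (either dimension < 3).
#' @export
laplacian_quality_score <- function(image) {
  lum <- luminance(image)
  h <- nrow(lum); w <- ncol(lum)
  if (h < 3L || w < 3L) {
    warning("image too small for a Laplacian interior response; score 0")
    return(0)
  }
  ci <- 2:(h - 1L); cj <- 2:(w - 1L)
  resp <- lum[ci - 1L, cj] + lum[ci + 1L, cj] +
    lum[ci, cj - 1L] + lum[ci, cj + 1L] - 4 * lum[ci, cj]
  if (length(resp) < 2L) return(0)
  stats::var(as.vector(resp))
}

#' Partition images by quality score
#'
#' Keeps images whose Laplacian-variance score is at least `threshold`
#' (`score >= threshold`), preserving input order in both parts.
#'
#' @param images List of [image_record()]s.
#' @param threshold Non-negative score threshold.
#' @return List with `kept`, `discarded` (lists of records) and `reports`, a
#'   data frame with one row per input: `image_id`, `score`, `threshold`,
#'   `kept`.
#' @export
filter_low_quality <- function(images, threshold) {
  stopifnot(threshold >= 0)
  if (!length(images))
    return(list(kept = list(), discarded = list(),
                reports = data.frame(image_id = character(0),
                                     score = numeric(0),
                                     threshold = numeric(0),
                                     kept = logical(0))))
  scores <- vapply(images, laplacian_quality_score, numeric(1))
  keep <- scores >= threshold
  list(kept = images[keep], discarded = images[!keep],
       reports = data.frame(
         image_id = vapply(images, function(im) im$image_id, character(1)),
         score = scores, threshold = threshold, kept = keep,
         stringsAsFactors = FALSE))
}

#' Bounding box of non-black content
#'
#' Finds the smallest axis-aligned rectangle containing every pixel whose
#' luminance exceeds `intensity_cutoff` — the content inside the black margin
#' that frames endoscopic snapshots. Coordinates are 0-based half-open
#' `(row0, col0, row1, col1)`, i.e. the content spans R rows
#' `(row0+1):row1` and columns `(col0+1):col1`.
#'
#' @param image [image_record()] or pixel array.
#' @param intensity_cutoff Luminance cutoff in `[0, 255]`.
#' @return Integer vector `c(row0, col0, row1, col1)`.
#' @export
detect_black_margin <- function(image, intensity_cutoff = 10L) {
  stopifnot(intensity_cutoff >= 0, intensity_cutoff <= 255)
  lum <- luminance(image)
  bright <- lum > intensity_cutoff
  if (!any(bright)) stop("all-black image: no pixel above cutoff")
  rows <- which(rowSums(bright) > 0)
  cols <- which(colSums(bright) > 0)
  c(row0 = min(rows) - 1L, col0 = min(cols) - 1L,
    row1 = max(rows), col1 = max(cols))
}

#' Crop to a rectangle and resize
#'
#' Cropping (half-open 0-based box, as produced by [detect_black_margin()])
#' precedes bilinear resizing to `output_size`. When the crop already has the
#' requested size the pixels pass through untouched.
#'
#' @param image [image_record()].
#' @param box `c(row0, col0, row1, col1)`, half-open, within bounds.
#' @param output_size `c(H, W)`.
#' @return An [image_record()] with the same ids and resized pixels.
#' @export
crop_resize <- function(image, box, output_size) {
  d <- dim(image$pixels)
  box <- as.integer(box)
  if (box[3] <= box[1] || box[4] <= box[2]) stop("empty crop rectangle")
  if (box[1] < 0L || box[2] < 0L || box[3] > d[1] || box[4] > d[2])
    stop("crop rectangle out of bounds")
  crop <- image$pixels[(box[1] + 1L):box[3], (box[2] + 1L):box[4], ,
                       drop = FALSE]
  out <- resize_rgb(crop, output_size[1], output_size[2])
  image_record(image$patient_id, image$image_id, out,
               source_path = image$source_path)
}

#' Region mask for artifact removal
#'
#' Marks pixels to be removed (text overlays, probes, other external
#' objects). Either a full boolean mask or a list of half-open 0-based boxes
#' may be given; boxes are rasterized into the mask.
#'
#' @param image_id Image the mask belongs to.
#' @param mask `H x W` logical matrix (`TRUE` = remove), or `NULL` when
#'   `boxes` with `shape` are given.
#' @param boxes Optional list of `c(row0, col0, row1, col1)` rectangles.
#' @param shape `c(H, W)`, required when `mask` is `NULL`.
#' @return Object of class `region_mask` with fields `image_id`, `mask`,
#'   `boxes`.
#' @export
region_mask <- function(image_id, mask = NULL, boxes = NULL, shape = NULL) {
  if (is.null(mask)) {
    stopifnot(!is.null(shape))
    mask <- matrix(FALSE, shape[1], shape[2])
  }
  for (b in boxes) {
    b <- as.integer(b)
    if (b[1] < 0L || b[2] < 0L || b[3] > nrow(mask) || b[4] > ncol(mask))
      stop("box out of bounds")
    if (b[3] > b[1] && b[4] > b[2])
      mask[(b[1] + 1L):b[3], (b[2] + 1L):b[4]] <- TRUE
  }
  structure(list(image_id = image_id, mask = mask, boxes = boxes),
            class = "region_mask")
}

#' Remove masked regions and fill them
#'
#' Pixels outside the mask are untouched. `mean_fill` replaces masked pixels
#' by the per-channel mean of unmasked pixels (integer-rounded); `diffusion`
#' fills by iterated harmonic averaging from the unmasked boundary, a
#' diffusion-style stand-in for learned inpainting.
#'
#' @param image [image_record()].
#' @param mask A [region_mask()] (or bare logical matrix) aligned to the
#'   image.
#' @param fill_strategy `"mean_fill"` or `"diffusion"`.
#' @param diffusion_iters Sweeps of the harmonic fill.
#' @return An [image_record()] with regions filled.
#' @export
remove_regions <- function(image, mask,
                           fill_strategy = c("mean_fill", "diffusion"),
                           diffusion_iters = 60L) {
  fill_strategy <- match.arg(fill_strategy)
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  d <- dim(image$pixels)
  if (!identical(dim(m), d[1:2])) stop("mask shape does not match image")
  if (all(m)) stop("mask covers the entire image")
  if (!any(m)) return(image)
  px <- image$pixels
  if (fill_strategy == "mean_fill") {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- round(mean(plane[!m]))
      px[, , ch] <- plane
    }
  } else {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- mean(plane[!m])           # seed value
      for (it in seq_len(diffusion_iters)) {
        up <- plane[c(1L, seq_len(d[1] - 1L)), ]
        dn <- plane[c(seq_len(d[1] - 1L) + 1L, d[1]), ]
        lf <- plane[, c(1L, seq_len(d[2] - 1L))]
        rt <- plane[, c(seq_len(d[2] - 1L) + 1L, d[2])]
        avg <- (up + dn + lf + rt) / 4
        plane[m] <- avg[m]
      }
      px[, , ch] <- round(plane)
    }
  }
  image_record(image$patient_id, image$image_id, px,
               source_path = image$source_path)
}

#' Build a region detector from a fixed box table
#'
#' The cleaning pipeline treats text and object detection as pluggable
#' stages: a detector is any `function(image_record) -> region_mask`. This
#' constructor wires a precomputed table of boxes (e.g. from an external OCR
#' or detector run, or from generator bookkeeping) into that interface.
#'
#' @param boxes_by_image Named list: `image_id -> list of boxes`
#'   (`c(row0,col0,row1,col1)`, half-open 0-based).
#' @return A detector function; images without an entry get an empty mask.
#' @export
sidecar_box_detector <- function(boxes_by_image) {
  force(boxes_by_image)
  function(image) {
    d <- dim(image$pixels)
    region_mask(image$image_id, boxes = boxes_by_image[[image$image_id]],
                shape = d[1:2])
  }
}

#' Run the automatic cleaning pipeline over a cohort
#'
#' Applies the enabled stages in order — quality filtering, text removal (with
#' fill), object removal (with fill), margin crop + resize — to every image of
#' every patient. The patient-centric structure is preserved: patients whose
#' image list empties out are retained with an empty sequence and flagged in
#' the report. A failing detector plugin leaves the image unmodified and is
#' logged in the report rather than aborting the run.
#'
#' @param x A [cohort()].
#' @param config A [preprocess_config()].
#' @param detectors Optional named list of plugins with elements `text`
#'   and/or `object`, each a `function(image_record) -> region_mask`.
#' @return List with `cohort` (cleaned) and `report`, a data frame with one
#'   row per input image: `patient_id`, `image_id`, `score`, `kept`,
#'   `crop_box`, `stages_applied`, `plugin_error`.
#' @export
run_preprocess <- function(x, config = preprocess_config(),
                           detectors = list()) {
  stopifnot(inherits(x, "cohort"), inherits(config, "preprocess_config"))
  st <- config$stages
  rows <- list()
  out_cases <- lapply(x$cases, function(cs) {
    kept_imgs <- list()
    for (im in cs$images) {
      applied <- character(0)
      plugin_error <- NA_character_
      score <- NA_real_
      crop_box <- NA_character_
      keep <- TRUE
      if (st[["quality"]]) {
        score <- laplacian_quality_score(im)
        keep <- score >= config$quality_threshold
        applied <- c(applied, "quality")
      }
      if (keep) {
        for (stage in c("text_removal", "object_removal")) {
          if (!st[[stage]]) next
          det <- detectors[[sub("_removal", "", stage)]]
          if (is.null(det)) next
          applied <- c(applied, stage)
          im <- tryCatch({
            msk <- det(im)
            if (any(msk$mask)) {
              remove_regions(im, msk, fill_strategy = config$fill_strategy)
            } else im
          }, error = function(e) {
            plugin_error <<- conditionMessage(e)
            im
          })
        }
        if (st[["crop_resize"]]) {
          applied <- c(applied, "crop_resize")
          res <- tryCatch({
            box <- detect_black_margin(im, config$margin_intensity_cutoff)
            crop_box <- paste(box, collapse = ",")
            list(im = crop_resize(im, box, config$output_size),
                 box = crop_box)
          }, error = function(e) NULL)
          if (is.null(res)) {
            keep <- FALSE                   # all-black frame: uninformative
          } else {
            im <- res$im
            crop_box <- res$box
          }
        }
      }
      if (keep) kept_imgs[[length(kept_imgs) + 1L]] <- im
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = cs$patient_id, image_id = im$image_id,
        score = score, kept = keep, crop_box = crop_box,
        stages_applied = paste(applied, collapse = "+"),
        plugin_error = plugin_error, stringsAsFactors = FALSE)
    }
    patient_case(cs$patient_id, cs$label, kept_imgs)
  })
  list(cohort = cohort(out_cases), report = do.call(rbind, rows))
}
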
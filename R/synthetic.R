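#' Configuration of the synthetic endoscopy-like cohort generator
#'
#' The generator emulates the structure of a multi-hospital endoscopy
#' cohort: each patient contributes a variable-length sequence of RGB
#' snapshots showing a bright circular field of view on a black frame
#' (the black margin), mucosa-like texture with sensor noise, and a
#' class-dependent signal — reddened lesion blobs whose expected count
#' scales with `signal_strength` in positive (IBD) patients. The artifact
#' taxonomy of real acquisitions is injected at configurable rates:
#' solid-colour frames, heavily blurred frames, and high-contrast text-like
#' overlays in the margin. Every artifact is recorded in the bookkeeping
#' table so downstream stages can be tested against ground truth.
#'
#' @param n_patients Number of patients.
#' @param images_per_patient `c(min, max)` snapshots per patient (uniform).
#' @param class_balance Proportion of positive patients.
#' @param signal_strength Non-negative class-separation knob: expected
#'   lesion blobs per positive image is `3 * signal_strength` (plus a 0.3
#'   background rate common to both classes); 0 gives a null cohort whose
#'   labels are independent of the pixels.
#' @param solid_frame_prob,blur_prob,text_overlay_prob Artifact rates.
#' @param image_size `c(H, W)` of generated frames (>= 32).
#' @param seed Integer seed; generation is fully deterministic.
#' @return Object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 30L,
                                    images_per_patient = c(6L, 12L),
                                    class_balance = 0.5,
                                    signal_strength = 1,
                                    solid_frame_prob = 0.05,
                                    blur_prob = 0.05,
                                    text_overlay_prob = 0.10,
                                    image_size = c(64L, 64L),
                                    seed = 1L) {
  stopifnot(n_patients >= 1, images_per_patient[1] <= images_per_patient[2],
            class_balance >= 0, class_balance <= 1, signal_strength >= 0,
            solid_frame_prob >= 0, solid_frame_prob <= 1,
            blur_prob >= 0, blur_prob <= 1,
            text_overlay_prob >= 0, text_overlay_prob <= 1)
  if (any(image_size < 32L))
    stop("image_size too small for the margin geometry (need >= 32)")
  structure(
    list(n_patients = as.integer(n_patients),
         images_per_patient = as.integer(images_per_patient),
         class_balance = class_balance, signal_strength = signal_strength,
         solid_frame_prob = solid_frame_prob, blur_prob = blur_prob,
         text_overlay_prob = text_overlay_prob,
         image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "synthetic_cohort_config")
}

# one mucosa frame: black margin, bright circular field of view, noise,
# and n_blobs reddened lesion blobs
render_frame <- function(h, w, n_blobs) {
  cy <- h / 2 + stats::runif(1, -h * 0.03, h * 0.03)
  cx <- w / 2 + stats::runif(1, -w * 0.03, w * 0.03)
  r <- 0.40 * min(h, w) * stats::runif(1, 0.9, 1.05)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  fov <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  base <- c(185, 125, 110)                  # mucosa tone
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[fov] <- base[ch] + stats::rnorm(sum(fov), sd = 8)
    px[, , ch] <- plane
  }
  if (n_blobs > 0) {
    for (b in seq_len(n_blobs)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.6 * r)
      by <- cy + rad * sin(ang); bx <- cx + rad * cos(ang)
      br <- stats::runif(1, 0.08, 0.16) * min(h, w)
      blob <- exp(-((yy - by)^2 + (xx - bx)^2) / (2 * br^2))
      blob[!fov] <- 0
      px[, , 1] <- px[, , 1] + 60 * blob    # redden
      px[, , 2] <- px[, , 2] - 45 * blob
      px[, , 3] <- px[, , 3] - 35 * blob
    }
  }
  pmin(pmax(round(px), 0), 255)
}

# glyph-like high-contrast strokes in the top-left margin corner
render_text_overlay <- function(px) {
  h <- dim(px)[1]; w <- dim(px)[2]
  n_glyph <- sample(3:6, 1)
  x0 <- 3L
  for (g in seq_len(n_glyph)) {
    gw <- sample(3:5, 1); gh <- sample(6:9, 1)
    if (x0 + gw > w %/% 2) break
    rows <- 3:(3 + gh)
    # vertical stroke + random horizontal bars, like blocky characters
    px[rows, x0:(x0 + 1L), ] <- 235
    for (bar in sample(rows, 2))
      px[bar:(bar + 1L), x0:(x0 + gw), ] <- 235
    x0 <- x0 + gw + 2L
  }
  px
}

#' Generate a synthetic endoscopy-like cohort
#'
#' @param config A [synthetic_cohort_config()].
#' @return List with `cohort` (a labeled [cohort()]) and `bookkeeping`, a
#'   data frame with one row per image: `patient_id`, `image_id`, `label`,
#'   `n_blobs`, `solid_frame`, `blurred`, `text_overlay`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  h <- config$image_size[1]; w <- config$image_size[2]
  withr::with_seed(config$seed, {
    labels <- ifelse(
      stats::runif(config$n_patients) < config$class_balance,
      "positive", "negative")
    rows <- list()
    cases <- lapply(seq_len(config$n_patients), function(i) {
      pid <- sprintf("P%03d", i)
      rng <- config$images_per_patient
      n_img <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1)
      imgs <- lapply(seq_len(n_img), function(j) {
        iid <- sprintf("%s_img%02d", pid, j)
        lambda <- 0.3 +
          if (labels[i] == "positive") 3 * config$signal_strength else 0
        n_blobs <- stats::rpois(1, lambda)
        solid <- stats::runif(1) < config$solid_frame_prob
        blurred <- !solid && stats::runif(1) < config$blur_prob
        text <- stats::runif(1) < config$text_overlay_prob
        if (solid) {
          px <- array(rep(round(stats::runif(3, 40, 210)),
                          each = h * w), c(h, w, 3))
        } else {
          px <- render_frame(h, w, n_blobs)
          if (blurred) px <- blur_rgb(px, sigma = max(3, min(h, w) / 12))
          if (text) px <- render_text_overlay(px)
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          patient_id = pid, image_id = iid, label = labels[i],
          n_blobs = n_blobs, solid_frame = solid, blurred = blurred,
          text_overlay = text, stringsAsFactors = FALSE)
        image_record(pid, iid, px)
      })
      patient_case(pid, labels[i], imgs)
    })
    list(cohort = cohort(cases), bookkeeping = do.call(rbind, rows))
  })
}

#' Configuration of the synthetic per-image prediction generator
#'
#' Drives the per-patient aggregation machinery without a trained model:
#' each image's prediction is correct with probability
#' `per_image_accuracy`, and its confidence is drawn from a Beta
#' distribution mapped into `[0.5, 1]`, with separate shapes for correct
#' and incorrect predictions. The defaults make correct predictions more
#' confident than incorrect ones — the premise that low-confidence
#' predictions are the misleading ones, which the threshold `t` exploits.
#'
#' @param n_patients Number of patients.
#' @param images_per_patient `c(min, max)` predictions per patient.
#' @param class_balance Proportion positive.
#' @param per_image_accuracy Probability a per-image prediction matches the
#'   patient label, in (0, 1].
#' @param conf_correct,conf_incorrect `c(shape1, shape2)` of the Beta
#'   confidence draw for correct / incorrect predictions.
#' @param seed Integer seed.
#' @return Object of class `synthetic_prediction_config`.
#' @export
synthetic_prediction_config <- function(n_patients = 40L,
                                        images_per_patient = c(9L, 15L),
                                        class_balance = 0.5,
                                        per_image_accuracy = 0.9,
                                        conf_correct = c(8, 2),
                                        conf_incorrect = c(2, 4),
                                        seed = 1L) {
  stopifnot(per_image_accuracy > 0, per_image_accuracy <= 1,
            images_per_patient[1] <= images_per_patient[2])
  structure(
    list(n_patients = as.integer(n_patients),
         images_per_patient = as.integer(images_per_patient),
         class_balance = class_balance,
         per_image_accuracy = per_image_accuracy,
         conf_correct = conf_correct, conf_incorrect = conf_incorrect,
         seed = as.integer(seed)),
    class = "synthetic_prediction_config")
}

#' Generate synthetic per-image predictions
#'
#' @param config A [synthetic_prediction_config()].
#' @return List with `predictions` (data frame in [predict_images()] layout)
#'   and `truth` (named label vector).
#' @export
generate_predictions <- function(config = synthetic_prediction_config()) {
  withr::with_seed(config$seed, {
    labels <- ifelse(stats::runif(config$n_patients) < config$class_balance,
                     "positive", "negative")
    names(labels) <- sprintf("P%03d", seq_len(config$n_patients))
    rows <- lapply(seq_len(config$n_patients), function(i) {
      pid <- names(labels)[i]
      rng <- config$images_per_patient
      n_img <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1)
      correct <- stats::runif(n_img) < config$per_image_accuracy
      shp <- ifelse(correct, 1, 2)
      conf <- numeric(n_img)
      conf[correct] <- 0.5 + 0.5 * stats::rbeta(sum(correct),
                                                config$conf_correct[1],
                                                config$conf_correct[2])
      conf[!correct] <- 0.5 + 0.5 * stats::rbeta(sum(!correct),
                                                 config$conf_incorrect[1],
                                                 config$conf_incorrect[2])
      pred_lab <- ifelse(correct, labels[i],
                         ifelse(labels[i] == "positive", "negative",
                                "positive"))
      p_pos <- ifelse(pred_lab == "positive", conf, 1 - conf)
      data.frame(patient_id = pid,
                 image_id = sprintf("%s_img%02d", pid, seq_len(n_img)),
                 p_pos = p_pos,
                 predicted_label = pred_lab,
                 confidence = conf, stringsAsFactors = FALSE)
    })
    list(predictions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = labels)
  })
}
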
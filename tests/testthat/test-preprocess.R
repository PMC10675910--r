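test_that("quality score is zero for constant images and matches the
           brute-force convolution oracle", {
  expect_equal(laplacian_quality_score(const_image(128)), 0)
  chk <- checkerboard_image(8, 8)
  expect_equal(laplacian_quality_score(chk),
               oracle_laplacian_var(luminance(chk)))
  nz <- noise_image(12, 12, seed = 4)
  expect_equal(laplacian_quality_score(nz),
               oracle_laplacian_var(luminance(nz)))
  expect_warning(s <- laplacian_quality_score(const_image(5, h = 1, w = 1)),
                 "too small")
  expect_equal(s, 0)
})

test_that("quality score is translation-invariant and scales
           quadratically", {
  px <- withr::with_seed(7, array(round(runif(300, 0, 200)), c(10, 10, 3)))
  nz <- image_record("P1", "nz", px)
  base <- laplacian_quality_score(nz)
  shifted <- image_record("P1", "s", px + 30)    # no clipping possible
  expect_lt(abs(laplacian_quality_score(shifted) - base), 1e-9)
  half <- image_record("P1", "h", px / 2)
  expect_equal(laplacian_quality_score(half), base / 4)
})

test_that("quality filtering partitions order-preservingly at any
           threshold", {
  sharp <- lapply(1:3, function(i)
    noise_image(10, 10, iid = paste0("s", i), seed = i))
  # linear gradients: smooth fields whose Laplacian response is ~zero
  blurred <- lapply(1:2, function(i) {
    grad <- outer(seq(0, 18, by = 2), rep(1, 10))
    image_record("P1", paste0("b", i), array(100 + grad, c(10, 10, 3)))
  })
  solid <- list(const_image(77, h = 10, w = 10, iid = "solid"))
  imgs <- c(sharp[1:2], blurred, sharp[3], solid)
  scores <- vapply(imgs, laplacian_quality_score, numeric(1))
  thr <- (min(scores[c(1, 2, 5)]) + max(scores[c(3, 4, 6)])) / 2
  res <- filter_low_quality(imgs, thr)
  expect_length(res$kept, 3L)
  expect_equal(vapply(res$kept, function(x) x$image_id, character(1)),
               c("s1", "s2", "s3"))           # order preserved
  expect_length(res$discarded, 3L)
  expect_equal(nrow(res$reports), 6L)
  expect_equal(res$reports$kept, scores >= thr)
  # threshold extremes
  expect_length(filter_low_quality(imgs, 0)$kept, 6L)
  expect_length(filter_low_quality(imgs, Inf)$kept, 0L)
  expect_equal(nrow(filter_low_quality(list(), 1)$reports), 0L)
})

test_that("black-margin detection finds the exact content box", {
  im <- framed_image(100, 100, rr = 11:90, cc = 21:80)
  expect_equal(unname(detect_black_margin(im, 10)), c(10, 20, 90, 80))
  bright <- const_image(200, h = 10, w = 12)
  expect_equal(unname(detect_black_margin(bright, 10)), c(0, 0, 10, 12))
  expect_error(detect_black_margin(const_image(0, h = 5, w = 5), 10),
               "all-black")
  # exhaustive scan agrees on a random sparse image
  px <- array(0, c(20, 20, 3))
  withr::with_seed(3, {
    on <- cbind(sample(4:17, 5), sample(3:18, 5))
    for (r in seq_len(nrow(on))) px[on[r, 1], on[r, 2], ] <- 255
  })
  im2 <- image_record("P1", "sparse", px)
  box <- detect_black_margin(im2, 10)
  lum <- luminance(im2)
  hits <- which(lum > 10, arr.ind = TRUE)
  expect_equal(unname(box),
               c(min(hits[, 1]) - 1L, min(hits[, 2]) - 1L,
                 max(hits[, 1]), max(hits[, 2])))
})

test_that("margin detection is idempotent after cropping", {
  im <- framed_image(60, 60, rr = 8:50, cc = 12:49)
  box <- detect_black_margin(im, 10)
  cropped <- crop_resize(im, box, c(box[3] - box[1], box[4] - box[2]))
  expect_equal(unname(detect_black_margin(cropped, 10)),
               c(0, 0, dim(cropped$pixels)[1], dim(cropped$pixels)[2]))
})

test_that("crop_resize honours its shape and identity contracts", {
  nz <- noise_image(16, 16, seed = 9)
  full <- crop_resize(nz, c(0, 0, 16, 16), c(16, 16))
  expect_identical(full$pixels, nz$pixels)    # identity passthrough
  im <- framed_image(100, 100, 11:90, 21:80)
  out <- crop_resize(im, c(10, 20, 90, 80), c(64, 64))
  expect_equal(dim(out$pixels), c(64L, 64L, 3L))
  cc <- crop_resize(const_image(137, h = 20, w = 30), c(2, 3, 18, 27),
                    c(8, 8))
  expect_true(all(cc$pixels == 137))          # constant stays constant
  expect_error(crop_resize(nz, c(5, 5, 5, 9), c(4, 4)), "empty")
  expect_error(crop_resize(nz, c(0, 0, 99, 4), c(4, 4)), "bounds")
})

test_that("region removal fills only masked pixels per strategy", {
  nz <- noise_image(20, 20, seed = 5)
  empty <- region_mask("nz", shape = c(20, 20))
  expect_identical(remove_regions(nz, empty)$pixels, nz$pixels)
  cim <- const_image(90, h = 10, w = 10)
  anym <- region_mask("img1", boxes = list(c(2, 2, 6, 6)),
                      shape = c(10, 10))
  expect_identical(remove_regions(cim, anym)$pixels, cim$pixels)
  # 4x4 block mean fill equals the recomputed unmasked mean
  msk <- region_mask("nz", boxes = list(c(8, 8, 12, 12)), shape = c(20, 20))
  filled <- remove_regions(nz, msk, "mean_fill")
  for (ch in 1:3) {
    plane <- nz$pixels[, , ch]
    expect_true(all(filled$pixels[9:12, 9:12, ch] ==
                      round(mean(plane[!msk$mask]))))
    expect_identical(filled$pixels[, , ch][!msk$mask], plane[!msk$mask])
  }
  # diffusion fill stays within the data range and touches only the mask
  dif <- remove_regions(nz, msk, "diffusion")
  expect_identical(dif$pixels[, , 1][!msk$mask], nz$pixels[, , 1][!msk$mask])
  expect_true(all(dif$pixels >= 0 & dif$pixels <= 255))
  expect_error(remove_regions(nz, matrix(TRUE, 20, 20)), "entire image")
})

test_that("the pipeline keeps patient structure and discards only junk", {
  g <- generate_cohort(synthetic_cohort_config(
    n_patients = 6L, images_per_patient = c(4L, 6L),
    solid_frame_prob = 0.4, blur_prob = 0, text_overlay_prob = 0,
    seed = 21))
  res <- run_preprocess(g$cohort,
                        preprocess_config(output_size = c(32L, 32L)))
  expect_length(res$cohort, length(g$cohort))   # never loses patients
  # every solid frame is gone, every clean frame survives
  book <- g$bookkeeping
  rep <- res$report
  merged <- merge(book, rep, by = c("patient_id", "image_id"))
  expect_true(all(!merged$kept[merged$solid_frame]))
  expect_true(all(merged$kept[!merged$solid_frame]))
  # survivors are resized and carry no black border at the cutoff
  for (cs in res$cohort$cases) for (im in cs$images) {
    expect_equal(dim(im$pixels), c(32L, 32L, 3L))
    lum <- luminance(im)
    expect_gt(max(lum[1, ]), 10); expect_gt(max(lum[32, ]), 10)
    expect_gt(max(lum[, 1]), 10); expect_gt(max(lum[, 32]), 10)
  }
})

test_that("disabling all stages is the identity on the cohort", {
  ch <- tiny_cohort(3, n_images = 2)
  res <- run_preprocess(ch, preprocess_config(
    stages = c(quality = FALSE, text_removal = FALSE,
               object_removal = FALSE, crop_resize = FALSE)))
  expect_equal(res$cohort$cases, ch$cases)
})

test_that("detector plugins drive region removal; failures pass through", {
  im <- framed_image(40, 40, 5:36, 5:36, value = 150, iid = "t1")
  ch <- cohort(list(patient_case("P1", "positive", list(im))))
  det <- sidecar_box_detector(list(t1 = list(c(10, 10, 14, 14))))
  cfg <- preprocess_config(stages = c(quality = FALSE, text_removal = TRUE,
                                      crop_resize = FALSE))
  out <- run_preprocess(ch, cfg, detectors = list(text = det))
  got <- out$cohort$cases$P1$images[[1]]$pixels
  expect_false(all(got[11:14, 11:14, 1] == 150))  # region was filled
  expect_true(all(got[20:30, 20:30, 1] == 150))   # rest untouched
  boom <- function(image) stop("detector exploded")
  out2 <- run_preprocess(ch, cfg, detectors = list(text = boom))
  expect_identical(out2$cohort$cases$P1$images[[1]]$pixels, im$pixels)
  expect_match(out2$report$plugin_error, "exploded")
})
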
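# Programmatic fixtures shared across test files.

const_image <- function(value, h = 8, w = 8, pid = "P1", iid = "img1") {
  image_record(pid, iid, array(value, c(h, w, 3)))
}

checkerboard_image <- function(h = 8, w = 8, pid = "P1", iid = "chk") {
  plane <- outer(seq_len(h), seq_len(w),
                 function(i, j) ifelse((i + j) %% 2 == 0, 255, 0))
  image_record(pid, iid, array(rep(plane, 3), c(h, w, 3)))
}

noise_image <- function(h = 16, w = 16, pid = "P1", iid = "nz", seed = 1) {
  withr::with_seed(seed, {
    px <- array(round(runif(h * w * 3, 0, 255)), c(h, w, 3))
    image_record(pid, iid, px)
  })
}

# image with bright content in rows rr, cols cc (1-based), black elsewhere
framed_image <- function(h, w, rr, cc, value = 200, pid = "P1",
                         iid = "framed") {
  px <- array(0, c(h, w, 3))
  px[rr, cc, ] <- value
  image_record(pid, iid, px)
}

prediction_frame <- function(pid, p_pos, confidence) {
  data.frame(patient_id = rep(pid, length(p_pos)),
             image_id = sprintf("%s_i%02d", rep(pid, length(p_pos)),
                                seq_along(p_pos)),
             p_pos = p_pos,
             predicted_label = ifelse(p_pos >= 0.5, "positive", "negative"),
             confidence = confidence, stringsAsFactors = FALSE)
}

# small labeled cohort of trivial images for split/fold tests
tiny_cohort <- function(n_patients = 10, n_images = 3, seed = 1) {
  withr::with_seed(seed, {
    cases <- lapply(seq_len(n_patients), function(i) {
      pid <- sprintf("P%02d", i)
      imgs <- lapply(seq_len(n_images), function(j)
        image_record(pid, sprintf("%s_i%d", pid, j),
                     array(round(runif(48, 0, 255)), c(4, 4, 3))))
      patient_case(pid, if (i %% 2 == 0) "positive" else "negative", imgs)
    })
    cohort(cases)
  })
}

# a small, well-separated preprocessed cohort for training tests;
# cached per session because several tests share it
separable_cohort <- function(n_patients = 20, seed = 3) {
  key <- sprintf("sep_%d_%d", n_patients, seed)
  if (is.null(.fixture_cache[[key]])) {
    g <- generate_cohort(synthetic_cohort_config(
      n_patients = n_patients, images_per_patient = c(4L, 8L),
      signal_strength = 1.5, solid_frame_prob = 0, blur_prob = 0,
      text_overlay_prob = 0, seed = seed))
    pp <- run_preprocess(g$cohort,
                         preprocess_config(output_size = c(32L, 32L)))
    .fixture_cache[[key]] <- pp$cohort
  }
  .fixture_cache[[key]]
}

.fixture_cache <- new.env(parent = emptyenv())

# a trained tiny model on the separable cohort, cached
trained_model <- function() {
  if (is.null(.fixture_cache$model)) {
    ch <- separable_cohort()
    .fixture_cache$model <- train_fold(
      ch$cases[1:14], NULL, backbone_spec(),
      train_config(epochs = 20L, seed = 2L))
  }
  .fixture_cache$model
}
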
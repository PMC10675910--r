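# Scaled-down end-to-end study configuration shared by the pipeline and
# acceptance tests: 30 synthetic patients, tiny_cnn backbone, 2 folds, a
# reduced (t, k) grid, PTQ. Cached because several tests inspect the same
# run.

e2e_config <- function(seed = 1L) {
  pipeline_config(
    data = list(synthetic = TRUE,
                synthetic_config = synthetic_cohort_config(
                  n_patients = 30L, images_per_patient = c(5L, 9L),
                  signal_strength = 1.5, solid_frame_prob = 0.05,
                  blur_prob = 0.05, text_overlay_prob = 0.1,
                  seed = seed)),
    preprocess = preprocess_config(output_size = c(32L, 32L)),
    backbone = backbone_spec(input_size = c(32L, 32L)),
    train = train_config(epochs = 30L, lr_decay_every = 15L,
                         batch_size = 8L, seed = seed),
    n_folds = 2L,
    t_grid = c(0.85, 0.90, 0.93, 0.97),
    k_grid = c(1L, 3L, 6L, 10L),
    quantization = list(method = "ptq", calib_fraction = 0.15),
    bootstrap_B = 2000,
    seed = seed)
}

e2e_run <- function() {
  if (is.null(.fixture_cache$e2e)) {
    dir <- file.path(tempdir(), "endoquant_e2e")
    res <- suppressMessages(run_pipeline(e2e_config(), dir))
    .fixture_cache$e2e <- list(result = res, dir = dir)
  }
  .fixture_cache$e2e
}
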
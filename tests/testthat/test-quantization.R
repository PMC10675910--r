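test_that("affine calibration reproduces the printed parameter formulas", {
  p <- calibrate_affine(0, 255, uint8_range())
  expect_equal(p$s, 1); expect_equal(p$Z, 0)
  p2 <- calibrate_affine(-1, 1, uint8_range())
  expect_equal(p2$s, 2 / 255)
  expect_equal(p2$Z, 128)                 # round(127.5) half away from zero
  expect_error(calibrate_affine(3, 3, uint8_range()), "degenerate")
  expect_warning(
    pd <- calibrate_affine(3, 3, uint8_range(), degenerate = "unit_scale"),
    "degenerate")
  expect_equal(pd$s, 1); expect_equal(pd$Z, 0)
})

test_that("symmetric calibration centers the clip and drops the zero
           point", {
  p <- calibrate_symmetric(-3, 2, int8_symmetric_range())
  expect_equal(p$alpha, -3); expect_equal(p$beta, 3)
  expect_equal(p$s, 6 / 254)
  expect_equal(p$Z, 0)
  # symmetric observed data: affine and symmetric scales agree
  pa <- calibrate_affine(-2.5, 2.5, int8_symmetric_range())
  ps <- calibrate_symmetric(-2.5, 2.5, int8_symmetric_range())
  expect_equal(pa$s, ps$s)
  expect_error(calibrate_symmetric(0, 0, int8_symmetric_range()),
               "degenerate")
})

test_that("quantizer matches the scalar brute-force reference, including
           per-channel", {
  expect_equal(quantize_tensor(0, calibrate_affine(0, 255)), 0)
  p <- calibrate_affine(-0.8, 1.9, uint8_range())
  expect_equal(quantize_tensor(-0.8, p), 0)      # alpha -> q_min edge
  expect_equal(quantize_tensor(1.9, p), 255)
  withr::with_seed(31, {
    x <- matrix(rnorm(12, sd = 2), 4, 3)
    pc <- calibrate_symmetric(apply(x, 2, min), apply(x, 2, max),
                              channel_axis = 2L)
    got <- quantize_tensor(x, pc)
    for (j in 1:3)
      expect_equal(got[, j],
                   oracle_quantize(x[, j], pc$s[j], pc$Z[j], -127, 127))
    # dequantize round trip within s/2 per channel
    back <- dequantize_tensor(got, pc)
    for (j in 1:3)
      expect_true(all(abs(back[, j] - x[, j]) <= pc$s[j] / 2 + 1e-12))
  })
})

test_that("round-trip error obeys the s/2 bound on a dense in-clip sweep
           and equals clip distance outside", {
  p <- calibrate_affine(-1.3, 2.2, uint8_range())
  xs <- seq(-1.3, 2.2, length.out = 5000)
  err <- abs(xs - dequantize_tensor(quantize_tensor(xs, p), p))
  expect_true(all(err <= p$s / 2 + 1e-12))
  expect_equal(dequantize_tensor(quantize_tensor(0, p), p) * 0, 0)
  # out-of-clip points snap to the nearest representable value
  grid_vals <- dequantize_tensor(0:255, p)
  for (x in c(-5, -1.8, 2.5, 9)) {
    rt <- dequantize_tensor(quantize_tensor(x, p), p)
    expect_equal(abs(x - rt), min(abs(x - grid_vals)))
  }
})

test_that("per-channel reconstruction never loses to per-tensor on
           tensors with heterogeneous channel ranges", {
  # the regime per-channel granularity exists for: channel dynamic ranges
  # differing by an order of magnitude, so the shared per-tensor scale is
  # far too coarse for the small channels
  withr::with_seed(17, {
    for (i in 1:100) {
      sc <- c(1, runif(4, 0.05, 0.5))
      x <- matrix(rnorm(200 * 5), 200, 5) * rep(sc, each = 200)
      pt <- calibrate_symmetric(min(x), max(x))
      pc <- calibrate_symmetric(apply(x, 2, min), apply(x, 2, max),
                                channel_axis = 2L)
      e_t <- max(abs(x - dequantize_tensor(quantize_tensor(x, pt), pt)))
      e_c <- max(abs(x - dequantize_tensor(quantize_tensor(x, pc), pc)))
      expect_lte(e_c, e_t + 1e-12)
      # and the per-channel scales are bounded by the tensor scale
      expect_true(all(pc$s <= pt$s + 1e-15))
    }
  })
})

test_that("observers accumulate commutative extrema, scalar and
           per-channel", {
  o <- minmax_observer()
  expect_warning(observer_update(o, numeric(0)), "empty")
  b1 <- c(-1, 0.5, 2); b2 <- c(-3, 1)
  o12 <- observer_update(observer_update(o, b1), b2)
  o21 <- observer_update(observer_update(o, b2), b1)
  expect_equal(o12$running_min, -3); expect_equal(o12$running_max, 2)
  expect_equal(o12$running_min, o21$running_min)
  expect_equal(o12$running_max, o21$running_max)
  expect_equal(o12$n_batches, 2L)
  oc <- minmax_observer("per_channel", channel_axis = 2L)
  x <- cbind(c(-1, 4), c(2, -7))
  oc <- observer_update(oc, x)
  expect_equal(unname(oc$running_min), c(-1, -7))
  expect_equal(unname(oc$running_max), c(4, 2))
})

test_that("STE mask is the clip indicator and matches finite differences
           of the clamp surrogate", {
  p <- calibrate_affine(-1, 1, uint8_range())
  xs <- c(-3, -1.0001, -0.73, -0.2, 0, 0.41, 0.9999, 1.0001, 2.5)
  fq <- fake_quant(xs, p)
  expect_equal(fq$mask, as.numeric(xs >= -1 & xs <= 1))
  # the straight-through surrogate is clamp(x, alpha, beta); its finite
  # difference (away from the kinks) equals the mask
  clamp <- function(x) pmin(pmax(x, -1), 1)
  h <- 1e-5
  fd <- (clamp(xs + h) - clamp(xs - h)) / (2 * h)
  expect_equal(round(fd), fq$mask)
  # boundary points are included in the pass-through region
  expect_equal(fake_quant(c(-1, 1), p)$mask, c(1, 1))
})

test_that("PACT recomputes the scale from the trainable clip and recovers
           a known activation range", {
  r <- uint8_range()
  pf <- pact_fake_quant(c(0.2, 1.7, 3.5), alpha_tilde = 2, range = r)
  expect_equal(pf$s, 2 / 255)
  expect_equal(pf$dx_mask, c(1, 1, 0))
  expect_equal(pf$dalpha_mask, c(0, 0, 1))
  expect_equal(pf$value[3], 2)              # clamped to the clip
  # single-layer recovery: minimize reconstruction MSE over alpha by the
  # PACT gradient rule; data has true max 3
  withr::with_seed(23, {
    x <- runif(400, 0, 3)
    alpha <- 0.5
    for (step in 1:400) {
      f <- pact_fake_quant(x, alpha, r)
      g_clip <- sum(2 * (f$value - x) * f$dalpha_mask) / length(x)
      alpha <- max(alpha - 0.05 * g_clip, 1e-3)
    }
    expect_gt(alpha, 1.5); expect_lt(alpha, 6)  # within a factor 2 of 3
  })
})

test_that("the default selection spares the stem and the classifier", {
  m <- trained_model()
  sel <- default_layer_selection(m)
  expect_setequal(sel, c("conv2", "conv3"))
  expect_false("fc" %in% sel)
  expect_false("conv1" %in% sel)
})

test_that("PTQ simulation preserves accuracy and respects the identity
           contract for an empty selection", {
  m <- trained_model()
  ch <- separable_cohort()
  test_cases <- ch$cases[15:20]
  calib <- ch$cases[1:2]
  fp <- do.call(rbind, lapply(test_cases, function(c)
    predict_images(m, c)))
  q0 <- ptq(m, calib, selection = character(0))
  p0 <- do.call(rbind, lapply(test_cases, function(c)
    predict_images(q0, c)))
  expect_identical(fp$p_pos, p0$p_pos)        # bit-identical outputs
  qm <- ptq(m, calib)
  pq <- do.call(rbind, lapply(test_cases, function(c)
    predict_images(qm, c)))
  expect_false(identical(fp$p_pos, pq$p_pos))
  agreement <- mean((fp$p_pos >= 0.5) == (pq$p_pos >= 0.5))
  expect_gte(agreement, 0.9)
  # stored integer weights round-trip within s/2 per channel
  for (nm in qm$quant$selection) {
    wq <- qm$quant$wq[[nm]]
    back <- dequantize_tensor(qm$quant$w_int[[nm]], wq)
    err <- abs(back - m$layers[[nm]]$W)
    for (j in seq_len(ncol(err)))
      expect_true(all(err[, j] <= wq$s[j] / 2 + 1e-12))
  }
  expect_error(ptq(m, list()), "empty calibration")
})

test_that("QAT reduces to PTQ at zero epochs and freezes quantization
           parameters during training", {
  m <- trained_model()
  ch <- separable_cohort()
  calib <- ch$cases[1:2]
  qp <- ptq(m, calib)
  qz <- qat_train(m, ch$cases[1:14], train_config(epochs = 0, seed = 2),
                  calib_cases = calib)
  expect_equal(qz$quant$wq, qp$quant$wq)
  expect_equal(qz$quant$aq, qp$quant$aq)
  expect_identical(qz$quant$w_int, qp$quant$w_int)
  qt <- qat_train(m, ch$cases[1:14], train_config(epochs = 2, seed = 2),
                  calib_cases = calib)
  expect_equal(qt$quant$aq, qp$quant$aq)      # frozen through training
  expect_equal(qt$quant$wq, qp$quant$wq)
  expect_false(identical(qt$layers$conv2$W, m$layers$conv2$W))
})

test_that("QAT holds its ground against PTQ across seeds", {
  successes <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    g <- generate_cohort(synthetic_cohort_config(
      n_patients = 12L, images_per_patient = c(3L, 5L),
      signal_strength = 1.5, solid_frame_prob = 0, blur_prob = 0,
      text_overlay_prob = 0, seed = 300 + s))
    pp <- run_preprocess(g$cohort,
                         preprocess_config(output_size = c(32L, 32L)))
    cs <- pp$cohort$cases
    m <- train_fold(cs[1:8], NULL, backbone_spec(),
                    train_config(epochs = 10, seed = s))
    calib <- cs[1:2]
    test_cases <- cs[9:12]
    truth <- cohort_labels(pp$cohort)[9:12]
    acc_of <- function(model) {
      pr <- do.call(rbind, lapply(test_cases, function(c)
        predict_images(model, c)))
      mean(pr$predicted_label == truth[pr$patient_id])
    }
    a_ptq <- acc_of(ptq(m, calib))
    a_qat <- acc_of(qat_train(m, cs[1:8],
                              train_config(epochs = 3, seed = s),
                              calib_cases = calib))
    if (a_qat >= a_ptq) successes <- successes + 1L
  }
  expect_gte(successes / n_rep, 0.8)
})

test_that("PACT training reduces to QAT when the clip cannot move and
           learns clips near the observed activation scale", {
  m <- trained_model()
  ch <- separable_cohort()
  calib <- ch$cases[1:2]
  pa <- pact_train(m, ch$cases[1:14], train_config(epochs = 2, seed = 4),
                   calib_cases = calib)
  expect_true(all(unlist(pa$quant$alpha_tilde) > 0))
  # learned clip stays within a factor ~2 of the calibrated range
  init <- calibrate_model_clips <- ptq(m, calib)$quant$aq
  for (nm in names(pa$quant$alpha_tilde)) {
    ratio <- pa$quant$alpha_tilde[[nm]] / init[[nm]]$beta
    expect_gt(ratio, 0.3); expect_lt(ratio, 3)
  }
  # the final activation scale honours s = alpha / (q_max - q_min)
  for (nm in names(pa$quant$alpha_tilde))
    expect_equal(pa$quant$aq[[nm]]$s,
                 pa$quant$alpha_tilde[[nm]] / 255)
})

test_that("size accounting is exact, including the one-fourth ratio", {
  m <- trained_model()
  n_par <- sum(vapply(m$layers, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  expect_equal(model_size_bytes(m, selection = character(0)), n_par * 4)
  expect_equal(
    model_size_bytes(m, selection = names(m$layers),
                     include_overhead = FALSE),
    n_par)                                   # exactly 1/4 of fp32
  # default selection, hand-computed byte count
  sel <- default_layer_selection(m)
  by_layer <- vapply(m$layers, function(l) length(l$W) + length(l$b),
                     numeric(1))
  want <- sum(by_layer[sel]) + sum(by_layer[setdiff(names(by_layer),
                                                    sel)]) * 4
  over <- sum(vapply(sel, function(nm)
    2 * ncol(m$layers[[nm]]$W) * 4 + 8, numeric(1)))
  expect_equal(model_size_bytes(m, sel), want + over)
  expect_equal(model_size_bytes(m, sel, include_overhead = FALSE), want)
})
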
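test_that("aggregation follows the threshold/abstention/top-k rules", {
  # all below threshold -> abstain
  p <- prediction_frame("P1", p_pos = c(0.6, 0.7), confidence = c(0.6, 0.7))
  d <- aggregate_patient(p, aggregation_params(0.93, 6))
  expect_equal(d$outcome, "unpredicted")
  expect_true(is.na(d$score))
  expect_equal(nrow(d$evidence), 0L)
  # single survivor
  p2 <- prediction_frame("P1", 0.99, 0.99)
  d2 <- aggregate_patient(p2, aggregation_params(0.93, 6))
  expect_equal(d2$outcome, "positive")
  expect_equal(d2$score, 0.99)
  expect_equal(nrow(d2$evidence), 1L)
  # dissenter below the top-6 cut is excluded
  conf <- c(0.99, 0.98, 0.97, 0.96, 0.95, 0.94, 0.90)
  pp <- c(rep(0.97, 6), 0.10)
  p3 <- prediction_frame("P1", pp, conf)
  d3 <- aggregate_patient(p3, aggregation_params(0.93, 6))
  expect_equal(nrow(d3$evidence), 6L)
  expect_false("P1_i07" %in% d3$evidence$image_id)
  orc <- oracle_aggregate(pp, conf, 0.93, 6)
  expect_equal(d3$score, orc$score)
  # boundary: confidence == t is kept
  p4 <- prediction_frame("P1", 0.93, 0.93)
  expect_equal(aggregate_patient(p4, aggregation_params(0.93, 1))$outcome,
               "positive")
  # empty prediction set abstains
  d5 <- aggregate_patient(prediction_frame("P1", numeric(0), numeric(0)))
  expect_equal(d5$outcome, "unpredicted")
})

test_that("aggregation equals the brute-force reference on random sets", {
  withr::with_seed(42, {
    for (rep in 1:1000) {
      n <- sample(1:12, 1)
      conf <- round(runif(n, 0.5, 1), 3)   # rounded: forces ties
      lab_pos <- runif(n) < 0.5
      p_pos <- ifelse(lab_pos, conf, 1 - conf)
      t <- sample(c(0.5, 0.7, 0.85, 0.93, 0.99), 1)
      k <- sample(1:10, 1)
      got <- aggregate_patient(prediction_frame("P1", p_pos, conf),
                               aggregation_params(t, k))
      want <- oracle_aggregate(p_pos, conf, t, k)
      expect_identical(got$outcome, want$outcome)
      if (!is.na(want$score))
        expect_lt(abs(got$score - want$score), 1e-12)
      expect_equal(got$evidence$confidence, conf[want$taken])
    }
  })
})

test_that("label-vote averaging mode matches its own oracle", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      n <- sample(2:10, 1)
      conf <- round(runif(n, 0.5, 1), 2)
      p_pos <- ifelse(runif(n) < 0.5, conf, 1 - conf)
      got <- aggregate_patient(prediction_frame("P1", p_pos, conf),
                               aggregation_params(0.6, 4),
                               average = "label")
      want <- oracle_aggregate(p_pos, conf, 0.6, 4, average = "label")
      expect_identical(got$outcome, want$outcome)
    }
  })
})

test_that("unanimous survivors decide the patient regardless of k", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      n <- sample(1:10, 1)
      conf <- runif(n, 0.93, 1)
      lab <- sample(c("positive", "negative"), 1)
      p_pos <- if (lab == "positive") conf else 1 - conf
      for (k in c(1, 3, 10))
        expect_equal(
          aggregate_patient(prediction_frame("P1", p_pos, conf),
                            aggregation_params(0.9, k))$outcome, lab)
    }
  })
})

test_that("results saturate once k exceeds the survivor count", {
  p <- prediction_frame("P1", c(0.9, 0.8, 0.95, 0.3),
                        c(0.9, 0.8, 0.95, 0.7))
  base <- aggregate_patient(p, aggregation_params(0.75, 3))  # 3 survivors
  for (k in 3:10)
    expect_equal(aggregate_patient(p, aggregation_params(0.75, k))$score,
                 base$score)
})

test_that("abstention counting is exact and monotone in t", {
  gp <- generate_predictions(synthetic_prediction_config(
    n_patients = 30, seed = 13))
  preds <- gp$predictions
  expect_equal(count_unpredicted(preds, 0.5), 0L)
  expect_equal(count_unpredicted(preds, max(preds$confidence) + 1e-9),
               30L)
  counts <- vapply(default_t_grid(), count_unpredicted, numeric(1),
                   preds = preds)
  expect_true(all(diff(counts) >= 0))
})

test_that("the grid machinery matches cell-by-cell recomputation on a
           constructed six-patient cohort", {
  preds <- rbind(
    prediction_frame("A", c(0.98, 0.97, 0.96), c(0.98, 0.97, 0.96)),
    prediction_frame("B", c(0.96, 0.94, 0.10), c(0.96, 0.94, 0.90)),
    prediction_frame("C", c(0.05, 0.08, 0.60), c(0.95, 0.92, 0.60)),
    prediction_frame("D", c(0.12, 0.90, 0.88), c(0.88, 0.90, 0.88)),
    prediction_frame("E", c(0.55, 0.40, 0.94), c(0.55, 0.60, 0.94)),
    prediction_frame("F", c(0.86, 0.13, 0.08), c(0.86, 0.87, 0.92)))
  truth <- c(A = "positive", B = "positive", C = "negative",
             D = "positive", E = "positive", F = "negative")
  got <- evaluate_grid(preds, truth)
  want <- oracle_grid(preds, truth, default_t_grid(), default_k_grid())
  expect_equal(unname(got$mcc), want$mcc)
  expect_equal(unname(got$accuracy), want$accuracy)
  expect_equal(unname(got$f1), want$f1)
  expect_equal(unname(got$unpredicted), want$unpredicted)
  expect_equal(got$selected, want$selected)
  expect_equal(dim(got$mcc), c(10L, 10L))
})

test_that("a perfectly confident cohort maximizes every cell and the
           tie-break picks the largest threshold and k", {
  preds <- rbind(prediction_frame("A", 1, 1), prediction_frame("B", 0, 1),
                 prediction_frame("C", 1, 1), prediction_frame("D", 0, 1))
  truth <- c(A = "positive", B = "negative", C = "positive",
             D = "negative")
  got <- evaluate_grid(preds, truth)
  expect_true(all(got$mcc == 1))
  expect_equal(unname(got$selected), c(0.99, 10))
  expect_error(evaluate_grid(preds, truth, t_grid = numeric(0)), "empty")
})

test_that("zero-abstention thresholds are preferred among MCC ties", {
  # both patients classified correctly at every t, but B abstains at
  # t > 0.9; MCC then ties across t only below the abstention point
  preds <- rbind(
    prediction_frame("A", c(0.99, 0.98), c(0.99, 0.98)),
    prediction_frame("B", c(0.12, 0.10), c(0.88, 0.90)),
    prediction_frame("C", c(0.97, 0.95), c(0.97, 0.95)),
    prediction_frame("D", c(0.08, 0.15), c(0.92, 0.85)))
  truth <- c(A = "positive", B = "negative", C = "positive",
             D = "negative")
  got <- evaluate_grid(preds, truth)
  orc <- oracle_grid(preds, truth, default_t_grid(), default_k_grid())
  expect_equal(got$selected, orc$selected)
  # the selected threshold leaves no patient unpredicted
  sel_idx <- which(got$t_grid == got$selected[["t"]])
  expect_equal(unname(got$unpredicted[sel_idx]), 0L)
  # yet higher thresholds with abstentions exist in the grid
  expect_gt(max(got$unpredicted), 0L)
})

test_that("explanations expose exactly the evidence used and round-trip
           through JSON", {
  conf <- seq(0.99, 0.80, length.out = 20)
  p <- prediction_frame("P1", conf, conf)
  d <- aggregate_patient(p, aggregation_params(0.5, 6))
  ex <- explain_decision(d)
  expect_equal(nrow(ex$images), 6L)
  expect_equal(ex$images$image_id, d$evidence$image_id)
  expect_equal(order(ex$images$confidence, decreasing = TRUE), 1:6)
  path <- withr::local_tempfile(fileext = ".json")
  write_explanation(ex, path)
  re <- read_explanation(path)
  expect_equal(re$outcome, ex$outcome)
  expect_equal(re$score, ex$score)
  expect_equal(re$images$image_id, ex$images$image_id)
  expect_equal(re$images$confidence, ex$images$confidence)
  # abstention report lists zero images
  un <- aggregate_patient(p, aggregation_params(0.995, 6))
  exu <- explain_decision(un)
  expect_equal(exu$outcome, "unpredicted")
  expect_equal(nrow(exu$images), 0L)
  write_explanation(exu, path)
  expect_equal(read_explanation(path)$outcome, "unpredicted")
})

test_that("per-patient ensembling beats per-image decisions on reliable
           cohorts", {
  wins <- 0L
  for (s in 1:60) {
    gp <- generate_predictions(synthetic_prediction_config(
      n_patients = 40, images_per_patient = c(9L, 15L),
      per_image_accuracy = 0.9, seed = 100 + s))
    dec <- aggregate_cohort(gp$predictions, aggregation_params(0.93, 6))
    pat_mcc <- mcc(confusion(dec, gp$truth))
    img_truth <- gp$truth[gp$predictions$patient_id]
    names(img_truth) <- seq_along(img_truth)
    img_out <- gp$predictions$predicted_label
    names(img_out) <- seq_along(img_out)
    img_mcc <- mcc(confusion(img_out, img_truth))
    if (pat_mcc > img_mcc) wins <- wins + 1L
  }
  expect_gte(wins / 60, 0.95)
})
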
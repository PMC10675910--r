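#' Aggregation parameters of the per-patient model
#'
#' @param t Confidence threshold in (0, 1]: per-image predictions with
#'   confidence strictly below `t` are discarded before aggregation.
#' @param k Number of most-confident surviving predictions averaged.
#' @return Object of class `aggregation_params`. The study's selected tuple
#'   is `(t, k) = (0.93, 6)`.
#' @export
aggregation_params <- function(t = 0.93, k = 6L) {
  stopifnot(t > 0, t <= 1, k >= 1)
  structure(list(t = t, k = as.integer(k)), class = "aggregation_params")
}

#' Default (t, k) grids of the per-patient grid search
#'
#' @return `default_t_grid()` returns
#'   `{0.85, 0.87, 0.88, 0.90, 0.91, 0.93, 0.94, 0.96, 0.97, 0.99}`;
#'   `default_k_grid()` returns `1:10`.
#' @export
default_t_grid <- function() {
  c(0.85, 0.87, 0.88, 0.90, 0.91, 0.93, 0.94, 0.96, 0.97, 0.99)
}

#' @rdname default_t_grid
#' @export
default_k_grid <- function() 1:10

#' Aggregate one patient's image predictions into a decision
#'
#' The per-patient model: (i) discard predictions with confidence below `t`;
#' (ii) if none survive, abstain (`"unpredicted"`); (iii) sort survivors by
#' confidence, descending, stably (ties keep input order); (iv) keep the
#' first `min(k, #survivors)`; (v) score them by the confidence-weighted
#' mean and call the patient positive when the score reaches 0.5.
#'
#' By default the averaged quantity is the positive-class probability
#' (`score = sum(c_i * p_i) / sum(c_i)`), which uses the full classifier
#' output; `average = "label"` instead averages the 0/1 predicted labels
#' with the same weights.
#'
#' @param preds Data frame of per-image predictions for one patient
#'   ([predict_images()] output: `image_id`, `p_pos`, `confidence`).
#' @param params An [aggregation_params()].
#' @param average `"probability"` (default) or `"label"`.
#' @return Object of class `patient_decision`: `patient_id`, `outcome`
#'   (`"positive"`, `"negative"` or `"unpredicted"`), `score` (`NA` when
#'   unpredicted) and `evidence`, the data frame of the <= k predictions
#'   actually used, in the order used.
#' @export
aggregate_patient <- function(preds, params = aggregation_params(),
                              average = c("probability", "label")) {
  average <- match.arg(average)
  pid <- if (nrow(preds)) preds$patient_id[1] else NA_character_
  if (nrow(preds) && length(unique(preds$patient_id)) > 1L)
    stop("predictions span multiple patients")
  keep <- preds[preds$confidence >= params$t, , drop = FALSE]
  if (!nrow(keep))
    return(structure(list(patient_id = pid, outcome = "unpredicted",
                          score = NA_real_,
                          evidence = keep[, intersect(
                            c("image_id", "p_pos", "confidence"),
                            names(keep)), drop = FALSE]),
                     class = "patient_decision"))
  keep <- keep[order(-keep$confidence), , drop = FALSE]   # stable in ties
  taken <- keep[seq_len(min(params$k, nrow(keep))), , drop = FALSE]
  val <- if (average == "probability") taken$p_pos else
    as.numeric(taken$p_pos >= 0.5)
  score <- sum(taken$confidence * val) / sum(taken$confidence)
  structure(
    list(patient_id = pid,
         outcome = if (score >= 0.5) "positive" else "negative",
         score = score,
         evidence = taken[, c("image_id", "p_pos", "confidence")]),
    class = "patient_decision")
}

#' @export
print.patient_decision <- function(x, ...) {
  cat(sprintf("<patient_decision %s: %s score=%s evidence=%d>\n",
              x$patient_id, x$outcome,
              if (is.na(x$score)) "-" else signif(x$score, 4),
              nrow(x$evidence)))
  invisible(x)
}

# split a prediction table into per-patient data frames, preserving order
split_predictions <- function(preds) {
  split(preds, factor(preds$patient_id, levels = unique(preds$patient_id)))
}

#' Aggregate every patient of a prediction table
#'
#' @param preds Data frame of predictions for several patients.
#' @inheritParams aggregate_patient
#' @return Named list of `patient_decision`s (by patient id).
#' @export
aggregate_cohort <- function(preds, params = aggregation_params(),
                             average = c("probability", "label")) {
  average <- match.arg(average)
  lapply(split_predictions(preds), aggregate_patient, params = params,
         average = average)
}

#' Count abstaining patients at a threshold
#'
#' Number of patients none of whose predictions reaches confidence `t` —
#' the patients the per-patient model cannot classify at that threshold.
#' Non-decreasing in `t`; zero at `t <= 0.5` for patients with any image.
#'
#' @param preds Prediction table (several patients).
#' @param t Confidence threshold.
#' @return Integer count.
#' @export
count_unpredicted <- function(preds, t) {
  by_pat <- tapply(preds$confidence, preds$patient_id, max)
  sum(by_pat < t)
}

#' Grid search over (t, k) for the per-patient model
#'
#' Evaluates every cell of the threshold/ensemble-size grid: all patients
#' are aggregated at each `(t, k)`, abstentions are counted as
#' misclassifications of the true class, and MCC, accuracy and F1 are
#' tabulated. The selected cell attains the maximum MCC; among maximizers,
#' cells whose threshold produces zero abstentions are preferred (the
#' highest threshold that still guarantees a prediction for every patient),
#' then the largest `t`, then the largest `k` (include as much information
#' as possible).
#'
#' @param preds Prediction table covering every labeled patient.
#' @param truth Named character vector patient_id -> `"positive"` /
#'   `"negative"`.
#' @param t_grid,k_grid Grids (defaults: the printed study grids).
#' @param average Passed to [aggregate_patient()].
#' @return Object of class `grid_search_result`: matrices `mcc`,
#'   `accuracy`, `f1` (rows = t, columns = k), `unpredicted` (one count per
#'   t), and `selected = c(t, k)`.
#' @export
evaluate_grid <- function(preds, truth, t_grid = default_t_grid(),
                          k_grid = default_k_grid(),
                          average = c("probability", "label")) {
  if (!length(t_grid) || !length(k_grid)) stop("empty grid")
  average <- match.arg(average)
  ids <- unique(preds$patient_id)
  missing <- setdiff(ids, names(truth))
  if (length(missing))
    stop("no ground truth for: ", paste(missing, collapse = ", "))
  dn <- list(t = format(t_grid, trim = TRUE), k = as.character(k_grid))
  shape <- matrix(NA_real_, length(t_grid), length(k_grid), dimnames = dn)
  tabs <- list(mcc = shape, accuracy = shape, f1 = shape)
  unpred <- stats::setNames(integer(length(t_grid)), dn$t)
  for (i in seq_along(t_grid)) {
    unpred[i] <- count_unpredicted(preds, t_grid[i])
    for (j in seq_along(k_grid)) {
      dec <- aggregate_cohort(preds,
                              aggregation_params(t_grid[i], k_grid[j]),
                              average = average)
      cc <- confusion(dec, truth)
      tabs$mcc[i, j] <- mcc(cc)
      tabs$accuracy[i, j] <- accuracy(cc)
      tabs$f1[i, j] <- f1(cc)
    }
  }
  best <- max(tabs$mcc)
  cand <- which(tabs$mcc == best, arr.ind = TRUE)
  zero_un <- cand[unpred[cand[, 1]] == 0L, , drop = FALSE]
  if (nrow(zero_un)) cand <- zero_un
  cand <- cand[order(-t_grid[cand[, 1]], -k_grid[cand[, 2]]), ,
               drop = FALSE]
  sel <- c(t = t_grid[cand[1, 1]], k = k_grid[cand[1, 2]])
  structure(list(mcc = tabs$mcc, accuracy = tabs$accuracy, f1 = tabs$f1,
                 unpredicted = unpred, selected = sel,
                 t_grid = t_grid, k_grid = k_grid),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result %dx%d; max MCC %.4f at (t=%s, k=%d)>\n",
    length(x$t_grid), length(x$k_grid), max(x$mcc),
    format(x$selected[["t"]]), x$selected[["k"]]))
  invisible(x)
}

#' Explain a patient decision
#'
#' Builds the clinician-facing evidence report: the (at most `k`) snapshots
#' whose predictions produced the decision, in the order they were used,
#' with their probabilities, confidences and — when resolvable in the
#' cohort — source paths. An abstention yields a report that states so and
#' lists no images; an unresolvable image id produces a placeholder row.
#'
#' @param decision A `patient_decision`.
#' @param x Optional [cohort()] used to resolve image paths.
#' @return List of class `decision_explanation` with `patient_id`,
#'   `outcome`, `score` and `images` (data frame `image_id`, `p_pos`,
#'   `confidence`, `path`). Serializes losslessly through JSON via
#'   [write_explanation()].
#' @export
explain_decision <- function(decision, x = NULL) {
  ev <- decision$evidence
  paths <- rep(NA_character_, nrow(ev))
  if (!is.null(x) && nrow(ev)) {
    cs <- x$cases[[decision$patient_id]]
    lookup <- stats::setNames(
      vapply(cs$images, function(im)
        im$source_path %||% NA_character_, character(1)),
      vapply(cs$images, `[[`, character(1), "image_id"))
    paths <- unname(lookup[ev$image_id])
    if (anyNA(match(ev$image_id, names(lookup))))
      paths[is.na(match(ev$image_id, names(lookup)))] <- "<missing image>"
  }
  structure(
    list(patient_id = decision$patient_id, outcome = decision$outcome,
         score = decision$score,
         images = cbind(ev, path = paths)),
    class = "decision_explanation")
}

#' Serialize / deserialize a decision explanation as JSON
#' @param expl A `decision_explanation`.
#' @param path File path.
#' @return `read_explanation` returns a `decision_explanation`.
#' @export
write_explanation <- function(expl, path) {
  jsonlite::write_json(
    list(patient_id = expl$patient_id, outcome = expl$outcome,
         score = expl$score, images = expl$images),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_explanation
#' @export
read_explanation <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  imgs <- raw$images
  if (!is.data.frame(imgs))
    imgs <- data.frame(image_id = character(0), p_pos = numeric(0),
                       confidence = numeric(0), path = character(0))
  structure(list(patient_id = raw$patient_id, outcome = raw$outcome,
                 score = raw$score %||% NA_real_, images = imgs),
            class = "decision_explanation")
}
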
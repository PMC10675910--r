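#' Confusion counts with abstention handling
#'
#' Tallies patient decisions against ground truth. An abstaining
#' (`"unpredicted"`) patient is counted as an error against its true class:
#' a positive patient becomes a false negative, a negative patient a false
#' positive — the "considered wrong" rule used during hyperparameter tuning.
#'
#' @param decisions List of `patient_decision`s (or a character vector of
#'   outcomes named by patient id).
#' @param truth Named character vector patient_id -> `"positive"` /
#'   `"negative"`.
#' @return Object of class `confusion_counts`: integers `TP`, `TN`, `FP`,
#'   `FN` summing to the number of evaluated patients.
#' @export
confusion <- function(decisions, truth) {
  if (is.list(decisions)) {
    out <- vapply(decisions, `[[`, character(1), "outcome")
    names(out) <- vapply(decisions, `[[`, character(1), "patient_id")
  } else out <- decisions
  tr <- truth[names(out)]
  if (anyNA(tr) || !all(tr %in% c("positive", "negative")))
    stop("missing or non-binary ground-truth label")
  eff <- ifelse(out == "unpredicted",
                ifelse(tr == "positive", "negative", "positive"),  # wrong
                out)
  structure(list(TP = sum(eff == "positive" & tr == "positive"),
                 TN = sum(eff == "negative" & tr == "negative"),
                 FP = sum(eff == "positive" & tr == "negative"),
                 FN = sum(eff == "negative" & tr == "positive")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion TP=%d TN=%d FP=%d FN=%d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' confusion-matrix correlation in `[-1, 1]` that rewards good performance
#' on all four cells. Any zero factor in the denominator gives 0 by
#' convention.
#'
#' @param c A [confusion()] result (or list with TP/TN/FP/FN).
#' @return Scalar in `[-1, 1]`.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Accuracy and F1 score
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`; `F1 = 2TP / (2TP + FP + FN)`.
#'
#' @param c A [confusion()] result.
#' @return Scalar in `[0, 1]`; errors on an empty confusion matrix
#'   (accuracy) or when TP, FP and FN are all zero (F1).
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stop("empty confusion matrix")
  (c$TP + c$TN) / tot
}

#' @rdname accuracy
#' @export
f1 <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) stop("F1 undefined: TP, FP and FN all zero")
  2 * c$TP / den
}

metric_fun <- function(name) {
  switch(name, mcc = mcc, accuracy = accuracy, f1 = f1,
         stop("unknown metric: ", name))
}

#' Bootstrap confidence interval for a patient-level metric
#'
#' Resamples patients with replacement `B` times and summarizes the metric
#' over the resamples as a mean `mu` and a 5%-95% confidence radius `rho`.
#' Under the default normal mode the radius is `1.6449 * sd(resamples)`
#' (two-sided 90% normal interval); `mode = "percentile"` instead uses half
#' the distance between the 5% and 95% empirical quantiles.
#'
#' Because every supported metric depends on the resample only through its
#' confusion counts, the patient resample is drawn directly as a multinomial
#' over the four confusion categories — mathematically identical to
#' resampling patient ids, and fast enough for the study default
#' `B = 1e5`.
#'
#' @param decisions,truth As in [confusion()].
#' @param metric `"mcc"`, `"accuracy"` or `"f1"`.
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param mode `"normal"` or `"percentile"`.
#' @return Object of class `metric_estimate`: `metric`, `mu`, `rho`, `B`,
#'   `seed`, `level = "5%-95%"`, `plugin` (the metric on the full cohort).
#' @export
bootstrap_ci <- function(decisions, truth, metric = "mcc", B = 1e5,
                         seed = 1L, mode = c("normal", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  cc <- confusion(decisions, truth)
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (cc$TP + cc$FN == 0L || cc$TN + cc$FP == 0L)
    warning("one class absent from the cohort; metric conventions apply")
  f <- metric_fun(metric)
  draws <- withr::with_seed(seed, {
    stats::rmultinom(B, n, prob = c(cc$TP, cc$TN, cc$FP, cc$FN) / n)
  })
  # vectorized over resamples (counts as doubles: products reach n^4)
  TP <- as.numeric(draws[1, ]); TN <- as.numeric(draws[2, ])
  FP <- as.numeric(draws[3, ]); FN <- as.numeric(draws[4, ])
  vals <- switch(
    metric,
    mcc = {
      den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
      ifelse(den == 0, 0, (TP * TN - FP * FN) / sqrt(den))
    },
    accuracy = (TP + TN) / n,
    f1 = {
      den <- 2 * TP + FP + FN
      ifelse(den == 0, NA_real_, 2 * TP / den)
    })
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("metric undefined on every resample")
  mu <- mean(vals)
  rho <- if (mode == "normal") {
    1.6449 * stats::sd(vals)
  } else {
    diff(stats::quantile(vals, c(0.05, 0.95), names = FALSE)) / 2
  }
  if (is.na(rho)) rho <- 0   # B = 1
  structure(list(metric = metric, mu = mu, rho = rho, B = as.integer(B),
                 seed = as.integer(seed), level = "5%-95%",
                 mode = mode, plugin = f(cc)),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("<%s: mu=%.4f rho=%.2e (B=%d, %s %s)>\n",
              x$metric, x$mu, x$rho, x$B, x$level, x$mode))
  invisible(x)
}

#' Evaluate all three study metrics with bootstrap CIs
#'
#' @inheritParams bootstrap_ci
#' @return Data frame with one row per metric: `metric`, `mu`, `rho`,
#'   `plugin`, `B`.
#' @export
evaluate_metrics <- function(decisions, truth, B = 1e5, seed = 1L,
                             mode = c("normal", "percentile")) {
  mode <- match.arg(mode)
  rows <- lapply(c("mcc", "accuracy", "f1"), function(m) {
    est <- bootstrap_ci(decisions, truth, metric = m, B = B, seed = seed,
                        mode = mode)
    data.frame(metric = m, mu = est$mu, rho = est$rho,
               plugin = est$plugin, B = est$B, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
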
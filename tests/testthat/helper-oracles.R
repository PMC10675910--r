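# Independent brute-force references. These deliberately re-derive each
# quantity with plain loops and explicit formulas, sharing no code with the
# package implementation.

# confidence-filtered, stably sorted, top-k confidence-weighted mean
oracle_aggregate <- function(p_pos, conf, t, k, average = "probability") {
  surv <- which(conf >= t)
  if (!length(surv))
    return(list(outcome = "unpredicted", score = NA_real_,
                taken = integer(0)))
  ord <- surv[order(-conf[surv], surv)]       # ties: input order
  taken <- ord[seq_len(min(k, length(ord)))]
  val <- if (average == "probability") p_pos[taken]
         else as.numeric(p_pos[taken] >= 0.5)
  num <- 0; den <- 0
  for (i in seq_along(taken)) {
    num <- num + conf[taken[i]] * val[i]
    den <- den + conf[taken[i]]
  }
  score <- num / den
  list(outcome = if (score >= 0.5) "positive" else "negative",
       score = score, taken = taken)
}

# interior 3x3 Laplacian convolution followed by variance, via double loop
oracle_laplacian_var <- function(lum) {
  h <- nrow(lum); w <- ncol(lum)
  resp <- c()
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    resp <- c(resp, lum[i - 1, j] + lum[i + 1, j] +
                lum[i, j - 1] + lum[i, j + 1] - 4 * lum[i, j])
  }
  var(resp)
}

oracle_mcc <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# full grid evaluation with the abstention-is-wrong rule and the documented
# selection tie-break, all in plain loops
oracle_grid <- function(preds, truth, t_grid, k_grid) {
  pids <- unique(preds$patient_id)
  mcc_tab <- acc_tab <- f1_tab <-
    matrix(NA_real_, length(t_grid), length(k_grid))
  unpred <- integer(length(t_grid))
  for (ti in seq_along(t_grid)) {
    for (pid in pids) {
      pc <- preds[preds$patient_id == pid, ]
      if (max(pc$confidence) < t_grid[ti]) unpred[ti] <- unpred[ti] + 1L
    }
    for (ki in seq_along(k_grid)) {
      tp <- tn <- fp <- fn <- 0L
      for (pid in pids) {
        pc <- preds[preds$patient_id == pid, ]
        res <- oracle_aggregate(pc$p_pos, pc$confidence,
                                t_grid[ti], k_grid[ki])
        out <- res$outcome
        if (out == "unpredicted")
          out <- if (truth[pid] == "positive") "negative" else "positive"
        if (truth[pid] == "positive") {
          if (out == "positive") tp <- tp + 1L else fn <- fn + 1L
        } else {
          if (out == "negative") tn <- tn + 1L else fp <- fp + 1L
        }
      }
      mcc_tab[ti, ki] <- oracle_mcc(tp, tn, fp, fn)
      acc_tab[ti, ki] <- (tp + tn) / (tp + tn + fp + fn)
      f1_tab[ti, ki] <- 2 * tp / (2 * tp + fp + fn)
    }
  }
  best <- max(mcc_tab)
  cells <- list()
  for (ti in seq_along(t_grid)) for (ki in seq_along(k_grid))
    if (mcc_tab[ti, ki] == best)
      cells[[length(cells) + 1L]] <- c(ti, ki)
  zero <- Filter(function(c) unpred[c[1]] == 0L, cells)
  if (length(zero)) cells <- zero
  pick <- cells[[1]]
  for (c in cells) {
    if (t_grid[c[1]] > t_grid[pick[1]] ||
        (t_grid[c[1]] == t_grid[pick[1]] &&
         k_grid[c[2]] > k_grid[pick[2]])) pick <- c
  }
  list(mcc = mcc_tab, accuracy = acc_tab, f1 = f1_tab,
       unpredicted = unpred,
       selected = c(t = t_grid[pick[1]], k = k_grid[pick[2]]))
}

# elementwise scalar-loop quantizer
oracle_quantize <- function(x, s, Z, qmin, qmax) {
  out <- x
  for (i in seq_along(x)) {
    q <- round(x[i] / s + Z)
    out[i] <- min(max(q, qmin), qmax)
  }
  out
}
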
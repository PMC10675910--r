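# Internals of the tiny_cnn backbone: a compact three-conv network
# (3x3 valid convolutions via im2col, ReLU, 2x2 average pooling, linear
# head) with a hand-written backward pass. Gradient-level control is what
# lets the quantization engine insert fake-quant/STE and PACT hooks into
# both the forward and backward passes.

CONV_KSIZE <- 3L

# im2col for a 3x3 valid convolution on an H x W x C array.
# Rows index output positions (column-major over the Ho x Wo grid); columns
# index (di, dj, channel) with di fastest — the weight matrix row order.
im2col3 <- function(x) {
  d <- dim(x)
  Ho <- d[1] - 2L; Wo <- d[2] - 2L
  out <- matrix(0, Ho * Wo, 9L * d[3])
  k <- 0L
  for (c in seq_len(d[3])) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    out[, k] <- x[di + seq_len(Ho), dj + seq_len(Wo), c]
  }
  out
}

# adjoint of im2col3: scatter column gradients back onto the input array
col2im3 <- function(dcols, H, W, C) {
  dx <- array(0, c(H, W, C))
  Ho <- H - 2L; Wo <- W - 2L
  k <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    dx[di + seq_len(Ho), dj + seq_len(Wo), c] <-
      dx[di + seq_len(Ho), dj + seq_len(Wo), c] + matrix(dcols[, k], Ho, Wo)
  }
  dx
}

# 2x2 average pooling, stride 2, trailing row/column dropped when odd
avgpool2 <- function(a) {
  d <- dim(a)
  Hp <- d[1] %/% 2L; Wp <- d[2] %/% 2L
  i1 <- seq_len(Hp) * 2L - 1L
  j1 <- seq_len(Wp) * 2L - 1L
  (a[i1, j1, , drop = FALSE] + a[i1 + 1L, j1, , drop = FALSE] +
     a[i1, j1 + 1L, , drop = FALSE] + a[i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
}

unpool2 <- function(dp, Ho, Wo) {
  d <- dim(dp)
  da <- array(0, c(Ho, Wo, d[3]))
  i1 <- seq_len(d[1]) * 2L - 1L
  j1 <- seq_len(d[2]) * 2L - 1L
  g <- dp / 4
  da[i1, j1, ] <- g
  da[i1 + 1L, j1, ] <- g
  da[i1, j1 + 1L, ] <- g
  da[i1 + 1L, j1 + 1L, ] <- g
  da
}

tinycnn_channels <- c(conv1 = 8L, conv2 = 12L, conv3 = 16L)

# spatial dimensions after each conv+pool stage
tinycnn_geometry <- function(input_size) {
  h <- input_size[1]; w <- input_size[2]
  geom <- list()
  for (nm in names(tinycnn_channels)) {
    ho <- h - 2L; wo <- w - 2L
    if (ho < 2L || wo < 2L)
      stop("input_size too small for the tiny_cnn stage stack")
    h <- ho %/% 2L; w <- wo %/% 2L
    geom[[nm]] <- list(Ho = ho, Wo = wo, Hp = h, Wp = w)
  }
  geom
}

init_tinycnn <- function(spec, seed = 1L) {
  geom <- tinycnn_geometry(spec$input_size)
  withr::with_seed(seed, {
    layers <- list()
    c_in <- 3L
    for (nm in names(tinycnn_channels)) {
      c_out <- tinycnn_channels[[nm]]
      fan_in <- 9L * c_in
      layers[[nm]] <- list(
        type = "conv", c_in = c_in, c_out = c_out,
        W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                   fan_in, c_out),
        b = numeric(c_out))
      c_in <- c_out
    }
    g <- geom[[length(geom)]]
    n_flat <- g$Hp * g$Wp * c_in
    layers$fc <- list(
      type = "fc", c_in = n_flat, c_out = spec$n_classes,
      W = matrix(stats::rnorm(n_flat * spec$n_classes,
                              sd = sqrt(2 / n_flat)),
                 n_flat, spec$n_classes),
      b = numeric(spec$n_classes))
    structure(list(backbone = spec, layers = layers, geometry = geom,
                   quant = NULL, history = NULL),
              class = "tinycnn")
  })
}

#' @export
print.tinycnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b),
                   numeric(1)))
  q <- if (is.null(x$quant)) "fp32" else
    paste0(x$quant$mode, "[", paste(x$quant$selection, collapse = ","), "]")
  cat(sprintf("<tinycnn %dx%d input, %d params, %s>\n",
              x$backbone$input_size[1], x$backbone$input_size[2], np, q))
  invisible(x)
}

# effective (possibly fake-quantized) weight of a layer, with STE mask
effective_weight <- function(model, nm) {
  q <- model$quant
  lay <- model$layers[[nm]]
  if (is.null(q) || !(nm %in% q$selection))
    return(list(W = lay$W, mask = NULL))
  fq <- fake_quant(lay$W, q$wq[[nm]])
  list(W = fq$value, mask = fq$mask)
}

# Forward pass for one image tensor x (H x W x 3 in [0,1]).
# want = "probs" for inference, "cache" for training, "acts" to harvest
# post-ReLU activations for observer calibration.
forward_tinycnn <- function(model, x, want = "probs") {
  q <- model$quant
  cache <- if (want == "cache") list() else NULL
  acts <- if (want == "acts") list() else NULL
  for (nm in names(tinycnn_channels)) {
    cols <- im2col3(x)
    ew <- effective_weight(model, nm)
    pre <- sweep(cols %*% ew$W, 2L, model$layers[[nm]]$b, "+")
    a <- pre * (pre > 0)
    amask <- NULL
    if (!is.null(q) && nm %in% q$selection) {
      if (identical(q$mode, "pact")) {
        pf <- pact_fake_quant(a, q$alpha_tilde[[nm]], q$act_range)
        amask <- pf
        a <- pf$value
      } else if (!is.null(q$aq[[nm]])) {
        af <- fake_quant(a, q$aq[[nm]])
        amask <- af$mask
        a <- af$value
      }
    }
    if (want == "acts") acts[[nm]] <- a
    g <- model$geometry[[nm]]
    a_arr <- array(a, c(g$Ho, g$Wo, model$layers[[nm]]$c_out))
    pooled <- avgpool2(a_arr)
    if (want == "cache")
      cache[[nm]] <- list(x_dim = dim(x), cols = cols, pre = pre,
                          wmask = ew$mask, amask = amask, W_eff = ew$W)
    x <- pooled
  }
  v <- as.vector(x)
  ewf <- effective_weight(model, "fc")
  logits <- drop(v %*% ewf$W) + model$layers$fc$b
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  out <- list(logits = logits, p = p)
  if (want == "cache") {
    cache$fc <- list(v = v, wmask = ewf$mask, W_eff = ewf$W)
    out$cache <- cache
  }
  if (want == "acts") out$acts <- acts
  out
}

# Backward pass; returns per-layer gradients (and PACT clip gradients).
# dlogits is the cross-entropy gradient at the logits.
backward_tinycnn <- function(model, cache, dlogits) {
  q <- model$quant
  grads <- list()
  galpha <- list()
  fcc <- cache$fc
  gW <- fcc$v %o% dlogits
  if (!is.null(fcc$wmask)) gW <- gW * fcc$wmask
  grads$fc <- list(W = gW, b = dlogits)
  dv <- drop(fcc$W_eff %*% dlogits)
  nms <- names(tinycnn_channels)
  g_last <- model$geometry[[nms[length(nms)]]]
  dpool <- array(dv, c(g_last$Hp, g_last$Wp,
                       model$layers[[nms[length(nms)]]]$c_out))
  for (i in rev(seq_along(nms))) {
    nm <- nms[i]
    cc <- cache[[nm]]
    g <- model$geometry[[nm]]
    da_arr <- unpool2(dpool, g$Ho, g$Wo)
    da <- matrix(da_arr, g$Ho * g$Wo, model$layers[[nm]]$c_out)
    if (!is.null(cc$amask)) {
      if (identical(q$mode, "pact")) {
        galpha[[nm]] <- sum(da * cc$amask$dalpha_mask)
        da <- da * cc$amask$dx_mask
      } else {
        da <- da * cc$amask
      }
    }
    dpre <- da * (cc$pre > 0)
    gW <- crossprod(cc$cols, dpre)
    if (!is.null(cc$wmask)) gW <- gW * cc$wmask
    grads[[nm]] <- list(W = gW, b = colSums(dpre))
    if (i > 1L) {
      dcols <- tcrossprod(dpre, cc$W_eff)
      dpool <- col2im3(dcols, cc$x_dim[1], cc$x_dim[2], cc$x_dim[3])
    }
  }
  list(grads = grads, galpha = galpha)
}

# --- Adam -------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- grads[[nm]] * 0
      state$v[[nm]] <- grads[[nm]] * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
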
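#' Integer quantization range
#'
#' The target set of a quantizer: consecutive integers from `q_min` to
#' `q_max`. Two presets cover the defaults used throughout: signed symmetric
#' int8 `[-127, 127]` for weights and unsigned uint8 `[0, 255]` for
#' (non-negative) activations.
#'
#' @param q_min,q_max Integer bounds, `q_min < q_max`.
#' @return Object of class `quant_range`.
#' @export
quant_range <- function(q_min, q_max) {
  stopifnot(q_min < q_max)
  structure(list(q_min = as.integer(q_min), q_max = as.integer(q_max)),
            class = "quant_range")
}

#' @rdname quant_range
#' @export
int8_symmetric_range <- function() quant_range(-127L, 127L)

#' @rdname quant_range
#' @export
uint8_range <- function() quant_range(0L, 255L)

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

new_quant_params <- function(s, Z, range, alpha, beta, scheme, granularity,
                             channel_axis = NULL) {
  stopifnot(all(s > 0))
  structure(
    list(s = s, Z = Z, range = range, alpha = alpha, beta = beta,
         scheme = scheme, granularity = granularity,
         channel_axis = channel_axis),
    class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat(sprintf("<quant_params %s/%s s=%s Z=%s clip=[%s, %s] Q=[%d,%d]>\n",
              x$scheme, x$granularity,
              paste(signif(x$s, 4), collapse = ","),
              paste(x$Z, collapse = ","),
              paste(signif(x$alpha, 4), collapse = ","),
              paste(signif(x$beta, 4), collapse = ","),
              x$range$q_min, x$range$q_max))
  invisible(x)
}

#' Affine (asymmetric) calibration
#'
#' Maps the observed clipping range `[alpha, beta]` onto the integer range:
#' `s = (beta - alpha) / (q_max - q_min)` and
#' `Z = round(-(alpha/s - q_min))` (zero point rounded half away from zero).
#' Vector `alpha`/`beta` produce per-channel parameters.
#'
#' @param alpha,beta Observed minimum / maximum (scalars, or vectors for
#'   per-channel calibration), `alpha < beta` elementwise.
#' @param range A [quant_range()].
#' @param channel_axis Channel axis for per-channel parameters (vector
#'   input), `NULL` for per-tensor.
#' @param degenerate Policy when `alpha == beta`: `"error"` (default) or
#'   `"unit_scale"` (`s = 1`, `Z = q_min`, with a warning).
#' @return A `quant_params` object.
#' @export
calibrate_affine <- function(alpha, beta, range = uint8_range(),
                             channel_axis = NULL,
                             degenerate = c("error", "unit_scale")) {
  degenerate <- match.arg(degenerate)
  stopifnot(length(alpha) == length(beta), all(alpha <= beta))
  bad <- alpha == beta
  if (any(bad)) {
    if (degenerate == "error")
      stop("degenerate clipping range: alpha == beta")
    warning("degenerate clipping range; substituting s = 1, Z = q_min")
  }
  s <- (beta - alpha) / (range$q_max - range$q_min)
  s[bad] <- 1
  Z <- round_half_away(-(alpha / s - range$q_min))
  Z[bad] <- range$q_min
  new_quant_params(s, Z, range, alpha, beta, scheme = "affine",
                   granularity = if (length(s) > 1L) "per_channel"
                   else "per_tensor",
                   channel_axis = channel_axis)
}

#' Symmetric calibration
#'
#' Centers the clipping range on zero: `beta = max(|alpha_obs|, |beta_obs|)`,
#' clip `[-beta, beta]`, `s = 2 beta / (q_max - q_min)`; the zero point is the
#' midpoint of the integer range, so real 0 maps to integer 0 on symmetric
#' signed ranges.
#'
#' @param alpha_obs,beta_obs Observed extrema (scalars or per-channel
#'   vectors).
#' @inheritParams calibrate_affine
#' @return A `quant_params` object.
#' @export
calibrate_symmetric <- function(alpha_obs, beta_obs,
                                range = int8_symmetric_range(),
                                channel_axis = NULL,
                                degenerate = c("error", "unit_scale")) {
  degenerate <- match.arg(degenerate)
  stopifnot(length(alpha_obs) == length(beta_obs))
  beta <- pmax(abs(alpha_obs), abs(beta_obs))
  bad <- beta == 0
  if (any(bad)) {
    if (degenerate == "error")
      stop("degenerate clipping range: all-zero tensor")
    warning("degenerate clipping range; substituting s = 1")
    beta[bad] <- (range$q_max - range$q_min) / 2
  }
  s <- 2 * beta / (range$q_max - range$q_min)
  Z <- rep(round_half_away((range$q_min + range$q_max) / 2), length(s))
  new_quant_params(s, Z, range, alpha = -beta, beta = beta,
                   scheme = "symmetric",
                   granularity = if (length(s) > 1L) "per_channel"
                   else "per_tensor",
                   channel_axis = channel_axis)
}

# broadcast a per-channel parameter vector over the shape of x
broadcast_param <- function(p, x, channel_axis) {
  if (length(p) == 1L) return(p)
  if (is.null(dim(x))) return(p[seq_along(x)])
  idx <- slice.index(x, channel_axis)
  array(p[idx], dim = dim(x))
}

#' Quantize a tensor
#'
#' Elementwise `round(x/s + Z)`, clamped to the integer range. Per-channel
#' parameters are applied along `params$channel_axis`.
#'
#' @param x Numeric vector, matrix or array.
#' @param params A `quant_params` object.
#' @return Integer-valued object of the same shape.
#' @export
quantize_tensor <- function(x, params) {
  s <- broadcast_param(params$s, x, params$channel_axis)
  Z <- broadcast_param(params$Z, x, params$channel_axis)
  q <- round(x / s + Z)
  pmin(pmax(q, params$range$q_min), params$range$q_max)
}

#' Dequantize a tensor
#'
#' Inverse map `s * (q - Z)`.
#'
#' @param q Integer-valued tensor from [quantize_tensor()].
#' @param params A `quant_params` object.
#' @return Numeric object of the same shape.
#' @export
dequantize_tensor <- function(q, params) {
  s <- broadcast_param(params$s, q, params$channel_axis)
  Z <- broadcast_param(params$Z, q, params$channel_axis)
  s * (q - Z)
}

#' Fake (simulated) quantization with the straight-through gradient mask
#'
#' Forward pass of quantization-aware training: `dequantize(quantize(x))`,
#' computed in floating point. The returned `mask` is the straight-through
#' estimator's gradient: 1 where `x` lies inside the clipping interval
#' `[alpha, beta]` (boundary included), 0 outside; the backward pass
#' multiplies the upstream gradient by it.
#'
#' @param x Numeric tensor.
#' @param params A `quant_params` object (frozen).
#' @return List with `value` (same shape as `x`) and `mask` (0/1, same
#'   shape).
#' @export
fake_quant <- function(x, params) {
  a <- broadcast_param(params$alpha, x, params$channel_axis)
  b <- broadcast_param(params$beta, x, params$channel_axis)
  list(value = dequantize_tensor(quantize_tensor(x, params), params),
       mask = (x >= a & x <= b) * 1)
}

#' Running min/max observer
#'
#' Collects elementwise extrema over the batches it sees; used during
#' calibration to estimate the clipping range on a held-out subset.
#' Per-channel observers track one (min, max) pair per channel slice.
#'
#' @param granularity `"per_tensor"` or `"per_channel"`.
#' @param channel_axis Axis of the channel dimension (per-channel only).
#' @return Object of class `minmax_observer` with `running_min`,
#'   `running_max`, `n_batches`.
#' @export
minmax_observer <- function(granularity = c("per_tensor", "per_channel"),
                            channel_axis = NULL) {
  granularity <- match.arg(granularity)
  if (granularity == "per_channel" && is.null(channel_axis))
    stop("per_channel observer needs a channel_axis")
  structure(
    list(granularity = granularity, channel_axis = channel_axis,
         running_min = NULL, running_max = NULL, n_batches = 0L),
    class = "minmax_observer")
}

#' Update an observer with a tensor
#'
#' @param state A [minmax_observer()].
#' @param x Numeric tensor (empty input is a no-op with a warning).
#' @return Updated observer. Order of batches does not matter.
#' @export
observer_update <- function(state, x) {
  if (!length(x)) {
    warning("empty tensor ignored by observer")
    return(state)
  }
  if (state$granularity == "per_tensor") {
    mn <- min(x); mx <- max(x)
  } else {
    idx <- if (is.null(dim(x))) seq_along(x) else
      slice.index(x, state$channel_axis)
    mn <- c(tapply(x, idx, min))
    mx <- c(tapply(x, idx, max))
  }
  if (state$n_batches == 0L) {
    state$running_min <- mn
    state$running_max <- mx
  } else {
    state$running_min <- pmin(state$running_min, mn)
    state$running_max <- pmax(state$running_max, mx)
  }
  state$n_batches <- state$n_batches + 1L
  state
}

#' PACT fake quantization of a non-negative activation
#'
#' Parameterized-clipping activation: the clipping parameter `alpha_tilde` is
#' trainable and sets the scale directly, `s = alpha_tilde / (q_max - q_min)`
#' with zero point 0 on the unsigned range. Inputs are clamped to
#' `[0, alpha_tilde]` before quantize/dequantize. The returned masks carry
#' the two STE-style gradients: `dx_mask` (pass-through for
#' `0 <= x < alpha_tilde`) and `dalpha_mask` (pass-through for
#' `x >= alpha_tilde`, so the clip learns from saturated inputs).
#'
#' @param x Non-negative numeric tensor (post-ReLU activations).
#' @param alpha_tilde Positive scalar clipping parameter.
#' @param range Integer range, default unsigned 8-bit `[0, 255]`.
#' @return List `value`, `dx_mask`, `dalpha_mask`, `s`.
#' @export
pact_fake_quant <- function(x, alpha_tilde, range = uint8_range()) {
  stopifnot(alpha_tilde > 0)
  s <- alpha_tilde / (range$q_max - range$q_min)
  xc <- pmin(pmax(x, 0), alpha_tilde)
  q <- pmin(pmax(round(xc / s), range$q_min), range$q_max)
  list(value = s * q,
       dx_mask = (x >= 0 & x < alpha_tilde) * 1,
       dalpha_mask = (x >= alpha_tilde) * 1,
       s = s)
}
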
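#' Default layer-selection policy
#'
#' Selects every quantizable layer except the first convolution and the
#' final classifier — the configuration found to preserve performance, since
#' the input stem and the head hold few, highly task-critical parameters.
#'
#' @param model A `tinycnn`.
#' @return Character vector of layer names to quantize; empty (with a
#'   warning) when the model has fewer than 3 layers.
#' @export
default_layer_selection <- function(model) {
  nms <- names(model$layers)
  if (length(nms) < 3L) {
    warning("model too small for the default selection policy")
    return(character(0))
  }
  setdiff(nms, c(nms[1], "fc"))
}

# Calibration shared by PTQ / QAT / PACT: symmetric per-channel weight
# parameters from the weights themselves; affine per-tensor activation
# parameters from min/max observers fed with post-ReLU activations on the
# calibration set (forward run with fake-quantized weights).
calibrate_model <- function(model, calib_cases, selection,
                            weight_range = int8_symmetric_range(),
                            act_range = uint8_range()) {
  ds <- build_image_dataset(calib_cases, model$backbone$input_size)
  if (!length(ds$x)) stop("empty calibration set")
  wq <- list()
  for (nm in selection) {
    W <- model$layers[[nm]]$W
    wq[[nm]] <- calibrate_symmetric(apply(W, 2, min), apply(W, 2, max),
                                    range = weight_range, channel_axis = 2L)
  }
  conv_sel <- intersect(selection,
                        names(tinycnn_channels))
  probe <- model
  probe$quant <- list(mode = "weights_only", selection = selection, wq = wq)
  obs <- stats::setNames(
    lapply(conv_sel, function(nm) minmax_observer("per_tensor")), conv_sel)
  for (x in ds$x) {
    acts <- forward_tinycnn(probe, x, want = "acts")$acts
    for (nm in conv_sel) obs[[nm]] <- observer_update(obs[[nm]], acts[[nm]])
  }
  aq <- lapply(obs, function(o) {
    if (o$running_max <= o$running_min)
      stop("degenerate activation range during calibration")
    calibrate_affine(o$running_min, o$running_max, range = act_range)
  })
  list(selection = selection, wq = wq, aq = aq,
       weight_range = weight_range, act_range = act_range)
}

# Freeze a calibrated/trained model into its deployable quantized form:
# integer weight tensors plus parameters, simulated at inference time.
freeze_quantized <- function(model, q) {
  q$mode <- "ptq"
  q$w_int <- stats::setNames(
    lapply(q$selection, function(nm)
      quantize_tensor(model$layers[[nm]]$W, q$wq[[nm]])),
    q$selection)
  model$quant <- q
  model
}

#' Post-training quantization
#'
#' Quantizes the selected layers' weights (symmetric, per output channel,
#' signed int8 by default) and calibrates activation quantizers (affine,
#' per-tensor, unsigned 8-bit) with min/max observers on the calibration
#' cases; all parameters are then frozen. Unselected layers are untouched,
#' and an empty selection leaves model outputs bit-identical. Inference runs
#' in quantize-dequantize simulation.
#'
#' @param model A fitted `tinycnn`.
#' @param calib_cases Calibration cases (typically a held-out subset of
#'   validation patients); must contain at least one image.
#' @param selection Layers to quantize; defaults to
#'   [default_layer_selection()].
#' @param weight_range,act_range Integer ranges for weights / activations.
#' @return The quantized model (`$quant$mode == "ptq"`).
#' @export
ptq <- function(model, calib_cases,
                selection = default_layer_selection(model),
                weight_range = int8_symmetric_range(),
                act_range = uint8_range()) {
  if (!length(calib_cases)) stop("empty calibration set")
  if (!length(selection)) {
    model$quant <- NULL
    return(model)
  }
  q <- calibrate_model(model, calib_cases, selection, weight_range,
                       act_range)
  freeze_quantized(model, q)
}

#' Quantization-aware training
#'
#' Calibrates scale and zero point exactly as [ptq()] does, freezes all
#' quantization parameters, then trains with fake quantization in the
#' selected layers: the forward pass applies quantize-dequantize while
#' gradients flow through the straight-through estimator (pass-through
#' inside the clipping range, zero outside). With `config$epochs = 0` the
#' result reduces to the PTQ model.
#'
#' @param model A fitted `tinycnn`.
#' @param train_cases Labeled cases to train on.
#' @param config A [train_config()].
#' @param calib_cases Cases for the initial calibration pass (default: the
#'   training cases).
#' @inheritParams ptq
#' @return Quantized model after training and final conversion.
#' @export
qat_train <- function(model, train_cases, config,
                      calib_cases = train_cases,
                      selection = default_layer_selection(model),
                      weight_range = int8_symmetric_range(),
                      act_range = uint8_range()) {
  if (!length(selection)) stop("empty layer selection")
  q <- calibrate_model(model, calib_cases, selection, weight_range,
                       act_range)
  q$mode <- "fake"
  model$quant <- q
  ds <- build_image_dataset(train_cases, model$backbone$input_size)
  model <- train_network(model, ds, config)
  freeze_quantized(model, q)
}

#' PACT training
#'
#' Quantization training in which each selected layer's activation clipping
#' parameter `alpha_tilde` is itself trainable, with the activation scale
#' recomputed every step as `s = alpha_tilde / (q_max - q_min)`.
#' `alpha_tilde` is initialized from the observer calibration and receives
#' the saturation gradient (pass-through where the activation exceeds the
#' clip); weights train as in [qat_train()]. A clip driven to zero or below
#' is clamped to a small positive value.
#'
#' @inheritParams qat_train
#' @return Quantized model; `$quant$alpha_tilde` records the learned clips.
#' @export
pact_train <- function(model, train_cases, config,
                       calib_cases = train_cases,
                       selection = default_layer_selection(model),
                       weight_range = int8_symmetric_range(),
                       act_range = uint8_range()) {
  if (!length(selection)) stop("empty layer selection")
  q <- calibrate_model(model, calib_cases, selection, weight_range,
                       act_range)
  q$mode <- "pact"
  q$alpha_tilde <- lapply(q$aq, function(p) p$beta)
  model$quant <- q
  ds <- build_image_dataset(train_cases, model$backbone$input_size)
  model <- train_network(model, ds, config)
  q <- model$quant                       # carries the learned clips
  q$aq <- lapply(q$alpha_tilde, function(a)
    calibrate_affine(0, a, range = q$act_range))
  freeze_quantized(model, q)
}

#' Storage size of a (partially quantized) model
#'
#' Accounts each parameter of a selected layer at `weight_bits` and each
#' remaining parameter at `fp_bits`, plus (optionally) the quantization
#' parameter overhead: one `(s, Z)` pair per weight channel and one
#' per-tensor pair per quantized activation, 8 bytes each. With every layer
#' selected at 8 bits and overhead excluded the total is exactly one-fourth
#' of the 32-bit size.
#'
#' @param model A `tinycnn`.
#' @param selection Layers counted as quantized.
#' @param weight_bits,fp_bits Bit widths in {8, 16, 32}.
#' @param include_overhead Count quantization parameters.
#' @return Size in bytes (numeric scalar).
#' @export
model_size_bytes <- function(model,
                             selection = default_layer_selection(model),
                             weight_bits = 8L, fp_bits = 32L,
                             include_overhead = TRUE) {
  stopifnot(weight_bits %in% c(8L, 16L, 32L), fp_bits %in% c(8L, 16L, 32L))
  total <- 0
  for (nm in names(model$layers)) {
    np <- length(model$layers[[nm]]$W) + length(model$layers[[nm]]$b)
    bits <- if (nm %in% selection) weight_bits else fp_bits
    total <- total + np * bits / 8
    if (include_overhead && nm %in% selection) {
      total <- total + 2 * ncol(model$layers[[nm]]$W) * 4   # per-channel s,Z
      if (model$layers[[nm]]$type == "conv") total <- total + 8
    }
  }
  total
}
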
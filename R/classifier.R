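#' Training configuration
#'
#' The training recipe: Adam with a starting learning rate of 0.001 decayed
#' by a factor of 0.1 every 20 epochs, LASSO (L1) regularization of the
#' trainable weights, and partial fine-tuning restricted to the last two
#' convolution-bearing stages plus the classification head.
#'
#' @param lr0 Starting learning rate (> 0).
#' @param lr_decay_factor Multiplicative decay in (0, 1].
#' @param lr_decay_every Epochs between decay steps.
#' @param l1_lambda L1 (LASSO) penalty strength on trainable weights.
#' @param epochs Number of training epochs (0 allowed: calibrate-only runs).
#' @param batch_size Minibatch size.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param trainable_scope `"last_two_conv_plus_head"` (freeze everything
#'   before the final two convolutional stages) or `"all"`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every = 20L, l1_lambda = 1e-5,
                         epochs = 60L, batch_size = 16L, seed = 1L,
                         trainable_scope = c("last_two_conv_plus_head",
                                             "all")) {
  stopifnot(lr0 > 0, lr_decay_factor > 0, lr_decay_factor <= 1,
            lr_decay_every >= 1, l1_lambda >= 0, epochs >= 0,
            batch_size >= 1)
  structure(
    list(lr0 = lr0, lr_decay_factor = lr_decay_factor,
         lr_decay_every = as.integer(lr_decay_every),
         l1_lambda = l1_lambda, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         trainable_scope = match.arg(trainable_scope)),
    class = "train_config")
}

#' Backbone specification
#'
#' The classifier backbone is pluggable; the package ships `tiny_cnn`, a
#' compact three-convolution network sized to train on one CPU in minutes,
#' which every test and the synthetic study use. Larger pretrained backbones
#' can be registered by supplying the same fit/predict surface, but none is
#' bundled (no pretrained weights ship with the package).
#'
#' @param architecture Currently `"tiny_cnn"`.
#' @param input_size `c(H, W)` expected by the network (default 32 x 32).
#' @param n_classes Number of classes (2: IBD vs control).
#' @return Object of class `backbone_spec`.
#' @export
backbone_spec <- function(architecture = "tiny_cnn",
                          input_size = c(32L, 32L), n_classes = 2L) {
  if (!identical(architecture, "tiny_cnn"))
    stop("unsupported architecture '", architecture,
         "'; this build ships tiny_cnn only")
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes)),
            class = "backbone_spec")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * factor^floor(epoch / every)` with 0-based epochs, so
#' epoch 0 trains at `lr0` and epoch 20 (defaults) at `lr0 * 0.1`.
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index.
#' @return Positive learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(all(epoch >= 0))
  config$lr0 * config$lr_decay_factor^floor(epoch / config$lr_decay_every)
}

#' LASSO penalty of a set of weights
#'
#' `lambda * sum(|w|)` over the supplied (trainable) weights; added to the
#' task loss during training to encourage sparse weights.
#'
#' @param weights Numeric vector/matrix, or list thereof.
#' @param lambda Penalty strength.
#' @return Non-negative scalar.
#' @export
l1_penalty <- function(weights, lambda) {
  lambda * sum(abs(unlist(weights, use.names = FALSE)))
}

trainable_layers <- function(model, scope) {
  nms <- names(model$layers)
  if (scope == "all") return(nms)
  convs <- nms[vapply(model$layers, function(l) l$type == "conv",
                      logical(1))]
  c(utils::tail(convs, 2L), "fc")
}

# assemble (x, y) image tensors from labeled patient cases
build_image_dataset <- function(cases, input_size) {
  xs <- list(); ys <- integer(0); pid <- character(0); iid <- character(0)
  for (cs in cases) {
    if (!length(cs$images)) next
    if (cs$label == "unknown")
      stop("patient ", cs$patient_id, " has unknown label; cannot train")
    y <- if (cs$label == "positive") 1L else 0L
    for (im in cs$images) {
      px <- im$pixels
      d <- dim(px)
      if (d[1] != input_size[1] || d[2] != input_size[2])
        px <- resize_rgb(px, input_size[1], input_size[2])
      xs[[length(xs) + 1L]] <- px / 255
      ys <- c(ys, y)
      pid <- c(pid, cs$patient_id)
      iid <- c(iid, im$image_id)
    }
  }
  list(x = xs, y = ys, patient_id = pid, image_id = iid)
}

# Core training loop shared by plain training, QAT and PACT. Mutates and
# returns the model; records per-epoch mean loss and the lr actually used.
train_network <- function(model, ds, config) {
  n <- length(ds$x)
  if (!n) stop("empty training set")
  train_set <- trainable_layers(model, config$trainable_scope)
  opt <- adam_init()
  pact <- !is.null(model$quant) && identical(model$quant$mode, "pact")
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0))
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at_epoch(config, epoch)
      idx <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        batch <- idx[start:min(start + config$batch_size - 1L, n)]
        acc <- NULL
        galpha_acc <- list()
        bloss <- 0
        for (i in batch) {
          fw <- forward_tinycnn(model, ds$x[[i]], want = "cache")
          y1 <- ds$y[i] + 1L
          bloss <- bloss - log(max(fw$p[y1], 1e-12))
          dlogits <- fw$p
          dlogits[y1] <- dlogits[y1] - 1
          bw <- backward_tinycnn(model, fw$cache, dlogits)
          if (is.null(acc)) acc <- bw$grads else
            for (nm in names(acc)) {
              acc[[nm]]$W <- acc[[nm]]$W + bw$grads[[nm]]$W
              acc[[nm]]$b <- acc[[nm]]$b + bw$grads[[nm]]$b
            }
          for (nm in names(bw$galpha))
            galpha_acc[[nm]] <- (galpha_acc[[nm]] %||% 0) + bw$galpha[[nm]]
        }
        nb <- length(batch)
        flat <- list()
        for (nm in train_set) {
          gW <- acc[[nm]]$W / nb +
            config$l1_lambda * sign(model$layers[[nm]]$W)
          flat[[paste0(nm, ".W")]] <- gW
          flat[[paste0(nm, ".b")]] <- acc[[nm]]$b / nb
        }
        if (pact)
          for (nm in names(galpha_acc))
            flat[[paste0("alpha.", nm)]] <- galpha_acc[[nm]] / nb
        params <- list()
        for (nm in train_set) {
          params[[paste0(nm, ".W")]] <- model$layers[[nm]]$W
          params[[paste0(nm, ".b")]] <- model$layers[[nm]]$b
        }
        if (pact)
          for (nm in names(galpha_acc))
            params[[paste0("alpha.", nm)]] <- model$quant$alpha_tilde[[nm]]
        stepped <- adam_step(opt, params, flat, lr)
        opt <- stepped$state
        for (nm in train_set) {
          model$layers[[nm]]$W <- stepped$params[[paste0(nm, ".W")]]
          model$layers[[nm]]$b <- stepped$params[[paste0(nm, ".b")]]
        }
        if (pact)
          for (nm in names(galpha_acc))
            model$quant$alpha_tilde[[nm]] <-
              max(stepped$params[[paste0("alpha.", nm)]], 1e-3)
        ep_loss <- ep_loss + bloss
      }
      l1 <- l1_penalty(lapply(model$layers[train_set], `[[`, "W"),
                       config$l1_lambda)
      mean_loss <- ep_loss / n + l1
      if (!is.finite(mean_loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr, loss = mean_loss))
    }
  })
  model$history <- history
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the backbone on one fold
#'
#' Initializes a `tiny_cnn` and trains it on the (patient-disjoint) training
#' cases with the recipe in `config`: Adam, step-decayed learning rate, L1
#' penalty, partial freezing per `trainable_scope`. Deterministic for a fixed
#' seed. Validation cases, when given, are scored once at the end
#' (image-level accuracy, recorded on the model).
#'
#' @param train_cases List of labeled [patient_case()]s (non-empty images).
#' @param valid_cases Optional list of validation cases (patient-disjoint).
#' @param backbone A [backbone_spec()].
#' @param config A [train_config()].
#' @return A fitted `tinycnn` with `$history` (per-epoch `lr`, `loss`) and,
#'   when validation cases were supplied, `$valid_accuracy`.
#' @export
train_fold <- function(train_cases, valid_cases = NULL,
                       backbone = backbone_spec(),
                       config = train_config()) {
  if (!length(train_cases)) stop("empty train set")
  overlap <- intersect(
    vapply(train_cases, `[[`, character(1), "patient_id"),
    vapply(valid_cases %||% list(), `[[`, character(1), "patient_id"))
  if (length(overlap))
    stop("train/valid patient overlap: ", paste(overlap, collapse = ", "))
  ds <- build_image_dataset(train_cases, backbone$input_size)
  if (!length(ds$x)) stop("empty train set (no images)")
  model <- init_tinycnn(backbone, seed = config$seed)
  model$config <- config
  model <- train_network(model, ds, config)
  if (length(valid_cases)) {
    preds <- do.call(rbind, lapply(valid_cases, function(cs)
      predict_images(model, cs)))
    if (!is.null(preds) && nrow(preds)) {
      labs <- vapply(valid_cases, `[[`, character(1), "label")
      names(labs) <- vapply(valid_cases, `[[`, character(1), "patient_id")
      model$valid_accuracy <-
        mean(preds$predicted_label == labs[preds$patient_id])
    }
  }
  model
}

#' Patient-level k-fold cross-validation
#'
#' Trains one model per fold on all other folds and predicts the held-out
#' fold's images, yielding out-of-fold predictions for every training
#' patient — the inputs to the per-patient (t, k) grid search.
#'
#' @param x A [cohort()] restricted to training patients.
#' @param fold_of Named fold map from [assign_folds()].
#' @param backbone A [backbone_spec()].
#' @param config A [train_config()]; fold f trains with seed
#'   `config$seed + f`.
#' @return List with `models` (one per fold), `predictions` (row-bound
#'   out-of-fold [predict_images()] output with a `fold` column) and
#'   `fold_metrics` (per-fold image-level accuracy and counts).
#' @export
cross_validate <- function(x, fold_of, backbone = backbone_spec(),
                           config = train_config()) {
  stopifnot(inherits(x, "cohort"))
  folds <- sort(unique(fold_of))
  labs <- cohort_labels(x)
  models <- list()
  preds <- list()
  metrics <- list()
  for (f in folds) {
    valid_ids <- names(fold_of)[fold_of == f]
    train_ids <- names(fold_of)[fold_of != f]
    cfg <- config
    cfg$seed <- config$seed + as.integer(f)
    m <- train_fold(x$cases[train_ids], x$cases[valid_ids],
                    backbone = backbone, config = cfg)
    pf <- do.call(rbind, lapply(x$cases[valid_ids], function(cs)
      predict_images(m, cs)))
    if (!is.null(pf) && nrow(pf)) pf$fold <- f
    models[[as.character(f)]] <- m
    preds[[as.character(f)]] <- pf
    acc <- if (!is.null(pf) && nrow(pf))
      mean(pf$predicted_label == labs[pf$patient_id]) else NA_real_
    metrics[[as.character(f)]] <- data.frame(
      fold = f, n_patients = length(valid_ids),
      n_images = if (is.null(pf)) 0L else nrow(pf),
      image_accuracy = acc)
  }
  list(models = models,
       predictions = do.call(rbind, c(preds, list(make.row.names = FALSE))),
       fold_metrics = do.call(rbind, metrics))
}

#' Per-image predictions for one patient
#'
#' Classifies every image of a case independently. Confidence is the maximum
#' class probability (hence in `[0.5, 1]` for two classes); a positive-class
#' probability of exactly 0.5 classifies positive (documented tie-break).
#'
#' @param model A fitted `tinycnn` (floating-point or quantized).
#' @param case A [patient_case()]; images are resized to the backbone input
#'   size if needed.
#' @return Data frame with columns `patient_id`, `image_id`, `p_pos`,
#'   `predicted_label`, `confidence`; zero rows for an empty case.
#' @export
predict_images <- function(model, case) {
  if (!length(case$images))
    return(data.frame(patient_id = character(0), image_id = character(0),
                      p_pos = numeric(0), predicted_label = character(0),
                      confidence = numeric(0)))
  insz <- model$backbone$input_size
  p_pos <- vapply(case$images, function(im) {
    px <- im$pixels
    d <- dim(px)
    if (d[1] != insz[1] || d[2] != insz[2])
      px <- resize_rgb(px, insz[1], insz[2])
    forward_tinycnn(model, px / 255)$p[2]
  }, numeric(1))
  data.frame(
    patient_id = case$patient_id,
    image_id = vapply(case$images, `[[`, character(1), "image_id"),
    p_pos = p_pos,
    predicted_label = ifelse(p_pos >= 0.5, "positive", "negative"),
    confidence = pmax(p_pos, 1 - p_pos),
    stringsAsFactors = FALSE, row.names = NULL)
}
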
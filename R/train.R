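#' Prepare a stack for a convolutional backbone
#'
#' Applies one shared linear map per stack sending `[min, max]` of the whole
#' tensor to `[0, 255]` (mimicking 8-bit image range while preserving the
#' relative order of all entries), followed by the backbone's canonical
#' input normalization: `"tf"` mode scales to `[-1, 1]`, `"caffe"` mode
#' subtracts the ImageNet channel means (103.939, 116.779, 123.68).
#'
#' @param stack A [stack3d()].
#' @param backbone A [backbone_spec()] or backbone name (default TinyConv).
#' @return N x N x 3 numeric array ready for the backbone.
#' @export
prepare_input <- function(stack, backbone = backbone_spec("TinyConv")) {
  validate_stack3d(stack)
  if (!inherits(backbone, "backbone_spec")) backbone <- backbone_spec(backbone)
  x <- stack$channels
  rng <- range(x)
  if (rng[1] == rng[2])
    stopf("constant stack (min = max = %g): cannot scale", rng[1])
  x <- (x - rng[1]) / (rng[2] - rng[1]) * 255
  switch(backbone$preprocess,
         tf = x / 127.5 - 1,
         caffe = {
           means <- c(103.939, 116.779, 123.68)
           for (ch in 1:3) x[, , ch] <- x[, , ch] - means[ch]
           x
         },
         x)
}

#' Extract convolutional features
#'
#' Runs a prepared input tensor through the backbone's convolutional stage,
#' stopping before any fully connected layer. Only `TinyConv` can be
#' evaluated numerically in this package; the seven ImageNet architectures
#' are available for exact feature-geometry analysis via
#' [feature_map_shape()] but their pretrained weights are not shipped, so
#' requesting features from them raises an error.
#'
#' @param tensor Prepared N x N x 3 array (see [prepare_input()]).
#' @param backbone A [instantiate_tinyconv()] backbone, or a
#'   [backbone_spec()] (TinyConv specs are instantiated on the fly).
#' @return Feature array of shape [feature_map_shape()].
#' @export
extract_features <- function(tensor, backbone) {
  if (inherits(backbone, "backbone_spec")) {
    if (backbone$name != "TinyConv")
      stopf(paste0("%s pretrained weights are not available offline; ",
                   "numeric feature extraction is supported for TinyConv only ",
                   "(use feature_map_shape() for %s's exact feature geometry)"),
            backbone$name, backbone$name)
    backbone <- instantiate_tinyconv(dim(tensor)[1], dim(tensor)[3])
  }
  stopifnot(inherits(backbone, "tinyconv_backbone"))
  if (dim(tensor)[1] < 8L)
    stopf("TinyConv requires input side >= 8, got %d", dim(tensor)[1])
  if (dim(tensor)[1] != backbone$input_side)
    stopf("backbone was instantiated for side %d, tensor has side %d",
          backbone$input_side, dim(tensor)[1])
  tinyconv_forward(backbone, tensor)$features
}

#' Classifier head: flatten -> dropout -> sigmoid unit
#'
#' A single-unit logistic head over the flattened backbone features,
#' trained with binary cross-entropy. With `dropout_rate = 0` it is a plain
#' linear classifier. Parameter count is `prod(feature_shape) + 1`.
#'
#' @param feature_shape Integer vector, shape of the backbone feature map.
#' @param dropout_rate Dropout probability in `[0, 1)` applied to the
#'   flattened features during training only.
#' @return Object of class `cnn_head`.
#' @export
build_head <- function(feature_shape, dropout_rate = 0.5) {
  if (!(is.numeric(dropout_rate) && length(dropout_rate) == 1 &&
        dropout_rate >= 0 && dropout_rate < 1))
    stopf("dropout_rate must lie in [0, 1)")
  n_in <- prod(feature_shape)
  structure(list(feature_shape = as.integer(feature_shape),
                 n_in = as.integer(n_in), dropout = dropout_rate,
                 v = numeric(n_in), b = 0,
                 n_params = as.integer(n_in + 1L)),
            class = "cnn_head")
}

#' @export
print.cnn_head <- function(x, ...) {
  cat(sprintf("<cnn_head> %d features -> dropout(%.2f) -> sigmoid (%d parameters)\n",
              x$n_in, x$dropout, x$n_params))
  invisible(x)
}

head_predict <- function(head, features) {
  as.numeric(stats::plogis(features %*% head$v + head$b))
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Training schedule
#'
#' Hyperparameters for the two-phase transfer-learning workflow. Phase 1
#' trains the head only (backbone frozen); phase 2 (fine-tuning) unfreezes
#' everything and continues end-to-end at a much lower learning rate.
#'
#' @param lr_phase1 Head learning rate (Adam).
#' @param lr_fine_tune End-to-end fine-tuning learning rate; must be lower
#'   than `lr_phase1`.
#' @param epochs_phase1,epochs_fine_tune Epoch caps per phase.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param dropout Head dropout rate.
#' @param fine_tune Run phase 2?
#' @param seed Seed for batching, dropout and weight initialization.
#' @return List of class `training_schedule`.
#' @export
training_schedule <- function(lr_phase1 = 1e-3, lr_fine_tune = 1e-5,
                              epochs_phase1 = 100L, epochs_fine_tune = 5L,
                              batch_size = 16L, patience = 10L,
                              dropout = 0.5, fine_tune = FALSE, seed = 0L) {
  if (lr_fine_tune >= lr_phase1)
    stopf("fine-tuning learning rate (%g) must be lower than phase-1 rate (%g)",
          lr_fine_tune, lr_phase1)
  structure(list(lr_phase1 = lr_phase1, lr_fine_tune = lr_fine_tune,
                 epochs_phase1 = as.integer(epochs_phase1),
                 epochs_fine_tune = as.integer(epochs_fine_tune),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), dropout = dropout,
                 fine_tune = isTRUE(fine_tune), seed = as.integer(seed)),
            class = "training_schedule")
}

# Minimal Adam optimizer over a named list of arrays.
adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

#' Train the classifier head on fixed features
#'
#' Mini-batch Adam on binary cross-entropy with inverted dropout, early
#' stopping on validation loss (best weights restored). This is the
#' phase-1 ("frozen backbone") optimizer of [train_transfer()], exposed so
#' the head can be fitted and tested on any feature matrix.
#'
#' @param features n x d numeric matrix (one row per subject).
#' @param labels 0/1 vector (1 = case).
#' @param head A [build_head()] object with `n_in == ncol(features)`.
#' @param val_features,val_labels Validation set; defaults to the training
#'   set when absent (then early stopping monitors training loss).
#' @param lr,epochs,batch_size,patience,seed Optimization controls.
#' @return The fitted head, with a `history` data.frame attached
#'   (epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_head <- function(features, labels, head,
                       val_features = features, val_labels = labels,
                       lr = 1e-3, epochs = 100L, batch_size = 16L,
                       patience = 10L, seed = 0L) {
  features <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(ncol(features) == head$n_in, length(y) == nrow(features))
  if (length(unique(y)) < 2L)
    stopf("training set contains a single class")
  n <- nrow(features)
  params <- list(v = head$v, b = head$b)
  opt <- adam_new(params)
  best <- list(loss = Inf, params = params, wait = 0L)
  hist <- vector("list", epochs)
  with_seed(derive_seed(seed, 11L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, n)]
        fb <- features[bi, , drop = FALSE]
        if (head$dropout > 0) {
          mask <- matrix(stats::rbinom(length(fb), 1L, 1 - head$dropout),
                         nrow(fb)) / (1 - head$dropout)
          fb <- fb * mask
        }
        p <- as.numeric(stats::plogis(fb %*% params$v + params$b))
        dz <- (p - y[bi]) / length(bi)
        grads <- list(v = as.numeric(crossprod(fb, dz)), b = sum(dz))
        st <- adam_step(opt, params, grads, lr)
        opt <- st$state; params <- st$params
      }
      ptr <- as.numeric(stats::plogis(features %*% params$v + params$b))
      pva <- as.numeric(stats::plogis(as.matrix(val_features) %*% params$v + params$b))
      vl <- bce_loss(pva, as.numeric(val_labels))
      hist[[ep]] <- data.frame(epoch = ep,
                               train_loss = bce_loss(ptr, y),
                               train_acc = mean((ptr > 0.5) == (y == 1)),
                               val_loss = vl,
                               val_acc = mean((pva > 0.5) == (as.numeric(val_labels) == 1)))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= patience) break
      }
    }
  })
  head$v <- best$params$v
  head$b <- best$params$b
  head$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  head
}

#' Two-phase transfer-learning training
#'
#' Phase 1 extracts features with the frozen backbone and trains only the
#' dropout + sigmoid head. Phase 2 (if `schedule$fine_tune`) unfreezes the
#' backbone and re-trains everything end-to-end at the (much lower)
#' fine-tuning learning rate, with early stopping on validation loss.
#' Backbone weights are bit-identical before and after training when
#' fine-tuning is disabled.
#'
#' @param train,val Lists with elements `stacks` (list of [stack3d()]) and
#'   `labels` (factor case/control or 0/1 with 1 = case).
#' @param backbone A TinyConv [backbone_spec()] or an already instantiated
#'   [instantiate_tinyconv()] backbone.
#' @param schedule A [training_schedule()].
#' @return Object of class `transfer_model` with the (possibly fine-tuned)
#'   backbone, fitted head, and per-phase history.
#' @export
train_transfer <- function(train, val, backbone = backbone_spec("TinyConv"),
                           schedule = training_schedule()) {
  y_tr <- label_to_binary(train$labels)
  y_va <- label_to_binary(val$labels)
  if (!length(y_tr)) stopf("empty training set")
  if (length(unique(y_tr)) < 2L) stopf("training set contains a single class")

  side <- train$stacks[[1]]$N
  if (inherits(backbone, "backbone_spec")) {
    if (backbone$name != "TinyConv")
      stopf("end-to-end training is supported for the TinyConv backbone only")
    backbone <- instantiate_tinyconv(side, 3L, seed = schedule$seed)
  }
  spec <- backbone_spec("TinyConv")
  x_tr <- lapply(train$stacks, prepare_input, backbone = spec)
  x_va <- lapply(val$stacks, prepare_input, backbone = spec)

  feat <- function(bb, xs) t(vapply(xs, function(x)
    as.numeric(tinyconv_forward(bb, x)$features),
    numeric(prod(bb$feature_shape))))

  f_tr <- feat(backbone, x_tr)
  f_va <- feat(backbone, x_va)
  head <- build_head(backbone$feature_shape, schedule$dropout)
  head <- train_head(f_tr, y_tr, head, f_va, y_va,
                     lr = schedule$lr_phase1, epochs = schedule$epochs_phase1,
                     batch_size = schedule$batch_size,
                     patience = schedule$patience, seed = schedule$seed)
  history <- list(phase1 = head$history)

  if (schedule$fine_tune) {
    ft <- fine_tune_all(backbone, head, x_tr, y_tr, x_va, y_va, schedule)
    backbone <- ft$backbone
    head <- ft$head
    history$phase2 <- ft$history
  }
  structure(list(backbone = backbone, head = head, schedule = schedule,
                 history = history, fine_tuned = schedule$fine_tune),
            class = "transfer_model")
}

# End-to-end fine-tuning: joint Adam update of conv weights and head at the
# low learning rate; dropout still applies to the flattened features.
fine_tune_all <- function(backbone, head, x_tr, y_tr, x_va, y_va, schedule) {
  n <- length(x_tr)
  params <- c(backbone$params, list(hv = head$v, hb = head$b))
  opt <- adam_new(params)
  eval_loss <- function(params, xs, ys) {
    bb <- backbone; bb$params <- params[names(backbone$params)]
    f <- t(vapply(xs, function(x) as.numeric(tinyconv_forward(bb, x)$features),
                  numeric(prod(bb$feature_shape))))
    p <- as.numeric(stats::plogis(f %*% params$hv + params$hb))
    list(loss = bce_loss(p, ys), acc = mean((p > 0.5) == (ys == 1)))
  }
  best <- list(loss = eval_loss(params, x_va, y_va)$loss, params = params,
               wait = 0L)
  hist <- list()
  with_seed(derive_seed(schedule$seed, 23L), {
    for (ep in seq_len(schedule$epochs_fine_tune)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = schedule$batch_size)) {
        bi <- ord[start:min(start + schedule$batch_size - 1L, n)]
        bb <- backbone; bb$params <- params[names(backbone$params)]
        gsum <- NULL
        for (i in bi) {
          fw <- tinyconv_forward(bb, x_tr[[i]], with_cache = TRUE)
          fvec <- as.numeric(fw$features)
          mask <- if (head$dropout > 0)
            stats::rbinom(length(fvec), 1L, 1 - head$dropout) / (1 - head$dropout)
          else rep(1, length(fvec))
          fd <- fvec * mask
          p <- stats::plogis(sum(fd * params$hv) + params$hb)
          dz <- (p - y_tr[i]) / length(bi)
          dfeat_flat <- dz * params$hv * mask
          g <- tinyconv_backward(bb, fw$caches,
                                 array(dfeat_flat, dim(fw$features)))
          g$hv <- dz * fd
          g$hb <- dz
          gsum <- if (is.null(gsum)) g
                  else Map(`+`, gsum, g)
        }
        st <- adam_step(opt, params, gsum, schedule$lr_fine_tune)
        opt <- st$state; params <- st$params
      }
      tr <- eval_loss(params, x_tr, y_tr)
      va <- eval_loss(params, x_va, y_va)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tr$loss,
                               train_acc = tr$acc, val_loss = va$loss,
                               val_acc = va$acc)
      if (va$loss < best$loss - 1e-9) {
        best <- list(loss = va$loss, params = params, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= schedule$patience) break
      }
    }
  })
  backbone$params <- best$params[names(backbone$params)]
  head$v <- best$params$hv
  head$b <- best$params$hb
  list(backbone = backbone, head = head,
       history = do.call(rbind, hist))
}

label_to_binary <- function(labels) {
  if (is.factor(labels) || is.character(labels))
    as.numeric(as.character(labels) == "case")
  else as.numeric(labels)
}

#' Predict case probabilities from a fitted transfer model
#'
#' @param object A `transfer_model` from [train_transfer()].
#' @param stacks List of [stack3d()] objects.
#' @param type `"prob"` for sigmoid outputs, `"label"` for case/control at
#'   threshold 0.5.
#' @param ... Unused.
#' @return Numeric probabilities or a case/control factor.
#' @export
predict.transfer_model <- function(object, stacks, type = c("prob", "label"),
                                   ...) {
  type <- match.arg(type)
  spec <- backbone_spec("TinyConv")
  f <- t(vapply(stacks, function(s)
    as.numeric(tinyconv_forward(object$backbone,
                                prepare_input(s, spec))$features),
    numeric(prod(object$backbone$feature_shape))))
  p <- head_predict(object$head, f)
  if (type == "prob") p
  else factor(ifelse(p > 0.5, "case", "control"), levels = c("case", "control"))
}
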
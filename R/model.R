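#' Architecture specification for the tone estimator
#'
#' All profiles share the same structure: stacked 3x3 convolution blocks
#' (each convolution followed by batch normalisation and ReLU), max pooling
#' between stages, then fully connected layers with sigmoid activation and
#' dropout, ending in either a single real output (regression) or ten
#' class probabilities through a softmax (classification).
#'
#' Profiles:
#' * `"tiny"` — three conv blocks (8, 16, 32 filters), pooled to a 4x4
#'   map, one hidden FC layer of 64 units; sized for 32-64 px inputs and
#'   CPU training (inputs above 32 px pass through a fixed 2x2
#'   average-pool stem first).
#' * `"vgg11_like"` / `"vgg16_like"` — the 8- and 13-convolution layouts
#'   of the VGG family with two 4096-unit FC layers.
#'
#' @param profile One of `"tiny"`, `"vgg11_like"`, `"vgg16_like"`.
#' @param in_channels 3 or 9 input channels.
#' @param head `"regression"` (1 output) or `"classification"` (10
#'   probabilities).
#' @param side Input side in pixels.
#' @param dropout_p Dropout probability on the FC layers (default 0.5).
#' @param fc_widths Optional override of the hidden FC widths.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(profile = c("tiny", "vgg11_like", "vgg16_like"),
                              in_channels = 3L,
                              head = c("regression", "classification"),
                              side = 64L, dropout_p = 0.5,
                              fc_widths = NULL) {
  profile <- match.arg(profile)
  head <- match.arg(head)
  if (!in_channels %in% c(3L, 9L)) {
    abort("in_channels must be 3 or 9")
  }
  plan <- switch(profile,
    tiny = list(conv = list(8, "M", 16, "M", 32, "M"),
                fc = fc_widths %||% 64L),
    vgg11_like = list(
      conv = list(64, "M", 128, "M", 256, 256, "M", 512, 512, "M",
                  512, 512, "M"),
      fc = fc_widths %||% c(4096L, 4096L)),
    vgg16_like = list(
      conv = list(64, 64, "M", 128, 128, "M", 256, 256, 256, "M",
                  512, 512, 512, "M", 512, 512, 512, "M"),
      fc = fc_widths %||% c(4096L, 4096L))
  )
  structure(list(profile = profile, in_channels = as.integer(in_channels),
                 head = head, side = as.integer(side),
                 dropout_p = dropout_p, plan = plan),
            class = "architecture_spec")
}

#' Training configuration
#'
#' Defaults follow the tuned hyperparameters of the study protocol:
#' SGD with momentum 0.9, learning rate 1e-5, batch size 32, dropout 0.5
#' on the output layers.
#'
#' @param learning_rate Positive learning rate (default `1e-5`).
#' @param momentum SGD momentum in \[0, 1) (default 0.9).
#' @param batch_size Mini-batch size (default 32).
#' @param dropout_p Dropout probability in \[0, 1) (default 0.5).
#' @param epochs Number of training epochs (default 50).
#' @param loss `"mse"` (regression) or `"cross_entropy"` (classification).
#' @param seed Integer seed governing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, momentum = 0.9,
                         batch_size = 32L, dropout_p = 0.5, epochs = 50L,
                         loss = c("mse", "cross_entropy"), seed = 1L) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (momentum < 0 || momentum >= 1) abort("momentum must lie in [0, 1)")
  if (dropout_p < 0 || dropout_p >= 1) abort("dropout_p must lie in [0, 1)")
  if (batch_size < 1) abort("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size), dropout_p = dropout_p,
                 epochs = as.integer(epochs), loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a tone-estimation CNN
#'
#' Assembles the network described by an [architecture_spec()] with
#' deterministic (He-normal) weight initialisation given `seed`.
#'
#' @param arch An [architecture_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `monk_model` object.
#' @export
build_model <- function(arch, seed = 1L) {
  if (!inherits(arch, "architecture_spec")) {
    abort("arch must be an architecture_spec()")
  }
  withr::with_seed(as.integer(seed), {
    layers <- list()
    c_in <- arch$in_channels
    spatial <- arch$side
    if (arch$profile == "tiny" && spatial > 32L && spatial %% 2 == 0) {
      # stride-reducing stem: fixed 2x2 average pool keeps the tiny
      # profile's compute budget flat for 64 px inputs
      layers <- c(layers, list(nn_avgpool()))
      spatial <- spatial %/% 2L
    }
    conv_index <- 0L
    for (item in arch$plan$conv) {
      if (identical(item, "M")) {
        if (spatial %% 2 != 0) abort("input side not divisible by pooling")
        layers <- c(layers, list(nn_pool(2L)))
        spatial <- spatial %/% 2L
      } else {
        conv_index <- conv_index + 1L
        conv <- nn_conv(c_in, item)
        conv$conv_index <- conv_index
        bn <- nn_bn(item)
        bn$conv_index <- conv_index
        layers <- c(layers, list(conv, bn, nn_relu()))
        c_in <- item
      }
    }
    while (spatial > 4L && spatial %% 2 == 0) {
      layers <- c(layers, list(nn_pool(2L)))
      spatial <- spatial %/% 2L
    }
    layers <- c(layers, list(nn_flatten()))
    d_in <- spatial * spatial * c_in
    for (width in arch$plan$fc) {
      layers <- c(layers, list(nn_dense(d_in, width), nn_sigmoid(),
                               nn_dropout(arch$dropout_p)))
      d_in <- width
    }
    out_dim <- if (arch$head == "regression") 1L else 10L
    layers <- c(layers, list(nn_dense(d_in, out_dim, init_scale = 0.1)))
    if (arch$head == "classification") {
      layers <- c(layers, list(nn_softmax()))
    }
    structure(list(layers = layers, arch = arch, n_conv = conv_index),
              class = "monk_model")
  })
}

#' @export
print.monk_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) {
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }, numeric(1)))
  cat(sprintf("<monk_model> profile=%s head=%s in_channels=%d side=%d\n",
              x$arch$profile, x$arch$head, x$arch$in_channels, x$arch$side))
  cat(sprintf("  %d conv layers, %s parameters\n", x$n_conv,
              format(n_par, big.mark = ",")))
  invisible(x)
}

#' Mean squared error between estimate and target vectors
#'
#' The training loss for the regression head:
#' `(1/N) * sum((est - target)^2)`.
#'
#' @param estimates,targets Equal-length numeric vectors.
#' @return A single number.
#' @export
mse_loss <- function(estimates, targets) {
  if (length(estimates) != length(targets) || length(estimates) < 1) {
    abort("estimates and targets must be non-empty and of equal length")
  }
  mean((estimates - targets)^2)
}

#' Freeze the first feature-extraction layers of a model
#'
#' "Layers" are counted as the convolutional weight-bearing layers of the
#' feature extractor, in forward order; freezing a conv layer also freezes
#' its attached batch-norm parameters. Head (fully connected) layers are
#' always trainable.
#'
#' @param model A `monk_model`.
#' @param n_frozen Number of feature layers to freeze (0 to the model's
#'   conv layer count).
#' @return The model with `trainable` flags updated.
#' @export
freeze_layers <- function(model, n_frozen) {
  if (n_frozen < 0 || n_frozen > model$n_conv) {
    abort(sprintf("n_frozen must lie in [0, %d] for this model",
                  model$n_conv))
  }
  model$layers <- lapply(model$layers, function(layer) {
    if (!is.null(layer$conv_index)) {
      layer$trainable <- layer$conv_index > n_frozen
    }
    layer
  })
  model
}

n_trainable_tensors <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (!isTRUE(l$trainable)) return(0L)
    if (l$type == "bn") 2L else 2L
  }, integer(1)))
}

batch_loss_grad <- function(out, targets, loss) {
  if (loss == "mse") {
    est <- out[, 1]
    n <- length(est)
    list(loss = mean((est - targets)^2),
         dout = matrix(2 * (est - targets) / n, ncol = 1))
  } else {
    n <- nrow(out)
    y <- matrix(0, n, ncol(out))
    y[cbind(seq_len(n), targets)] <- 1
    p <- pmax(out, 1e-12)
    list(loss = -mean(log(p[cbind(seq_len(n), targets)])),
         dout = -(y / p) / n)
  }
}

class_targets <- function(y) {
  # continuous labels round half-up to integer tones 1..10 -> classes 1..10
  as.integer(clamp(floor(y + 0.5), 1, 10))
}

#' Train a tone-estimation model
#'
#' Mini-batch stochastic gradient descent with momentum. Each epoch the
#' training set is reshuffled; batch losses are aggregated into the epoch
#' loss, and threshold-0.5 accuracy is recorded on the training batches
#' and (in evaluation mode, dropout off and batch-norm running statistics)
#' on the validation set. All randomness is governed by `config$seed`.
#'
#' @param model A `monk_model` built with [build_model()].
#' @param train_data List with `x` (array `side x side x n x channels`,
#'   as from [prepare_tensors()]) and `y` (numeric tone targets).
#' @param val_data Optional list like `train_data`.
#' @param config A [train_config()]; `config$loss` must match the model
#'   head (`mse` for regression, `cross_entropy` for classification).
#' @return A `monk_fit` object: the trained `$model` and a `$history`
#'   tibble with one row per epoch (`epoch`, `loss`, `train_acc`,
#'   `val_acc`).
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = train_config()) {
  n <- dim(train_data$x)[3]
  if (is.null(n) || n < 1) abort("training split is empty")
  if (!is.null(val_data) && (dim(val_data$x)[3] %||% 0) < 1) {
    abort("validation split is empty")
  }
  expected_loss <- if (model$arch$head == "regression") "mse"
                   else "cross_entropy"
  if (config$loss != expected_loss) {
    abort(sprintf("loss '%s' does not match the %s head", config$loss,
                  model$arch$head))
  }
  model$layers <- lapply(model$layers, function(l) {
    if (l$type == "dropout") l$p <- config$dropout_p
    l
  })
  cls <- model$arch$head == "classification"
  y_train <- if (cls) class_targets(train_data$y) else train_data$y
  history <- vector("list", config$epochs)
  withr::with_seed(config$seed, {
    velocity <- nn_init_velocity(model)
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      batch_starts <- seq(1, n, by = config$batch_size)
      losses <- numeric(length(batch_starts))
      sizes <- numeric(length(batch_starts))
      correct <- 0
      for (b in seq_along(batch_starts)) {
        idx <- order_idx[batch_starts[b]:min(batch_starts[b] +
                                               config$batch_size - 1, n)]
        xb <- train_data$x[, , idx, , drop = FALSE]
        yb <- y_train[idx]
        fwd <- nn_forward(model, xb, training = TRUE)
        model <- fwd$model
        lg <- batch_loss_grad(fwd$out, yb, config$loss)
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d",
                        epoch))
        }
        losses[b] <- lg$loss
        sizes[b] <- length(idx)
        correct <- correct + if (cls) {
          sum(max.col(fwd$out, ties.method = "first") == yb)
        } else {
          sum(abs(fwd$out[, 1] - yb) <= 0.5)
        }
        grads <- nn_backward(model, fwd$caches, lg$dout)
        step <- nn_sgd_step(model, grads, velocity,
                            config$learning_rate, config$momentum)
        model <- step$model
        velocity <- step$velocity
      }
      val_acc <- NA_real_
      if (!is.null(val_data)) {
        val_est <- predict_tensor(model, val_data$x)
        val_acc <- if (cls) {
          100 * mean(max.col(val_est, ties.method = "first") ==
                       class_targets(val_data$y))
        } else {
          100 * mean(abs(clamp(val_est[, 1], 1, 10) - val_data$y) <= 0.5)
        }
      }
      history[[epoch]] <- tibble(
        epoch = epoch,
        loss = sum(losses * sizes) / sum(sizes),
        train_acc = 100 * correct / n,
        val_acc = val_acc
      )
    }
  })
  structure(list(model = model, config = config,
                 history = bind_rows(history)),
            class = "monk_fit")
}

predict_tensor <- function(model, x, batch_size = 128L) {
  n <- dim(x)[3]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- nn_forward(model, x[, , idx, , drop = FALSE], training = FALSE)
    out <- rbind(out, fwd$out)
  }
  out
}

#' Predict tone estimates from prepared tensors
#'
#' @param object A `monk_model` or `monk_fit`.
#' @param x Input tensor array (`side x side x n x channels`) or a
#'   `prepare_tensors()` list.
#' @param ... Unused.
#' @return For a regression head, a numeric vector of tone estimates
#'   clamped to \[1, 10\]; for a classification head, an `n x 10`
#'   probability matrix.
#' @export
predict.monk_model <- function(object, x, ...) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  out <- predict_tensor(object, x)
  if (object$arch$head == "regression") clamp(out[, 1], 1, 10) else out
}

#' @rdname predict.monk_model
#' @export
predict.monk_fit <- function(object, x, ...) {
  predict(object$model, x, ...)
}

#' @export
print.monk_fit <- function(x, ...) {
  cat(sprintf("<monk_fit> %d epochs", nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(": final loss %.4f, train acc %.1f%%", last$loss,
                last$train_acc))
    if (is.finite(last$val_acc)) cat(sprintf(", val acc %.1f%%", last$val_acc))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.monk_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.monk_fit <- function(x, ...) {
  if (nrow(x$history) == 0) {
    return(tibble(epochs = 0L, final_loss = NA_real_,
                  final_train_acc = NA_real_, final_val_acc = NA_real_))
  }
  last <- x$history[nrow(x$history), ]
  tibble(epochs = nrow(x$history), final_loss = last$loss,
         final_train_acc = last$train_acc, final_val_acc = last$val_acc)
}

#' Fine-tune a trained model on a single light type
#'
#' Freezes the whole feature extractor (all convolutional layers) and
#' continues training the head only, at a reduced learning rate, on
#' records that all share one light type.
#'
#' @param fit A `monk_fit` (or bare `monk_model`).
#' @param records Manifest records, all with the same `light_type`.
#' @param config A [train_config()]; its learning rate is divided by 10
#'   unless `learning_rate` is given (the protocol default reduces 1e-5 to
#'   1e-6).
#' @param spec [input_tensor_spec()] used to prepare tensors.
#' @param learning_rate Optional explicit fine-tuning learning rate.
#' @param val_records Optional held-out records for per-epoch validation.
#' @param ... Passed to [prepare_tensors()].
#' @return A `monk_fit`.
#' @export
fine_tune <- function(fit, records, config = train_config(),
                      spec = input_tensor_spec(), learning_rate = NULL,
                      val_records = NULL, ...) {
  model <- if (inherits(fit, "monk_fit")) fit$model else fit
  if (length(unique(records$light_type)) != 1) {
    abort("fine-tuning records must share a single light_type")
  }
  config$learning_rate <- learning_rate %||% (config$learning_rate / 10)
  model <- freeze_layers(model, model$n_conv)
  train_data <- prepare_tensors(records, spec, ...)
  val_data <- if (!is.null(val_records)) {
    prepare_tensors(val_records, spec, ...)
  }
  train_model(model, train_data, val_data, config)
}
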
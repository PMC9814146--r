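#' CNN configuration
#'
#' Architecture and training hyperparameters of the structure-retrieval
#' regressor. The default architecture follows the reference design: three
#' convolutional layers (32 filters of 5x5, then twice 32 of 3x3), batch
#' normalization, 2x2 max-pooling after each convolution block, a deep fully
#' connected stack, a batch size of 120, and more than 50 passes over the
#' training set.
#'
#' @param conv_layers List of `c(filters, kernel)` pairs.
#' @param fc_depth Number of hidden fully connected layers.
#' @param fc_width Neurons per hidden fully connected layer.
#' @param batch_size Mini-batch size.
#' @param learning_rate Step size `alpha` of the gradient-descent update.
#' @param epochs Number of full passes over the training split (the
#'   "iteration number").
#' @param batch_norm Use batch normalization?
#' @param optimizer `"sgd"` -- the plain rule `w <- w - alpha * dCost/dw` --
#'   or `"adam"`, an adaptive variant of the same gradient descent.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_layers = list(c(32, 5), c(32, 3), c(32, 3)),
                       fc_depth = 30L, fc_width = 64L,
                       batch_size = 120L, learning_rate = 1e-3,
                       epochs = 50L, batch_norm = TRUE,
                       optimizer = c("sgd", "adam"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(length(conv_layers) >= 1L, fc_depth >= 1L, fc_width >= 1L,
            batch_size >= 1L, learning_rate > 0, epochs >= 1L)
  for (cl in conv_layers) stopifnot(length(cl) == 2L, all(cl >= 1L))
  structure(list(conv_layers = conv_layers, fc_depth = as.integer(fc_depth),
                 fc_width = as.integer(fc_width),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_norm = isTRUE(batch_norm), optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Quadratic regression cost
#'
#' `mean over components of (y_pre - y_real)^2 / 2`: zero exactly when the
#' prediction equals the target, and the quantity whose gradient drives the
#' weight updates during training.
#'
#' @param y_pre,y_real Numeric vectors of equal length (predicted and real
#'   label values).
#' @return Non-negative scalar.
#' @export
cnn_cost <- function(y_pre, y_real) {
  if (length(y_pre) != length(y_real)) stop("label vectors differ in length")
  mean(0.5 * (y_pre - y_real)^2)
}

#' Gradient-descent weight update
#'
#' `w_new = w - alpha * gradient`: the new weight is the current weight
#' minus the learning rate times the partial derivative of the cost.
#'
#' @param w Current weight(s).
#' @param gradient Partial derivative of the cost with respect to `w`.
#' @param alpha Positive learning rate.
#' @return Updated weight(s).
#' @export
weight_update <- function(w, gradient, alpha) {
  if (alpha <= 0) stop("learning rate must be positive")
  w - alpha * gradient
}

#' Build an untrained CNN model
#'
#' Assembles convolution blocks (convolution, optional batch normalization,
#' rectifier, 2x2 max-pool) followed by a fully connected stack with a
#' linear output layer of the label dimension. Initialization is seeded
#' variance-scaled random normal, so identical seeds give identical weights.
#'
#' @param config A [cnn_config()].
#' @param input_shape `c(H, W)` pixel dimensions of the input difference
#'   maps.
#' @param n_labels Output (label-vector) dimension.
#' @return Object of class `cnn_model`.
#' @export
build_model <- function(config, input_shape, n_labels) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 2L,
            n_labels >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  shape <- c(as.integer(input_shape), 1L)
  layers <- list()
  for (cl in config$conv_layers) {
    blk <- layer_conv_block(shape, filters = cl[1L], kernel = cl[2L],
                            use_bn = config$batch_norm)
    layers <- c(layers, list(blk))
    shape <- blk$out_shape
  }
  width <- prod(shape)
  for (d in seq_len(config$fc_depth)) {
    layers <- c(layers, list(layer_dense(width, config$fc_width)))
    if (config$batch_norm) {
      layers <- c(layers, list(layer_bn(config$fc_width, 1L)))
    }
    layers <- c(layers, list(layer_relu(config$fc_width)))
    width <- config$fc_width
  }
  layers <- c(layers, list(layer_dense(width, as.integer(n_labels))))
  structure(list(layers = layers, config = config,
                 input_shape = as.integer(input_shape),
                 n_labels = as.integer(n_labels),
                 label_stats = NULL, trained_epochs = 0L),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) sum(lengths(l$params)), numeric(1)))
  cat(sprintf("<cnn_model> %dx%d -> %d label(s), %d layer(s), %d parameters%s\n",
              x$input_shape[1L], x$input_shape[2L], x$n_labels,
              length(x$layers), np,
              if (x$trained_epochs > 0L) {
                sprintf(", trained %d epoch(s)", x$trained_epochs)
              } else " (untrained)"))
  invisible(x)
}

# Min-max label scaling to [0, 1] per dimension using training-split
# statistics; mixed-unit labels (distances and angles) become commensurate.
scale_labels <- function(labels, stats) {
  rng <- pmax(stats$max - stats$min, 1e-12)
  sweep(sweep(labels, 2L, stats$min), 2L, rng, "/")
}

unscale_labels <- function(scaled, stats) {
  rng <- pmax(stats$max - stats$min, 1e-12)
  sweep(sweep(scaled, 2L, rng, "*"), 2L, -stats$min)
}

# One optimizer step over every parameter of every layer.
optimizer_step <- function(layers, grads, state, config, iter) {
  lr <- config$learning_rate
  for (l in seq_along(layers)) {
    for (nm in names(grads[[l]])) {
      g <- grads[[l]][[nm]]
      if (config$optimizer == "sgd") {
        layers[[l]]$params[[nm]] <- weight_update(layers[[l]]$params[[nm]], g, lr)
      } else {  # adam
        st <- state[[l]][[nm]]
        if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
        st$m <- 0.9 * st$m + 0.1 * g
        st$v <- 0.999 * st$v + 0.001 * g * g
        mhat <- st$m / (1 - 0.9^iter)
        vhat <- st$v / (1 - 0.999^iter)
        layers[[l]]$params[[nm]] <- layers[[l]]$params[[nm]] -
          lr * mhat / (sqrt(vhat) + 1e-8)
        state[[l]][[nm]] <- st
      }
    }
  }
  list(layers = layers, state = state)
}

# Forward pass in inference mode, batched to bound memory.
model_forward_inference <- function(model, X, chunk = 512L) {
  n <- ncol(X)
  out <- matrix(0, model$n_labels, n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[, s:e] <- nn_forward(model$layers, X[, s:e, drop = FALSE],
                             training = FALSE)$out
  }
  out
}

#' Train the CNN on a prepared dataset
#'
#' Minimizes the batch-mean quadratic cost by mini-batch gradient descent.
#' Labels are min-max scaled internally with training-split statistics and
#' unscaled on output; the per-epoch mean absolute error (MAE) is reported
#' in physical label units (Angstrom / degrees) for the training split (as
#' the running average over the epoch's mini-batches) and the validation
#' split (full forward pass after each epoch).
#'
#' @param model An untrained or previously trained [build_model()] result.
#' @param dataset A [assemble_dataset()] result with non-empty train and
#'   validation splits.
#' @param config Optional [cnn_config()] overriding the model's stored one.
#' @param verbose Print the MAE every `verbose` epochs (0 = silent).
#' @return List with `model` (trained `cnn_model`) and `report` (class
#'   `train_report`): per-epoch train/validation MAE history, final
#'   test-split MAE, seed and config snapshot. Reruns with identical seed
#'   and data give identical reports.
#' @export
train_cnn <- function(model, dataset, config = model$config, verbose = 0L) {
  stopifnot(inherits(model, "cnn_model"), inherits(dataset, "dcs_dataset"))
  if (length(dataset$splits$train) == 0L ||
      length(dataset$splits$validation) == 0L) {
    stop("train and validation splits must be non-empty")
  }
  model$label_stats <- dataset$label_stats
  y_all <- t(scale_labels(dataset$labels, model$label_stats))  # d x n
  tr <- dataset$splits$train; va <- dataset$splits$validation
  rng <- pmax(model$label_stats$max - model$label_stats$min, 1e-12)
  d <- model$n_labels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  state <- rep(list(list()), length(model$layers))
  hist_train <- hist_val <- numeric(config$epochs)
  iter <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- tr[sample.int(length(tr))]
    abs_err_sum <- 0; n_seen <- 0L
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      X <- dataset$inputs[, b, drop = FALSE]
      Yt <- y_all[, b, drop = FALSE]
      fw <- nn_forward(model$layers, X, training = TRUE)
      model$layers <- fw$layers
      resid <- fw$out - Yt
      cost <- mean(0.5 * resid^2)
      if (!is.finite(cost)) {
        stop(sprintf("training diverged at epoch %d (non-finite cost)", epoch))
      }
      # batch-mean cost gradient: d Cost / d y_pre
      bw <- nn_backward(model$layers, fw$caches, resid / length(resid))
      iter <- iter + 1L
      stp <- optimizer_step(model$layers, bw$grads, state, config, iter)
      model$layers <- stp$layers; state <- stp$state
      abs_err_sum <- abs_err_sum + sum(abs(resid) * rng)
      n_seen <- n_seen + length(b)
    }
    hist_train[epoch] <- abs_err_sum / (n_seen * d)
    pv <- model_forward_inference(model, dataset$inputs[, va, drop = FALSE])
    hist_val[epoch] <- mean(abs(pv - y_all[, va, drop = FALSE]) * rng)
    if (verbose > 0L && epoch %% verbose == 0L) {
      message(sprintf("epoch %3d  train MAE %.5f  val MAE %.5f",
                      epoch, hist_train[epoch], hist_val[epoch]))
    }
  }
  model$trained_epochs <- model$trained_epochs + config$epochs
  te <- dataset$splits$test
  test_mae <- NA_real_
  test_mae_dim <- rep(NA_real_, d)
  if (length(te) > 0L) {
    pt <- model_forward_inference(model, dataset$inputs[, te, drop = FALSE])
    err <- abs(pt - y_all[, te, drop = FALSE]) * rng
    test_mae <- mean(err)
    test_mae_dim <- rowMeans(err)
  }
  report <- structure(
    list(history = data.frame(epoch = seq_len(config$epochs),
                              train_mae = hist_train, val_mae = hist_val),
         test_mae = test_mae, test_mae_dim = test_mae_dim,
         seed = config$seed, config = config),
    class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(paste0("<train_report> %d epoch(s); final train MAE %.5f, ",
                     "val MAE %.5f, test MAE %.5f\n"),
              n, x$history$train_mae[n], x$history$val_mae[n], x$test_mae))
  invisible(x)
}

#' Export a training report history as CSV
#' @param report A `train_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_train_report <- function(report, path) {
  stopifnot(inherits(report, "train_report"))
  utils::write.csv(report$history, path, row.names = FALSE)
  invisible(path)
}

#' Predict structure labels from a difference map
#'
#' @param object A trained `cnn_model`.
#' @param input A `dcs_diff`, a matrix of the model's input shape, a
#'   flattened pixel vector, or a pixels-x-n matrix of several inputs.
#' @param ... Unused.
#' @return Numeric label vector in physical units (or an n x d matrix for
#'   several inputs). Deterministic for fixed weights.
#' @export
predict.cnn_model <- function(object, input, ...) {
  if (is.null(object$label_stats)) stop("model has not been trained")
  npx <- prod(object$input_shape)
  X <- if (inherits(input, "dcs_diff")) as.vector(input$values)
       else if (is.matrix(input) && all(dim(input) == object$input_shape)) {
         as.vector(input)
       } else input
  X <- as.matrix(X)
  if (nrow(X) != npx) {
    stop(sprintf("input has %d pixels; model expects %d", nrow(X), npx))
  }
  out <- model_forward_inference(object, X)
  phys <- unscale_labels(t(out), object$label_stats)
  if (ncol(X) == 1L) as.vector(phys) else phys
}

#' Save / load a trained model
#'
#' Serializes the full model state (weights, filter banks, batch-norm
#' running statistics, label scaling, config snapshot); reloading gives
#' bit-identical predictions.
#'
#' @param model A `cnn_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cnn_model"))
  model
}
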
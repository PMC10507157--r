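# A small fully connected softmax network, written out explicitly so the
# forward pass and backpropagated gradients are inspectable and testable
# against finite differences. Architecture fixed by the task: 12 inputs, one
# hidden layer of 6 units, 6 softmax outputs.

#' Training configuration for the softmax network
#'
#' Full-batch gradient descent on mean categorical cross-entropy with a fixed
#' learning rate. The hidden activation defaults to the logistic sigmoid; the
#' output layer is always softmax.
#'
#' @param learning_rate Step size (default 0.5).
#' @param epochs Number of full-batch updates (default 5000).
#' @param seed Seed for weight initialization and the train/test split.
#' @param hidden_activation `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param features_normalized Whether inputs are band-normalized positions.
#' @param standardize Z-score inputs using training-set statistics (stored in
#'   the model and reapplied at prediction time). Helps because band-relative
#'   positions occupy a narrow slice of `[0, 1]`.
#' @param train_size Training-set size for [split_features()] (default 540).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.5, epochs = 5000, seed = 1,
                         hidden_activation = c("sigmoid", "tanh", "relu"),
                         features_normalized = TRUE, standardize = TRUE,
                         train_size = 540) {
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (epochs < 0) abort("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = epochs, seed = seed,
                 hidden_activation = match.arg(hidden_activation),
                 features_normalized = features_normalized,
                 standardize = standardize, train_size = train_size),
            class = "train_config")
}

#' Initialize network parameters
#'
#' Glorot-style uniform initialization: weights drawn from
#' \eqn{U(-\sqrt{6/(fan_{in}+fan_{out})}, +\sqrt{6/(fan_{in}+fan_{out})})},
#' biases zero.
#'
#' @param seed Integer seed.
#' @param n_in,n_hidden,n_out Layer sizes (default 12, 6, 6).
#' @return An `mlp_params` list with `W1` (n_in x n_hidden), `b1`, `W2`
#'   (n_hidden x n_out), `b2`.
#' @export
mlp_init <- function(seed = 1, n_in = 12, n_hidden = 6, n_out = 6) {
  set.seed(seed)
  lim1 <- sqrt(6 / (n_in + n_hidden))
  lim2 <- sqrt(6 / (n_hidden + n_out))
  structure(list(
    W1 = matrix(runif(n_in * n_hidden, -lim1, lim1), n_in, n_hidden),
    b1 = rep(0, n_hidden),
    W2 = matrix(runif(n_hidden * n_out, -lim2, lim2), n_hidden, n_out),
    b2 = rep(0, n_out)
  ), class = "mlp_params")
}

activation_fun <- function(name) {
  switch(name,
         sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                        df = function(a, z) a * (1 - a)),
         tanh = list(f = tanh, df = function(a, z) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a, z) (z > 0) * 1),
         abort(paste0("unknown activation: ", name)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass
#'
#' `hidden = act(X W1 + b1)`, `probs = softmax(hidden W2 + b2)` with
#' max-subtracted softmax for numerical stability. Probabilities in each row
#' sum to one.
#'
#' @param params An `mlp_params`.
#' @param x Numeric matrix `n x 12` (or a single 12-vector).
#' @param activation Hidden activation name.
#' @return Matrix `n x 6` of class probabilities.
#' @export
mlp_forward <- function(params, x, activation = "sigmoid") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) abort("non-finite features")
  act <- activation_fun(activation)
  z1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  h <- act$f(z1)
  z2 <- sweep(h %*% params$W2, 2, params$b2, "+")
  softmax_rows(z2)
}

# Mean cross-entropy loss and backpropagated gradients for a batch.
# Returns list(loss, grads = list(W1, b1, W2, b2)).
mlp_loss_grads <- function(params, x, y_onehot, activation = "sigmoid") {
  n <- nrow(x)
  act <- activation_fun(activation)
  z1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  h <- act$f(z1)
  z2 <- sweep(h %*% params$W2, 2, params$b2, "+")
  p <- softmax_rows(z2)
  loss <- -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
  dz2 <- (p - y_onehot) / n
  gW2 <- t(h) %*% dz2
  gb2 <- colSums(dz2)
  dh <- dz2 %*% t(params$W2)
  dz1 <- dh * act$df(h, z1)
  gW1 <- t(x) %*% dz1
  gb1 <- colSums(dz1)
  list(loss = loss, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

onehot <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    abort(paste0("unknown label(s): ",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")))
  }
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(idx), idx)] <- 1
  y
}

#' Stratified train/test split of a feature table
#'
#' Splits per class with largest-remainder rounding so per-class training
#' proportions match the overall `train_size / n` as closely as possible;
#' train and test are disjoint and their union is the input.
#'
#' @param features Wide feature table (from [featurize_spectra()]) with a
#'   `label` column.
#' @param train_size Total training rows (default 540).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_features <- function(features, train_size = 540, seed = 1) {
  n <- nrow(features)
  if (train_size >= n) abort("train_size must be < number of samples")
  if (train_size < 1) abort("train_size must be >= 1")
  labs <- features$label
  classes <- unique(labs)
  n_c <- vapply(classes, function(cl) sum(labs == cl), numeric(1))
  exact <- train_size * n_c / n
  base <- floor(exact)
  rem <- train_size - sum(base)
  if (rem > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  set.seed(seed)
  train_idx <- unlist(lapply(seq_along(classes), function(k) {
    idx <- which(labs == classes[k])
    sample(idx, base[k])
  }))
  train_idx <- sort(train_idx)
  list(train = features[train_idx, , drop = FALSE],
       test = features[-train_idx, , drop = FALSE])
}

#' Train the 12-6-6 softmax network
#'
#' Deterministic full-batch gradient descent on mean categorical
#' cross-entropy, gradients by backpropagation. With `epochs = 0` the
#' returned parameters equal the initialization.
#'
#' @param features Wide feature table with `label` and `f01`..`f12` columns
#'   (the training portion).
#' @param config A [train_config()].
#' @param classes Class order for the one-hot encoding.
#' @return A `sers_mlp` model: `params`, `loss_history` (one mean
#'   cross-entropy per epoch), `config`, `classes`, standardization
#'   statistics. Supports [predict()], [tidy()], [glance()].
#' @export
mlp_train <- function(features, config = train_config(),
                      classes = aldehyde_classes()) {
  fcols <- feature_columns(features)
  x <- as.matrix(features[, fcols])
  present <- intersect(classes, unique(features$label))
  missing_cl <- setdiff(classes, present)
  if (length(missing_cl) > 0) {
    abort(paste0("class absent from training set: ",
                 paste(missing_cl, collapse = ", ")))
  }
  y <- onehot(features$label, classes)
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (isTRUE(config$standardize)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  params <- mlp_init(config$seed, ncol(x), 6, length(classes))
  loss_history <- numeric(config$epochs)
  lr <- config$learning_rate
  for (e in seq_len(config$epochs)) {
    lg <- mlp_loss_grads(params, xs, y, config$hidden_activation)
    if (!is.finite(lg$loss)) {
      abort(paste0("non-finite loss at epoch ", e, "; lower the learning rate"))
    }
    loss_history[e] <- lg$loss
    params$W1 <- params$W1 - lr * lg$grads$W1
    params$b1 <- params$b1 - lr * lg$grads$b1
    params$W2 <- params$W2 - lr * lg$grads$W2
    params$b2 <- params$b2 - lr * lg$grads$b2
  }
  structure(list(params = params, loss_history = loss_history,
                 config = config, classes = classes,
                 center = center, scale = scale, feature_names = fcols),
            class = "sers_mlp")
}

#' @export
print.sers_mlp <- function(x, ...) {
  cat("Fully connected softmax network 12 -> 6 -> 6\n")
  cat(sprintf("  %d epochs, learning rate %g, hidden %s\n",
              x$config$epochs, x$config$learning_rate,
              x$config$hidden_activation))
  if (length(x$loss_history) > 0) {
    cat(sprintf("  cross-entropy %.4f -> %.4f\n",
                x$loss_history[1], tail(x$loss_history, 1)))
  }
  invisible(x)
}

#' Predict classes or probabilities
#'
#' @param object A `sers_mlp`.
#' @param new_data Wide feature table (columns `f01`..`f12`).
#' @param type `"class"` (argmax, ties to the lowest class index) or
#'   `"prob"`.
#' @param ... Unused.
#' @return For `"class"`, a character vector; for `"prob"`, an `n x 6`
#'   probability matrix with class-named columns.
#' @export
predict.sers_mlp <- function(object, new_data, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  x <- as.matrix(new_data[, object$feature_names])
  xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  p <- mlp_forward(object$params, xs, object$config$hidden_activation)
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[apply(p, 1, which.max)]
}
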
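# The baseline dTm predictor: a single-hidden-layer feed-forward network
# (19 inputs -> 64 rectified hidden units -> 1 linear output) trained by
# full-batch Adam on mean-square error, with early stopping driven by a
# held-out validation set and restoration of the best-validation weights.
# Written in plain R matrix code: the model is small enough that
# vectorized full-batch gradients are fast, exactly reproducible, and
# dependency-free.

#' Network training configuration
#'
#' @param hidden_units Hidden-layer width (default 64).
#' @param activation Hidden activation, `"relu"` (rectifier; default) or
#'   `"tanh"`. The output is always linear.
#' @param max_epochs Maximum training epochs (default 2000).
#' @param early_stop_patience Epochs without validation-MSE improvement
#'   before stopping (default 50).
#' @param learning_rate Adam step size (default 0.01, tuned for full-batch
#'   gradients on z-scored inputs).
#' @param batch_size Minibatch size; `NULL` (default) trains full-batch.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `net_config`.
#' @export
net_config <- function(hidden_units = 64, activation = c("relu", "tanh"),
                       max_epochs = 2000, early_stop_patience = 50,
                       learning_rate = 0.01, batch_size = NULL, seed = 1) {
  activation <- match.arg(activation)
  stopifnot(hidden_units >= 1, early_stop_patience >= 1, max_epochs >= 1,
            learning_rate > 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 learning_rate = learning_rate,
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "net_config")
}

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         tanh = list(f = tanh,
                     df = function(z, a) 1 - a^2))
}

mlp_forward <- function(w, X, activation) {
  act <- act_fun(activation)
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  A1 <- act$f(Z1)
  drop(A1 %*% w$W2 + w$b2)
}

# Full training loop. X*, y* are already normalized/raw numeric.
train_mlp <- function(Xtr, ytr, Xval, yval, cfg) {
  set.seed(cfg$seed)
  n_in <- ncol(Xtr); n_h <- cfg$hidden_units
  act <- act_fun(cfg$activation)
  w <- list(W1 = matrix(stats::rnorm(n_in * n_h, sd = sqrt(2 / n_in)),
                        n_in, n_h),
            b1 = rep(0, n_h),
            W2 = matrix(stats::rnorm(n_h, sd = sqrt(1 / n_h)), n_h, 1),
            b2 = 0)
  adam <- list(m = lapply(w, function(p) p * 0),
               v = lapply(w, function(p) p * 0))
  b1 <- 0.9; b2m <- 0.999; eps <- 1e-8; t <- 0
  n <- nrow(Xtr)
  batch <- if (is.null(cfg$batch_size)) n else min(cfg$batch_size, n)

  val_mse <- function(w) mean((mlp_forward(w, Xval, cfg$activation) - yval)^2)
  best <- list(w = w, mse = val_mse(w), epoch = 0L)
  history <- matrix(NA_real_, cfg$max_epochs, 2,
                    dimnames = list(NULL, c("train_mse", "val_mse")))
  wait <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    idx_all <- if (batch < n) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = batch)
    for (s in starts) {
      idx <- idx_all[s:min(s + batch - 1, n)]
      X <- Xtr[idx, , drop = FALSE]; y <- ytr[idx]
      m <- length(idx)
      Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
      A1 <- act$f(Z1)
      yhat <- drop(A1 %*% w$W2 + w$b2)
      d_out <- matrix(2 * (yhat - y) / m, ncol = 1)
      g <- list(W2 = crossprod(A1, d_out),
                b2 = sum(d_out))
      dA1 <- d_out %*% t(w$W2) * act$df(Z1, A1)
      g$W1 <- crossprod(X, dA1)
      g$b1 <- colSums(dA1)
      t <- t + 1
      for (p in names(w)) {
        adam$m[[p]] <- b1 * adam$m[[p]] + (1 - b1) * g[[p]]
        adam$v[[p]] <- b2m * adam$v[[p]] + (1 - b2m) * g[[p]]^2
        mhat <- adam$m[[p]] / (1 - b1^t)
        vhat <- adam$v[[p]] / (1 - b2m^t)
        w[[p]] <- w[[p]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    tr_mse <- mean((mlp_forward(w, Xtr, cfg$activation) - ytr)^2)
    v_mse <- val_mse(w)
    if (!is.finite(tr_mse) || !is.finite(v_mse)) {
      stop("non-finite loss at epoch ", epoch,
           " (train ", tr_mse, ", val ", v_mse,
           "); consider lowering learning_rate", call. = FALSE)
    }
    history[epoch, ] <- c(tr_mse, v_mse)
    if (v_mse < best$mse) {
      best <- list(w = w, mse = v_mse, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  list(weights = best$w, best_epoch = best$epoch,
       history = history[seq_len(epoch), , drop = FALSE])
}

#' Train the baseline dTm network
#'
#' Featurizes the training and validation datasets, fits the input
#' normalizer on the training features, and trains the
#' 19 -> `hidden_units` -> 1 network on mean-square error with
#' validation-driven early stopping. The returned model carries the
#' weights from the best-validation epoch together with its normalizer,
#' so prediction is a pure function of (weights, normalizer, input).
#'
#' @param train,validation Annotated, non-empty `mutation_dataset`s.
#' @param cfg A [net_config()].
#' @param table Property table used to featurize.
#' @return Object of class `tm_baseline`: list with `weights` (`W1`, `b1`,
#'   `W2`, `b2`), `normalizer`, `config`, `history` (per-epoch train and
#'   validation MSE), `best_epoch`, `property_table`.
#' @export
train_baseline <- function(train, validation, cfg = net_config(),
                           table = default_property_table()) {
  if (nrow(train) == 0 || nrow(validation) == 0) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  Xtr_raw <- featurize_dataset(train, table)
  Xval_raw <- featurize_dataset(validation, table)
  norm <- fit_normalizer(Xtr_raw)
  fit <- train_mlp(apply_normalizer(norm, Xtr_raw), train$d_tm,
                   apply_normalizer(norm, Xval_raw), validation$d_tm, cfg)
  structure(list(weights = fit$weights, normalizer = norm, config = cfg,
                 history = fit$history, best_epoch = fit$best_epoch,
                 property_table = table),
            class = "tm_baseline")
}

#' Predict dTm with a trained baseline network
#'
#' @param object A `tm_baseline`.
#' @param newdata An annotated `mutation_dataset`, or a raw (unnormalized)
#'   19-column feature matrix as produced by [encode_mutation()].
#' @param ... Unused.
#' @return Numeric vector of predicted dTm, degrees C, one per entry.
#' @export
predict.tm_baseline <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else featurize_dataset(newdata, object$property_table)
  Xn <- apply_normalizer(object$normalizer, X)
  mlp_forward(object$weights, Xn, object$config$activation)
}

#' @export
print.tm_baseline <- function(x, ...) {
  cat(sprintf("baseline dTm network: %d -> %d -> 1 (%s), best epoch %d\n",
              nrow(x$weights$W1), ncol(x$weights$W1), x$config$activation,
              x$best_epoch))
  invisible(x)
}

#' Serialize / restore a trained baseline model as JSON
#'
#' The container holds the weight matrices as nested arrays, the
#' normalizer statistics, and the training configuration, making models
#' portable across implementations.
#'
#' @param model A `tm_baseline`.
#' @param path Output path.
#' @return `path` (write) or a `tm_baseline` (read).
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    weights = lapply(model$weights, function(p) unname(as.matrix(p))),
    normalizer = list(center = unname(model$normalizer$center),
                      scale = unname(model$normalizer$scale),
                      excluded = model$normalizer$excluded,
                      degenerate = model$normalizer$degenerate),
    config = unclass(model$config),
    best_epoch = model$best_epoch,
    property_table = list(values = unname(model$property_table),
                          aa = rownames(model$property_table),
                          scales = colnames(model$property_table)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tbl <- p$property_table$values
  dimnames(tbl) <- list(p$property_table$aa, p$property_table$scales)
  cfg <- do.call(net_config, p$config[c("hidden_units", "activation",
                                        "max_epochs", "early_stop_patience",
                                        "learning_rate", "seed")])
  norm <- structure(list(center = stats::setNames(p$normalizer$center,
                                                  FEATURE_NAMES),
                         scale = stats::setNames(p$normalizer$scale,
                                                 FEATURE_NAMES),
                         excluded = p$normalizer$excluded,
                         degenerate = p$normalizer$degenerate %||% integer()),
                    class = "tm_normalizer")
  structure(list(weights = list(W1 = p$weights$W1,
                                b1 = drop(p$weights$b1),
                                W2 = matrix(p$weights$W2, ncol = 1),
                                b2 = drop(p$weights$b2)),
                 normalizer = norm, config = cfg, history = NULL,
                 best_epoch = p$best_epoch, property_table = tbl),
            class = "tm_baseline")
}
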
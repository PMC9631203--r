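# The wrapper's internal classifier: a single-hidden-layer perceptron with
# logistic activations throughout, trained by full-batch gradient descent on
# mean squared error. Deliberately small and deterministic — the particle
# swarm calls it thousands of times, so reproducibility and speed matter
# more than squeezing out the last point of accuracy.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Configuration for the wrapper's MLP scorer
#'
#' @param hidden_size Hidden units `m` (default 10).
#' @param learning_rate Full-batch gradient-descent step (default 0.1).
#' @param epochs Maximum epochs (default 300).
#' @param tol Early stop when the loss improvement drops below this.
#' @param standardize Standardize features (training statistics) before
#'   training; applied to new data at prediction time.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_size = 10, learning_rate = 0.1, epochs = 300,
                       tol = 1e-6, standardize = TRUE) {
  stopifnot(hidden_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 tol = tol, standardize = standardize),
            class = "mlp_config")
}

#' Train the single-hidden-layer perceptron
#'
#' The network maps a feature vector through one logistic hidden layer to a
#' logistic output unit, so predicted probabilities lie strictly in (0, 1).
#' Weights are initialized uniform(-0.5, 0.5) from `seed`; training is
#' full-batch gradient descent on MSE, which makes the fit a pure function
#' of (data, config, seed).
#'
#' @param X Numeric matrix (samples x features) or expression tibble.
#' @param y Binary 0/1 labels (taken from a `label` column when `NULL`).
#' @param genes Optional gene subset when `X` is an expression tibble.
#' @param config An [mlp_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mlp_model`: weights, standardization statistics, and training
#'   metadata (`epochs_run`, `loss_history`).
#' @export
mlp_train <- function(X, y = NULL, genes = NULL, config = mlp_config(), seed = 1) {
  x <- expr_matrix(X, genes)
  y <- expr_labels(X, y)
  if (ncol(x) < 1) stop("empty feature subset", call. = FALSE)
  if (length(y) != nrow(x)) stop("label length must match sample count", call. = FALSE)
  check_two_classes(y)

  if (config$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(x))
    scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")

  n <- nrow(xs)
  p <- ncol(xs)
  m <- config$hidden_size
  init <- withr::with_seed(seed, {
    list(W1 = matrix(runif(p * m, -0.5, 0.5), p, m),
         b1 = runif(m, -0.5, 0.5),
         w2 = matrix(runif(m, -0.5, 0.5), m, 1),
         b2 = runif(1, -0.5, 0.5))
  })
  W1 <- init$W1; b1 <- init$b1; w2 <- init$w2; b2 <- init$b2

  lr <- config$learning_rate
  loss_hist <- numeric(config$epochs)
  prev <- Inf
  epochs_run <- 0L
  for (e in seq_len(config$epochs)) {
    H <- sigmoid(xs %*% W1 + matrix(b1, n, m, byrow = TRUE))
    yhat <- as.vector(sigmoid(H %*% w2 + b2))
    loss <- mean((yhat - y)^2)
    loss_hist[e] <- loss
    epochs_run <- e
    if (prev - loss < config$tol && e > 1) break
    prev <- loss
    d <- (2 / n) * (yhat - y) * yhat * (1 - yhat)   # dLoss/d(output pre-act)
    gw2 <- t(H) %*% d
    gb2 <- sum(d)
    dH <- (d %*% t(w2)) * H * (1 - H)
    gW1 <- t(xs) %*% dH
    gb1 <- colSums(dH)
    W1 <- W1 - lr * gW1
    b1 <- b1 - lr * gb1
    w2 <- w2 - lr * gw2
    b2 <- b2 - lr * gb2
  }

  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 center = ctr, scale = scl,
                 features = colnames(x),
                 config = config, seed = seed,
                 epochs_run = epochs_run,
                 loss_history = loss_hist[seq_len(epochs_run)]),
            class = "mlp_model")
}

#' Predict probabilities and labels from a trained perceptron
#'
#' @param model An `mlp_model` from [mlp_train()].
#' @param X New data: matrix or expression tibble with the model's features.
#' @return A tibble with `prob` (strictly in (0, 1)) and `label`
#'   (1 iff `prob >= 0.5`).
#' @export
mlp_predict <- function(model, X) {
  x <- expr_matrix(X, if (is.data.frame(X)) model$features else NULL)
  if (ncol(x) != nrow(model$W1)) {
    stop("feature dimension mismatch: model expects ", nrow(model$W1),
         ", got ", ncol(x), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  H <- sigmoid(xs %*% model$W1 + matrix(model$b1, nrow(xs), ncol(model$W1), byrow = TRUE))
  prob <- as.vector(sigmoid(H %*% model$w2 + model$b2))
  tibble::tibble(prob = prob, label = as.integer(prob >= 0.5))
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> ", nrow(x$W1), " inputs -> ", ncol(x$W1),
      " hidden -> 1 output; trained ", x$epochs_run, " epochs, final MSE ",
      signif(x$loss_history[x$epochs_run], 4), "\n", sep = "")
  invisible(x)
}

#' @rdname mlp_train
#' @param x An `mlp_model`.
#' @param ... Unused.
#' @method glance mlp_model
#' @export
glance.mlp_model <- function(x, ...) {
  tibble::tibble(hidden_size = ncol(x$W1),
                 epochs_run = x$epochs_run,
                 final_loss = x$loss_history[x$epochs_run])
}
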
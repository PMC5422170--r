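#' Hidden-layer size rule
#'
#' The hidden-node count of the one-hidden-layer network is the sum of the
#' input and output node counts plus a small offset `k` in `{-2, 0, 2}`.
#' With 7 features and 3 varieties this gives 8, 10 or 12 hidden nodes.
#'
#' @param n_i Number of input nodes.
#' @param n_o Number of output nodes.
#' @param k Offset, one of `-2`, `0`, `2`.
#' @return Integer hidden-node count.
#' @examples
#' hidden_nodes(7, 3, 0)
#' @export
hidden_nodes <- function(n_i, n_o, k = 0) {
  stopifnot(n_i >= 1, n_o >= 1)
  if (!k %in% c(-2, 0, 2)) stop("k must be one of -2, 0, 2", call. = FALSE)
  n_h <- as.integer(n_i + n_o + k)
  if (n_h < 1L) stop("hidden-node count must be at least 1", call. = FALSE)
  n_h
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Train the backpropagation neural-network classifier
#'
#' Fits a one-hidden-layer feedforward network to labelled seven-feature
#' seed descriptors by online (per-sample) gradient descent on squared
#' error, with logistic sigmoid activations, one-hot targets, and weight
#' initialisation uniform in `[-0.5, 0.5]`. Features are min–max normalized
#' to `[0, 1]` against the training table and the ranges are stored in the
#' model, so prediction accepts raw feature values. Training stops when the
#' epoch-mean squared error (over samples and output nodes) falls below
#' `tolerance`; if `max_epochs` is reached first the model is returned with
#' `converged = FALSE` and a warning.
#'
#' @param data Data frame with the [seed_feature_names] columns and a label
#'   column.
#' @param label_col Name of the label column (default `"label"`).
#' @param k Hidden-size offset passed to [hidden_nodes()]; ignored when
#'   `hidden` is given.
#' @param hidden Explicit hidden-node count (overrides `k`).
#' @param learning_rate Online learning rate (default 0.01).
#' @param tolerance MSE below which training is complete (default 0.01).
#' @param max_epochs Epoch cap (default 10000).
#' @param seed RNG seed controlling weight initialisation and the fixed
#'   sample order; fixed seed and data give a bitwise-identical model.
#' @param activation `"logistic"` (default) on both layers, or `"tanh"` on
#'   the hidden layer (output stays logistic, matching the 0/1 targets).
#' @return A `bpnn` model object.
#' @examples
#' pop <- sample_population(default_varieties(), n = 20, rng_seed = 1)
#' fit <- train_bpnn(pop, max_epochs = 50)
#' glance(fit)
#' @export
train_bpnn <- function(data, label_col = "label", k = 0, hidden = NULL,
                       learning_rate = 0.01, tolerance = 0.01,
                       max_epochs = 10000L, seed = 1L,
                       activation = c("logistic", "tanh")) {
  activation <- match.arg(activation)
  stopifnot(learning_rate > 0, tolerance > 0)
  if (!label_col %in% names(data)) stop("no label column '", label_col, "'", call. = FALSE)
  labels <- factor(data[[label_col]])
  if (any(table(labels) < 1L)) stop("need at least one sample per class", call. = FALSE)
  ranges <- fit_normalization(data)
  X <- as.matrix(apply_normalization(data, ranges)[seed_feature_names])
  if (any(!is.finite(X))) stop("non-finite inputs", call. = FALSE)
  n <- nrow(X); n_i <- ncol(X); n_o <- nlevels(labels)
  n_h <- if (is.null(hidden)) hidden_nodes(n_i, n_o, k) else as.integer(hidden)
  Tmat <- matrix(0, n, n_o)
  Tmat[cbind(seq_len(n), as.integer(labels))] <- 1
  init <- with_seed(seed, {
    list(W1 = matrix(stats::runif(n_h * n_i, -0.5, 0.5), n_h, n_i),
         b1 = stats::runif(n_h, -0.5, 0.5),
         W2 = matrix(stats::runif(n_o * n_h, -0.5, 0.5), n_o, n_h),
         b2 = stats::runif(n_o, -0.5, 0.5),
         order = sample.int(n))
  })
  fit <- bpnn_train_cpp(X, Tmat, init$W1, init$b1, init$W2, init$b2,
                        init$order, learning_rate, tolerance,
                        as.integer(max_epochs),
                        if (activation == "tanh") 1L else 0L)
  if (!fit$converged)
    warning("training did not reach tolerance ", tolerance, " within ",
            max_epochs, " epochs (final MSE ",
            signif(fit$mse[length(fit$mse)], 4), ")", call. = FALSE)
  structure(list(
    W1 = fit$W1, b1 = as.numeric(fit$b1),
    W2 = fit$W2, b2 = as.numeric(fit$b2),
    n_i = n_i, n_h = n_h, n_o = n_o,
    labels = levels(labels), ranges = ranges,
    activation = activation,
    config = list(learning_rate = learning_rate, tolerance = tolerance,
                  max_epochs = as.integer(max_epochs), k = k,
                  seed = as.integer(seed)),
    log = tibble::tibble(epoch = seq_along(fit$mse), mse = as.numeric(fit$mse)),
    epochs = fit$epochs, converged = fit$converged
  ), class = "bpnn")
}

bpnn_forward <- function(model, X) {
  act <- function(z) 1 / (1 + exp(-z))
  Z1 <- X %*% t(model$W1) + matrix(model$b1, nrow(X), model$n_h, byrow = TRUE)
  H <- if (model$activation == "tanh") tanh(Z1) else act(Z1)
  act(H %*% t(model$W2) + matrix(model$b2, nrow(X), model$n_o, byrow = TRUE))
}

#' Predict seed varieties with a trained BPNN
#'
#' Applies the stored normalization ranges, runs the forward pass, and
#' labels each row by the largest output activation (ties go to the first
#' label in the model's label order).
#'
#' @param object A `bpnn` model.
#' @param newdata Data frame with the [seed_feature_names] columns (raw,
#'   unnormalized values).
#' @param ... Unused.
#' @return A tibble with `.label` and one activation column per class
#'   (named `.act_<label>`).
#' @export
predict.bpnn <- function(object, newdata, ...) {
  X <- as.matrix(apply_normalization(newdata, object$ranges)[seed_feature_names])
  O <- bpnn_forward(object, X)
  pick <- apply(O, 1, which.max)   # which.max: first maximum = tie rule
  out <- tibble::tibble(.label = factor(object$labels[pick], levels = object$labels))
  for (j in seq_along(object$labels))
    out[[paste0(".act_", object$labels[j])]] <- O[, j]
  out
}

#' @export
print.bpnn <- function(x, ...) {
  cat("<bpnn> ", x$n_i, "-", x$n_h, "-", x$n_o, " network, classes: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d epochs, final MSE %.5f (%s)\n", x$epochs,
              x$log$mse[nrow(x$log)],
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a BPNN model into a weight table
#'
#' @param x A `bpnn` model.
#' @param ... Unused.
#' @return A tibble with columns `layer` (`"input->hidden"` or
#'   `"hidden->output"`), `from`, `to`, `weight` (biases have
#'   `from = "bias"`).
#' @export
tidy.bpnn <- function(x, ...) {
  w1 <- tibble::tibble(
    layer = "input->hidden",
    from = rep(seed_feature_names[seq_len(x$n_i)], each = x$n_h),
    to = rep(paste0("h", seq_len(x$n_h)), x$n_i),
    weight = as.vector(x$W1))
  b1 <- tibble::tibble(layer = "input->hidden", from = "bias",
                       to = paste0("h", seq_len(x$n_h)), weight = x$b1)
  w2 <- tibble::tibble(
    layer = "hidden->output",
    from = rep(paste0("h", seq_len(x$n_h)), each = x$n_o),
    to = rep(x$labels, x$n_h),
    weight = as.vector(x$W2))
  b2 <- tibble::tibble(layer = "hidden->output", from = "bias",
                       to = x$labels, weight = x$b2)
  dplyr::bind_rows(w1, b1, w2, b2)
}

#' One-row training summary of a BPNN model
#'
#' @param x A `bpnn` model.
#' @param ... Unused.
#' @return A tibble with `n_i`, `n_h`, `n_o`, `epochs`, `final_mse`,
#'   `converged`.
#' @export
glance.bpnn <- function(x, ...) {
  tibble::tibble(n_i = x$n_i, n_h = x$n_h, n_o = x$n_o,
                 epochs = x$epochs,
                 final_mse = x$log$mse[nrow(x$log)],
                 converged = x$converged)
}
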
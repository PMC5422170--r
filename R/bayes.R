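#' Train the Gaussian Bayes comparison classifier
#'
#' Fits a full-covariance Gaussian class-conditional model (quadratic
#' discriminant): per-class mean vector and covariance matrix over the
#' seven features, with priors proportional to class counts. Each
#' covariance is ridge-regularised by adding `1e-6 * trace(S)/p` to its
#' diagonal before inversion.
#'
#' @param data Data frame with the [seed_feature_names] columns and a label
#'   column; at least two samples per class.
#' @param label_col Name of the label column.
#' @return A `gauss_bayes` model object.
#' @examples
#' pop <- sample_population(default_varieties(), n = 20, rng_seed = 1)
#' fit <- train_bayes(pop)
#' glance(fit)
#' @export
train_bayes <- function(data, label_col = "label") {
  if (!label_col %in% names(data)) stop("no label column '", label_col, "'", call. = FALSE)
  labels <- factor(data[[label_col]])
  counts <- table(labels)
  if (any(counts < 2L)) stop("need at least two samples per class", call. = FALSE)
  X <- check_feature_frame(data)
  p <- ncol(X)
  classes <- levels(labels)
  fit_class <- function(cl) {
    Xc <- X[labels == cl, , drop = FALSE]
    S <- stats::cov(Xc)
    S <- S + diag(1e-6 * sum(diag(S)) / p, p)
    ch <- tryCatch(chol(S), error = function(e)
      stop("singular covariance for class '", cl, "'", call. = FALSE))
    list(mean = colMeans(Xc), cov = S, chol = ch,
         log_det = 2 * sum(log(diag(ch))))
  }
  structure(list(
    classes = classes,
    priors = as.numeric(counts) / sum(counts),
    params = lapply(classes, fit_class)
  ), class = "gauss_bayes")
}

bayes_log_posterior <- function(model, X) {
  p <- ncol(X)
  sapply(seq_along(model$classes), function(j) {
    par <- model$params[[j]]
    d2 <- stats::mahalanobis(X, par$mean, par$cov)
    log(model$priors[j]) - 0.5 * par$log_det - 0.5 * d2 - 0.5 * p * log(2 * pi)
  })
}

#' Predict seed varieties with the Gaussian Bayes classifier
#'
#' Labels each row by the maximum posterior under the class-conditional
#' Gaussian model; ties go to the first label in class order.
#'
#' @param object A `gauss_bayes` model.
#' @param newdata Data frame with the [seed_feature_names] columns.
#' @param ... Unused.
#' @return A tibble with `.label` and one log-posterior column per class
#'   (named `.logpost_<label>`).
#' @export
predict.gauss_bayes <- function(object, newdata, ...) {
  X <- check_feature_frame(newdata)
  lp <- bayes_log_posterior(object, X)
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
  pick <- apply(lp, 1, which.max)
  out <- tibble::tibble(.label = factor(object$classes[pick], levels = object$classes))
  for (j in seq_along(object$classes))
    out[[paste0(".logpost_", object$classes[j])]] <- lp[, j]
  out
}

#' @export
print.gauss_bayes <- function(x, ...) {
  cat("<gauss_bayes> classes: ", paste(x$classes, collapse = ", "),
      "; priors: ", paste(signif(x$priors, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy the Gaussian Bayes model into a class-mean table
#'
#' @param x A `gauss_bayes` model.
#' @param ... Unused.
#' @return A tibble with one row per class and feature: `class`, `feature`,
#'   `mean`, `sd` (the marginal standard deviation), `prior`.
#' @export
tidy.gauss_bayes <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$classes), function(j) {
    par <- x$params[[j]]
    tibble::tibble(class = x$classes[j],
                   feature = seed_feature_names,
                   mean = as.numeric(par$mean),
                   sd = sqrt(diag(par$cov)),
                   prior = x$priors[j])
  }))
}

#' One-row summary of the Gaussian Bayes model
#'
#' @param x A `gauss_bayes` model.
#' @param ... Unused.
#' @return A tibble with `n_classes` and `n_features`.
#' @export
glance.gauss_bayes <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_features = length(seed_feature_names))
}
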
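#' Save a trained classifier as JSON
#'
#' Serialises a `bpnn` or `gauss_bayes` model — weights or Gaussian
#' parameters, normalization ranges, labels, configuration and seed — at
#' full precision, so the round trip through [read_model()] is exact and
#' repeated saves of the same model are byte-identical.
#'
#' @param model A `bpnn` or `gauss_bayes` model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "bpnn")) {
    payload <- list(
      type = "bpnn",
      n_i = model$n_i, n_h = model$n_h, n_o = model$n_o,
      W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
      labels = model$labels,
      ranges = as.data.frame(model$ranges),
      activation = model$activation,
      config = model$config,
      log = as.data.frame(model$log),
      epochs = model$epochs, converged = model$converged)
  } else if (inherits(model, "gauss_bayes")) {
    payload <- list(
      type = "gauss_bayes",
      classes = model$classes,
      priors = model$priors,
      means = stats::setNames(lapply(model$params, `[[`, "mean"), model$classes),
      covs = stats::setNames(lapply(model$params, `[[`, "cov"), model$classes))
  } else stop("unsupported model type", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [write_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `bpnn` or `gauss_bayes` model.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) x else matrix(as.numeric(unlist(x)), nr, nc, byrow = TRUE)
  }
  if (identical(j$type, "bpnn")) {
    ranges <- tibble::as_tibble(j$ranges)
    class(ranges) <- c("feature_ranges", class(ranges))
    structure(list(
      W1 = as_mat(j$W1, j$n_h, j$n_i), b1 = as.numeric(j$b1),
      W2 = as_mat(j$W2, j$n_o, j$n_h), b2 = as.numeric(j$b2),
      n_i = j$n_i, n_h = j$n_h, n_o = j$n_o,
      labels = j$labels, ranges = ranges,
      activation = j$activation,
      config = j$config,
      log = tibble::as_tibble(j$log),
      epochs = j$epochs, converged = j$converged
    ), class = "bpnn")
  } else if (identical(j$type, "gauss_bayes")) {
    p <- length(seed_feature_names)
    params <- lapply(j$classes, function(cl) {
      S <- as_mat(j$covs[[cl]], p, p)
      dimnames(S) <- list(seed_feature_names, seed_feature_names)
      mean_i <- as.numeric(unlist(j$means[[cl]]))
      names(mean_i) <- seed_feature_names
      ch <- chol(S)
      list(mean = mean_i, cov = S, chol = ch,
           log_det = 2 * sum(log(diag(ch))))
    })
    structure(list(classes = j$classes, priors = as.numeric(j$priors),
                   params = params),
              class = "gauss_bayes")
  } else stop("unrecognised model file", call. = FALSE)
}
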
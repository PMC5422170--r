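#' Build a confusion matrix
#'
#' Counts are arranged with rows = predicted class and columns = true
#' class, so each column sums to the number of test samples of that
#' variety.
#'
#' @param truth Vector of true labels.
#' @param predicted Vector of predicted labels, same length.
#' @param labels Optional ordered class labels; defaults to the sorted
#'   union of both vectors. Unknown labels in either vector are an error.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length", call. = FALSE)
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% labels) || !all(predicted %in% labels))
    stop("labels outside the provided label set", call. = FALSE)
  cm <- table(factor(predicted, levels = labels), factor(truth, levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(predicted = labels, true = labels))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Wrap a printed count matrix as a confusion matrix
#'
#' For re-evaluating published confusion tables: `x` must be square with
#' rows = predicted and columns = true class.
#'
#' @param x A square numeric matrix of counts.
#' @param labels Class labels (defaults to existing dimnames or `C1..Cn`).
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("confusion matrix must be square", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(labels)) labels <- rownames(x) %||% paste0("C", seq_len(nrow(x)))
  storage.mode(x) <- "integer"
  dimnames(x) <- list(predicted = labels, true = labels)
  structure(x, class = c("confusion_matrix", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class and average classification accuracy
#'
#' Per-class accuracy is `100 * diagonal / column total` (the fraction of
#' each true class predicted correctly); average accuracy is
#' `100 * trace / grand total`. Values are rounded to 2 decimals for
#' reporting.
#'
#' @param cm A `confusion_matrix` (every column total must be positive).
#' @param digits Rounding for the reported percentages (default 2).
#' @return A list of class `confusion_eval` with `per_class` (named numeric
#'   vector, percent), `average` (percent), and the counts.
#' @examples
#' cm <- as_confusion_matrix(rbind(c(9, 1), c(1, 9)), c("a", "b"))
#' evaluate_confusion(cm)
#' @export
evaluate_confusion <- function(cm, digits = 2) {
  stopifnot(inherits(cm, "confusion_matrix"))
  totals <- colSums(cm)
  if (any(totals == 0)) stop("every true class must have test samples", call. = FALSE)
  per_class <- round(100 * diag(cm) / totals, digits)
  average <- round(100 * sum(diag(cm)) / sum(cm), digits)
  structure(list(per_class = per_class, average = average, counts = cm),
            class = "confusion_eval")
}

#' @export
print.confusion_eval <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = true):\n")
  print(unclass(x$counts))
  cat("Per-class accuracy (%): ",
      paste(names(x$per_class), format(x$per_class), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("Average accuracy (%): ", format(x$average), "\n", sep = "")
  invisible(x)
}

#' Tidy accuracy table of an evaluation
#'
#' @param x A `confusion_eval`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `n`, `correct`, `accuracy`
#'   (percent); the final row is the average over all classes.
#' @export
tidy.confusion_eval <- function(x, ...) {
  cm <- x$counts
  tibble::tibble(
    class = c(colnames(cm), "(average)"),
    n = c(as.integer(colSums(cm)), sum(cm)),
    correct = c(as.integer(diag(cm)), sum(diag(cm))),
    accuracy = c(as.numeric(x$per_class), x$average)
  )
}
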
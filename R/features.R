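#' The seven geometric seed features, in canonical order
#'
#' `len_AB` (longest chord), `len_CD` (perpendicular bisector chord),
#' `len_LK` (chaff-tip width), `h_c` (chaff-tip height), `d_K`, `d_L`
#' (concavity depths, deeper first) and `phi` (interior angle, degrees).
#' All classifier-facing tables use these column names in this order.
#'
#' @export
seed_feature_names <- c("len_AB", "len_CD", "len_LK", "h_c", "d_K", "d_L", "phi")

#' Extract the seven-feature descriptor from a seed geometry
#'
#' @param g A `seed_geometry` from [build_seed_geometry()].
#' @return A one-row tibble with the columns of [seed_feature_names].
#' @export
extract_features <- function(g) {
  stopifnot(inherits(g, "seed_geometry"))
  vals <- unlist(g[seed_feature_names])
  if (anyNA(vals)) stop("incomplete geometry: missing concavity data", call. = FALSE)
  tibble::as_tibble(as.list(vals))
}

check_feature_frame <- function(data) {
  missing <- setdiff(seed_feature_names, names(data))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(data[seed_feature_names])
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("features must be finite numbers", call. = FALSE)
  x
}

#' Learn per-feature normalization ranges
#'
#' Records the per-feature minimum and maximum over a training table; these
#' ranges map training values linearly onto `[0, 1]` for classifier input.
#' Constant (degenerate) features are flagged.
#'
#' @param data A data frame containing the [seed_feature_names] columns
#'   (at least two rows).
#' @return A tibble of class `feature_ranges` with columns `feature`,
#'   `min`, `max`, `degenerate`.
#' @export
fit_normalization <- function(data) {
  if (nrow(data) < 2L) stop("need at least two training vectors", call. = FALSE)
  x <- check_feature_frame(data)
  out <- tibble::tibble(
    feature = seed_feature_names,
    min = apply(x, 2, min),
    max = apply(x, 2, max)
  )
  out$degenerate <- out$max == out$min
  class(out) <- c("feature_ranges", class(out))
  out
}

#' Apply (or invert) min–max normalization
#'
#' Maps each feature through `(x - min) / (max - min)`. Values outside the
#' training range are clipped to `[0, 1]`; degenerate features map to 0.5.
#' With `invert = TRUE` the linear map is reversed (clipping and degeneracy
#' make the inverse exact only for in-range, non-degenerate values).
#'
#' @param data A data frame with the [seed_feature_names] columns.
#' @param ranges A [fit_normalization()] result.
#' @param invert Reverse the mapping.
#' @return A tibble with the seven normalized feature columns; any other
#'   columns of `data` are carried through unchanged.
#' @export
apply_normalization <- function(data, ranges, invert = FALSE) {
  stopifnot(inherits(ranges, "feature_ranges"))
  x <- check_feature_frame(data)
  out <- tibble::as_tibble(data)
  for (i in seq_along(seed_feature_names)) {
    f <- seed_feature_names[i]
    lo <- ranges$min[i]; hi <- ranges$max[i]
    if (ranges$degenerate[i]) {
      out[[f]] <- if (invert) rep(lo, nrow(out)) else rep(0.5, nrow(out))
    } else if (invert) {
      out[[f]] <- x[, i] * (hi - lo) + lo
    } else {
      out[[f]] <- pmin(pmax((x[, i] - lo) / (hi - lo), 0), 1)
    }
  }
  out
}
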
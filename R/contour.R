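# Moore neighbourhood in clockwise order for image coordinates
# (row increases downward): E, SE, S, SW, W, NW, N, NE.
.moore <- cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
                dc = c(1, 1, 0, -1, -1, -1, 0, 1))

#' Trace the closed boundary of a single-component mask
#'
#' Moore-neighbour contour following with Jacob's stopping criterion: the
#' trace terminates when the start pixel is re-entered such that the next
#' step would repeat the first step. The start pixel is the topmost, then
#' leftmost, foreground pixel; traversal is clockwise in image coordinates.
#' One-pixel-wide spurs are traversed out and back, so pixels may appear
#' more than once but never with immediate backtracking elsewhere.
#'
#' @param m A [binary_mask] containing exactly one 8-connected foreground
#'   component.
#' @return A `seed_contour`: an `n x 2` matrix of `(row, col)` pixel
#'   coordinates with attribute `closed = TRUE`. Consecutive points
#'   (including last-to-first) are 8-neighbours.
#' @examples
#' m <- binary_mask(matrix(1L, 3, 3))
#' trace_contour(m)
#' @export
trace_contour <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  n_fg <- sum(m)
  if (n_fg == 0L) stop("empty mask", call. = FALSE)
  lab <- label_components8(m)
  if (max(lab) > 1L) stop("multiple components", call. = FALSE)
  mm <- unclass(m)
  nr <- nrow(mm); nc <- ncol(mm)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mm[r, c] == 1L

  # topmost, then leftmost foreground pixel (row-major scan)
  start_idx <- which(t(mm) == 1L)[1]
  s <- c((start_idx - 1L) %/% nc + 1L, (start_idx - 1L) %% nc + 1L)

  if (n_fg == 1L)
    return(structure(matrix(s, nrow = 1,
                            dimnames = list(NULL, c("row", "col"))),
                     closed = TRUE, class = c("seed_contour", "matrix")))

  next_point <- function(p, b) {
    # direction index of backtrack b relative to p
    db <- b - p
    i_b <- which(.moore[, 1] == db[1] & .moore[, 2] == db[2])
    for (step in 1:8) {
      i <- (i_b + step - 1L) %% 8L + 1L
      q <- p + .moore[i, ]
      if (fg(q[1], q[2])) {
        prev <- p + .moore[(i_b + step - 2L) %% 8L + 1L, ]
        return(list(p = q, b = prev))
      }
    }
    NULL
  }

  b0 <- c(s[1], s[2] - 1L)   # west of start; background by construction
  first <- next_point(s, b0)
  pts <- matrix(NA_integer_, nrow = 4L * n_fg + 8L, ncol = 2L)
  pts[1, ] <- s
  npts <- 1L
  p <- first$p; b <- first$b
  max_iter <- 8L * n_fg + 16L
  for (iter in seq_len(max_iter)) {
    # Jacob's criterion: arrived back at start and about to repeat first move
    if (all(p == s)) {
      nxt <- next_point(p, b)
      if (all(nxt$p == first$p)) break
    }
    npts <- npts + 1L
    pts[npts, ] <- p
    nxt <- next_point(p, b)
    p <- nxt$p; b <- nxt$b
  }
  out <- pts[seq_len(npts), , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  structure(out, closed = TRUE, class = c("seed_contour", "matrix"))
}

#' @export
print.seed_contour <- function(x, ...) {
  cat("<seed_contour> ", nrow(x), " boundary points, start (",
      x[1, 1], ", ", x[1, 2], ")\n", sep = "")
  invisible(x)
}
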
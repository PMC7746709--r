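#' Closed planar contours
#'
#' A `closed_contour` is a tibble of ordered vertices (columns `x`, `y`)
#' describing a closed polygonal loop. Closure is implicit: the last vertex
#' connects back to the first and the first vertex is never duplicated.
#' On construction the contour is canonicalized:
#'
#' * orientation is made clockwise in screen coordinates (y growing
#'   downward), which equals a positive shoelace signed area when the
#'   coordinates are read as ordinary mathematical axes;
#' * the vertex list is rotated so that the reference start (the vertex with
#'   minimal x, ties broken by minimal y) comes first; arc position 0 lies
#'   there.
#'
#' Arc positions along the contour are expressed as fractions of the
#' perimeter in `[0, 1)`, measured from the reference start along the
#' canonical orientation.
#'
#' @param vertices A data frame with numeric columns `x` and `y`, one vertex
#'   per row, in traversal order, without a closing duplicate row.
#' @param canonicalize Re-orient and rotate to the canonical form described
#'   above. Set to `FALSE` only when the input is already canonical and the
#'   row order must be preserved (used internally).
#' @return A tibble of class `closed_contour` with columns `x` and `y` and a
#'   `perimeter` attribute.
#' @examples
#' sq <- closed_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' contour_perimeter(sq)
#' @export
closed_contour <- function(vertices, canonicalize = TRUE) {
  stopifnot(is.data.frame(vertices), all(c("x", "y") %in% names(vertices)))
  v <- tibble::tibble(x = as.numeric(vertices$x), y = as.numeric(vertices$y))
  if (anyNA(v$x) || anyNA(v$y)) {
    stop("invalid-contour: vertices contain missing coordinates")
  }
  # drop closing duplicate and any identical consecutive vertices
  n <- nrow(v)
  if (n >= 2 && v$x[1] == v$x[n] && v$y[1] == v$y[n]) v <- v[-n, ]
  keep <- c(TRUE, diff(v$x) != 0 | diff(v$y) != 0)
  v <- v[keep, ]
  if (nrow(v) < 3) stop("invalid-contour: fewer than 3 distinct vertices")
  if (canonicalize) {
    if (signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), ]
    i0 <- reference_start_index(v)
    if (i0 > 1) v <- v[c(i0:nrow(v), 1:(i0 - 1)), ]
  }
  per <- sum(edge_lengths(v))
  if (per <= 0) stop("invalid-contour: zero perimeter")
  structure(tibble::as_tibble(v),
            perimeter = per,
            class = c("closed_contour", class(tibble::tibble())))
}

#' @export
print.closed_contour <- function(x, ...) {
  cat(sprintf("<closed_contour: %d vertices, perimeter %.6g>\n",
              nrow(x), contour_perimeter(x)))
  NextMethod()
}

#' @rdname closed_contour
#' @param contour A `closed_contour`.
#' @export
contour_perimeter <- function(contour) {
  p <- attr(contour, "perimeter")
  if (is.null(p)) p <- sum(edge_lengths(contour))
  p
}

# shoelace signed area; positive = clockwise in screen (y-down) coordinates
signed_area <- function(v) {
  x <- v$x; y <- v$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

reference_start_index <- function(v) {
  cand <- which(v$x == min(v$x))
  cand[which.min(v$y[cand])]
}

edge_lengths <- function(v) {
  x <- v$x; y <- v$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sqrt((xn - x)^2 + (yn - y)^2)
}

# cumulative arc length at each vertex (first vertex at 0)
vertex_arcs <- function(contour) {
  el <- edge_lengths(contour)
  c(0, cumsum(el)[-length(el)])
}

#' Arc positions of the stored vertices
#'
#' @param contour A `closed_contour`.
#' @return Numeric vector in `[0, 1)`, one entry per vertex.
#' @export
vertex_arc_positions <- function(contour) {
  vertex_arcs(contour) / contour_perimeter(contour)
}

#' Point on the contour at given arc positions
#'
#' Linearly interpolates along the polygon edges.
#'
#' @param contour A `closed_contour`.
#' @param s Numeric vector of arc positions; values are wrapped into
#'   `[0, 1)`.
#' @return A tibble with columns `s`, `x`, `y`.
#' @export
arc_point <- function(contour, s) {
  s <- s %% 1
  per <- contour_perimeter(contour)
  cum <- c(vertex_arcs(contour), per)  # length n+1, last = perimeter
  target <- s * per
  idx <- findInterval(target, cum, rightmost.closed = FALSE)
  idx[idx > nrow(contour)] <- nrow(contour)
  x <- contour$x; y <- contour$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  seg_len <- cum[idx + 1] - cum[idx]
  frac <- ifelse(seg_len > 0, (target - cum[idx]) / seg_len, 0)
  tibble::tibble(s = s,
                 x = x[idx] + frac * (xn[idx] - x[idx]),
                 y = y[idx] + frac * (yn[idx] - y[idx]))
}

#' Equidistant resampling of a closed contour
#'
#' Places `n` points at equal arc-length intervals, starting at arc position
#' `start`. Probe grids in the dot-matching paradigm are built this way.
#'
#' @param contour A `closed_contour`.
#' @param n Number of samples (>= 1).
#' @param start Arc position of the first sample, fraction of perimeter.
#' @return A tibble with columns `index` (0-based sample index), `s`, `x`,
#'   `y`; consecutive samples are separated by `perimeter / n`.
#' @export
resample_equidistant <- function(contour, n, start = 0) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("invalid-argument: n must be a positive count")
  }
  n <- as.integer(n)
  s <- (start + (seq_len(n) - 1) / n) %% 1
  pts <- arc_point(contour, s)
  tibble::tibble(index = seq_len(n) - 1L, s = pts$s, x = pts$x, y = pts$y)
}

#' Circular distance between arc positions
#'
#' The along-contour distance on the unit circle of arc positions:
#' `min(|a - b|, 1 - |a - b|)`, a metric with maximum 0.5 (antipodal).
#'
#' @param a,b Numeric vectors of arc positions (recycled to common length).
#' @return Numeric vector in `[0, 0.5]`, fractions of perimeter.
#' @export
arc_distance <- function(a, b) {
  d <- abs((a %% 1) - (b %% 1))
  pmin(d, 1 - d)
}

#' Scale the test contour so both bounding boxes have equal area
#'
#' The test shape's vertices are multiplied by
#' `sqrt(area(bbox(base)) / area(bbox(test)))`; the base is left unchanged.
#' Mirrors the on-screen normalization used when presenting shape pairs.
#'
#' @param base,test `closed_contour` objects.
#' @return The rescaled test contour.
#' @export
normalize_pair_scale <- function(base, test) {
  f <- function(ct) {
    w <- diff(range(ct$x)); h <- diff(range(ct$y))
    a <- w * h
    if (a <= 0) stop("invalid-contour: zero-area bounding box")
    a
  }
  k <- sqrt(f(base) / f(test))
  out <- tibble::tibble(x = test$x * k, y = test$y * k)
  closed_contour(out, canonicalize = FALSE) |>
    structure(scale_factor = k, class = class(test))
}
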
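#' Filter order-reversing predictions before morphing
#'
#' Greedy cyclic-monotone scan over predictions in probe order: a
#' prediction is kept iff its predicted position advances (along the
#' heading direction) past the last kept prediction without completing a
#' full turn of the test contour. The surviving anchor set is guaranteed
#' cyclically monotone; fewer than 3 survivors is a morph-infeasible
#' error.
#'
#' @param predictions Prediction tibble (`probe_index`, `probe_s`,
#'   `predicted_s`, `valid`), in probe order.
#' @param heading `"same"` or `"reversed"`.
#' @return The consistent subset of `predictions`.
#' @export
filter_order_reversals <- function(predictions, heading = c("same", "reversed")) {
  heading <- match.arg(heading)
  pr <- predictions[predictions$valid & !is.na(predictions$predicted_s), ]
  if (nrow(pr) < 3) stop("morph-infeasible: fewer than 3 valid predictions")
  pr <- pr[order(pr$probe_index), ]
  sgn <- if (heading == "same") 1 else -1
  keep <- logical(nrow(pr))
  keep[1] <- TRUE
  last <- pr$predicted_s[1]
  cum <- 0
  for (k in 2:nrow(pr)) {
    gap <- (sgn * (pr$predicted_s[k] - last)) %% 1
    if (gap > 0 && cum + gap < 1) {
      keep[k] <- TRUE
      cum <- cum + gap
      last <- pr$predicted_s[k]
    }
  }
  out <- pr[keep, ]
  if (nrow(out) < 3) stop("morph-infeasible: fewer than 3 consistent anchors")
  out
}

# crossing test for proper segment intersection (shared endpoints ignored)
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

count_self_intersections <- function(contour) {
  v <- cbind(contour$x, contour$y)
  n <- nrow(v)
  nxt <- c(2:n, 1)
  cnt <- 0L
  for (i in 1:(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Correspondence-driven morph between two contours
#'
#' Linearly interpolates matched contour segments between consecutive
#' anchor pairs: each segment is resampled to a point count proportional
#' to the mean of the two segment arc lengths (minimum 2) and each point
#' moves on a straight line from its base to its test position. The test
#' contour is rescaled so both bounding boxes have equal area before
#' interpolation. Self-intersections of intermediate shapes are permitted
#' (and reported via a message), not repaired.
#'
#' @param base,test [closed_contour()] objects.
#' @param anchors A cyclically monotone prediction tibble from
#'   [filter_order_reversals()].
#' @param alpha Morph level in `[0, 1]` (0 = base, 1 = test).
#' @param heading `"same"` or `"reversed"`.
#' @param m Resampling density: points per full perimeter.
#' @param check_intersections Report self-intersections of the result.
#' @return A `closed_contour` at level `alpha`.
#' @export
morph <- function(base, test, anchors, alpha,
                  heading = c("same", "reversed"), m = 200,
                  check_intersections = FALSE) {
  heading <- match.arg(heading)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha <= 1)) {
    stop("invalid-argument: alpha must lie in [0, 1]")
  }
  test <- normalize_pair_scale(base, test)
  sgn <- if (heading == "same") 1 else -1
  na <- nrow(anchors)
  pieces <- vector("list", na)
  for (k in seq_len(na)) {
    k2 <- if (k == na) 1 else k + 1
    pb <- anchors$probe_s[k]
    lb <- (anchors$probe_s[k2] - pb) %% 1
    if (lb == 0) lb <- 1
    qt <- anchors$predicted_s[k]
    lt <- (sgn * (anchors$predicted_s[k2] - qt)) %% 1
    if (lt == 0) lt <- 1
    npts <- max(2, round(mean(c(lb, lt)) * m))
    frac <- (seq_len(npts) - 1) / npts  # endpoint excluded; next piece adds it
    bp <- arc_point(base, pb + lb * frac)
    tp <- arc_point(test, qt + sgn * lt * frac)
    pieces[[k]] <- tibble::tibble(
      x = (1 - alpha) * bp$x + alpha * tp$x,
      y = (1 - alpha) * bp$y + alpha * tp$y)
  }
  out <- closed_contour(dplyr::bind_rows(pieces), canonicalize = FALSE)
  if (check_intersections) {
    ci <- count_self_intersections(out)
    if (ci > 0) message(sprintf("morph at alpha=%.3g has %d self-intersection(s)", alpha, ci))
  }
  out
}

#' Morph sequence across levels
#'
#' Runs [filter_order_reversals()] once and [morph()] at each requested
#' level.
#'
#' @inheritParams morph
#' @param predictions Prediction tibble (will be filtered for order
#'   reversals).
#' @param levels Morph levels in `[0, 1]`.
#' @return Object of class `morph_sequence`: list with `levels`,
#'   `contours` (one `closed_contour` per level), `anchors`,
#'   `n_excluded` (predictions dropped by the reversal filter).
#' @export
morph_sequence <- function(base, test, predictions,
                           levels = c(0, 0.25, 0.5, 0.75, 1),
                           heading = c("same", "reversed"), m = 200) {
  heading <- match.arg(heading)
  anchors <- filter_order_reversals(predictions, heading)
  n_excluded <- sum(predictions$valid) - nrow(anchors)
  contours <- lapply(levels, function(a) {
    morph(base, test, anchors, a, heading = heading, m = m)
  })
  structure(list(levels = levels, contours = contours, anchors = anchors,
                 n_excluded = n_excluded),
            class = "morph_sequence")
}

#' @export
print.morph_sequence <- function(x, ...) {
  cat(sprintf("<morph_sequence: %d level(s) [%s], %d anchors, %d prediction(s) excluded>\n",
              length(x$levels), paste(signif(x$levels, 3), collapse = ", "),
              nrow(x$anchors), x$n_excluded))
  invisible(x)
}
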
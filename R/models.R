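#' Shared start alignment for the uniform and curvature models
#'
#' Returns the start boundary of the segment whose interval midpoint has
#' the smallest x coordinate (ties: lower `s_start`). Both shapes of a
#' pair are re-anchored at this arc position before uniform sampling or
#' profile alignment, which is what makes open-path alignment of the two
#' contours meaningful. A single full-circle segment returns the existing
#' reference start (0).
#'
#' @param contour A [closed_contour()].
#' @param seg Its [part_segmentation()].
#' @return Arc position in `[0, 1)`.
#' @export
align_start_to_leftmost_part <- function(contour, seg) {
  len <- segment_lengths(seg)
  if (nrow(seg) == 1 && len[1] == 1) return(0)
  mids <- (seg$s_start + len / 2) %% 1
  px <- arc_point(contour, mids)$x
  best <- which(px == min(px))
  if (length(best) > 1) best <- best[which.min(seg$s_start[best])]
  seg$s_start[best]
}

#' Uniform sampling correspondence model
#'
#' Distributes predicted locations at equidistant intervals around the
#' test contour, replicating the order of the probe points:
#' `predicted s = (start_test +/- i/n) mod 1`, `+` for heading `"same"`,
#' `-` for `"reversed"`.
#'
#' @param n Number of probes.
#' @param start_base,start_test Aligned start positions (from
#'   [align_start_to_leftmost_part()]) on base and test.
#' @param heading `"same"` or `"reversed"`.
#' @param probe_index 0-based probe indices; defaults to `0:(n-1)`.
#' @return Prediction tibble (`probe_index`, `probe_s`, `predicted_s`,
#'   `model`, `valid`).
#' @export
uniform_predict <- function(n, start_base, start_test,
                            heading = c("same", "reversed"),
                            probe_index = seq_len(n) - 1L) {
  heading <- match.arg(heading)
  sgn <- if (heading == "same") 1 else -1
  tibble::tibble(
    probe_index = as.integer(probe_index),
    probe_s = (start_base + probe_index / n) %% 1,
    predicted_s = (start_test + sgn * probe_index / n) %% 1,
    model = "uniform",
    valid = TRUE)
}

#' Dynamic time warping alignment of two profiles
#'
#' Minimum-total-cost monotone alignment of two numeric profiles under
#' squared-difference local cost, with steps (1,0), (0,1), (1,1) and a
#' diagonal-preferring tie-break in the backtrack. The profiles are
#' treated as open paths; cyclic structure is handled upstream by the
#' start alignment.
#'
#' @param a,b Numeric vectors (typically `u_norm` columns of
#'   [surprisal_profile()] objects sampled from start-aligned contours).
#' @return Tibble of class `warping_path` with columns `i`, `j` (1-based
#'   indices into `a` and `b`); attribute `total_cost`.
#' @export
dtw_align <- function(a, b) {
  if (inherits(a, "surprisal_profile")) a <- a$u_norm
  if (inherits(b, "surprisal_profile")) b <- b$u_norm
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("invalid-input: empty profile")
  local <- outer(a, b, function(x, y) (x - y)^2)
  D <- matrix(Inf, na, nb)
  D[1, 1] <- local[1, 1]
  for (j in 2:max(nb, 2)) if (nb > 1) D[1, j] <- D[1, j - 1] + local[1, j]
  for (i in 2:max(na, 2)) {
    if (na > 1) {
      D[i, 1] <- D[i - 1, 1] + local[i, 1]
      if (nb > 1) for (j in 2:nb) {
        D[i, j] <- local[i, j] + min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      }
    }
  }
  # backtrack, diagonal preferred on ties
  i <- na; j <- nb
  pi <- integer(na + nb); pj <- integer(na + nb); k <- 0L
  while (i > 1 || j > 1) {
    k <- k + 1L; pi[k] <- i; pj[k] <- j
    if (i > 1 && j > 1) {
      cand <- c(D[i - 1, j - 1], D[i, j - 1], D[i - 1, j])
      step <- which.min(cand)  # ties resolve to the diagonal
      if (step == 1) { i <- i - 1; j <- j - 1 }
      else if (step == 2) j <- j - 1
      else i <- i - 1
    } else if (j > 1) j <- j - 1 else i <- i - 1
  }
  k <- k + 1L; pi[k] <- 1L; pj[k] <- 1L
  structure(tibble::tibble(i = rev(pi[1:k]), j = rev(pj[1:k])),
            total_cost = D[na, nb],
            class = c("warping_path", class(tibble::tibble())))
}

#' Project probes through a warping path (curvature model core)
#'
#' Each probe is mapped to its nearest base profile index; its prediction
#' is the mean test index matched to that base index on the path,
#' converted back to an arc position by un-rotating the start alignment
#' (and un-reversing when the heading is reversed).
#'
#' @param probes Numeric arc positions or a tibble with columns `index`,
#'   `s`.
#' @param path A `warping_path` from [dtw_align()].
#' @param m_base,m_test Profile lengths.
#' @param start_base,start_test Aligned start positions.
#' @param heading `"same"` or `"reversed"`.
#' @return Prediction tibble with `model = "curvature"`.
#' @export
curvature_predict <- function(probes, path, m_base, m_test,
                              start_base, start_test,
                              heading = c("same", "reversed")) {
  heading <- match.arg(heading)
  if (is.data.frame(probes)) { idx <- probes$index; ps <- probes$s }
  else { ps <- as.numeric(probes) %% 1; idx <- seq_along(ps) - 1L }
  sgn <- if (heading == "same") 1 else -1
  rel <- (ps - start_base) %% 1
  bi <- (round(rel * m_base) %% m_base) + 1L
  pred <- vapply(bi, function(i) {
    jbar <- mean(path$j[path$i == i])
    (start_test + sgn * (jbar - 1) / m_test) %% 1
  }, numeric(1))
  tibble::tibble(probe_index = idx, probe_s = ps, predicted_s = pred,
                 model = "curvature", valid = !is.na(pred))
}

#' Full curvature-based correspondence model for a shape pair
#'
#' Start-aligns both contours at their leftmost semantic part, computes
#' normalized surprisal profiles (the test profile traversed along the
#' pair's heading), aligns them by [dtw_align()], and projects the probes.
#'
#' @param base,test [closed_contour()] objects.
#' @param base_seg,test_seg Their [part_segmentation()]s (used only for
#'   the start alignment).
#' @param probes Probe arc positions (vector or `index`/`s` tibble).
#' @param m Profile samples per contour. @param window_w Turning-angle
#' window. @param kappa von Mises concentration.
#' @param heading `"same"` or `"reversed"`.
#' @return Prediction tibble with `model = "curvature"`.
#' @export
curvature_model <- function(base, test, base_seg, test_seg, probes,
                            m = 200, window_w = 0.05, kappa = 1,
                            heading = c("same", "reversed")) {
  heading <- match.arg(heading)
  sb <- align_start_to_leftmost_part(base, base_seg)
  st <- align_start_to_leftmost_part(test, test_seg)
  pb <- contour_surprisal(base, m = m, window_w = window_w, kappa = kappa,
                          start = sb)
  pt <- contour_surprisal(test, m = m, window_w = window_w, kappa = kappa,
                          start = st, reverse = (heading == "reversed"))
  path <- dtw_align(pb$u_norm, pt$u_norm)
  curvature_predict(probes, path, m, m, sb, st, heading)
}

#' Detect surprisal landmarks on a contour
#'
#' A sample is a landmark iff it is a cyclic local extremum of the signed
#' normalized surprisal, the profile falls (for maxima) or rises (for
#' minima) by at least `flank` on both sides before any value beyond the
#' extremum is met, and its absolute value exceeds `min_abs`. Plateaus of
#' equal values count as one extremum located at the plateau center.
#'
#' @param profile A [surprisal_profile()].
#' @param flank Required drop/rise on both flanks. Default 0.05.
#' @param min_abs Minimum absolute landmark value. Default 0.02.
#' @return Tibble with columns `index`, `s`, `polarity` (`"max"`/`"min"`),
#'   `value`.
#' @export
detect_landmarks <- function(profile, flank = 0.05, min_abs = 0.02) {
  u <- profile$u_signed
  n <- length(u)
  # compress cyclic runs of equal values
  r <- rle(u)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  if (length(vals) > 1 && vals[1] == vals[length(vals)]) {
    # merge the wrap-around plateau
    starts[1] <- starts[length(vals)] - n
    vals <- vals[-length(vals)]; ends <- ends[-length(ends)]
    starts <- starts[-length(starts)]
  }
  nr <- length(vals)
  if (nr < 2) return(tibble::tibble(index = integer(0), s = numeric(0),
                                    polarity = character(0), value = numeric(0)))
  out <- list()
  for (k in seq_len(nr)) {
    v <- vals[k]
    prev <- vals[if (k == 1) nr else k - 1]
    nxt <- vals[if (k == nr) 1 else k + 1]
    pol <- if (v > prev && v > nxt) "max" else if (v < prev && v < nxt) "min" else next
    if (abs(v) <= min_abs) next
    ok_dir <- function(dirn) {
      kk <- k
      for (step in seq_len(nr - 1)) {
        kk <- ((kk - 1 + dirn) %% nr) + 1
        w <- vals[kk]
        if (pol == "max") {
          if (w > v) return(FALSE)
          if (w <= v - flank) return(TRUE)
        } else {
          if (w < v) return(FALSE)
          if (w >= v + flank) return(TRUE)
        }
      }
      FALSE
    }
    if (!ok_dir(-1) || !ok_dir(1)) next
    center <- round((starts[k] + ends[k]) / 2)
    center <- ((center - 1) %% n) + 1
    out[[length(out) + 1]] <- tibble::tibble(
      index = as.integer(center), s = profile$s[center],
      polarity = pol, value = v)
  }
  if (length(out) == 0) {
    return(tibble::tibble(index = integer(0), s = numeric(0),
                          polarity = character(0), value = numeric(0)))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$index)
}

#' Combined semantic + landmark correspondence model
#'
#' Starts from the semantic part prediction. Within each pair of
#' corresponding part spans, if the base and test spans contain the same
#' number (>= 1) of surprisal landmarks, the prediction becomes piecewise
#' linear in arc length between matched anchors (span start, the
#' landmarks in arc order, span end); with unequal landmark counts no
#' unequivocal assignment exists and the semantic prediction is kept.
#'
#' @inheritParams semantic_predict
#' @param landmarks_base,landmarks_test Landmark tibbles from
#'   [detect_landmarks()] computed on the base and test contours (test
#'   landmarks in the test contour's canonical coordinates; heading
#'   reversal is handled here).
#' @return Prediction tibble with `model = "combined"`.
#' @export
combined_predict <- function(probes, base_seg, test_seg, corr, heading,
                             landmarks_base, landmarks_test) {
  heading <- match.arg(heading, c("same", "reversed"))
  sem <- semantic_predict(probes, base_seg, test_seg, corr, heading)
  tseg <- if (heading == "reversed") reverse_segmentation(test_seg) else test_seg
  lt_s <- landmarks_test$s
  if (heading == "reversed") lt_s <- (1 - lt_s) %% 1
  pred <- sem$predicted_s
  for (k in seq_len(nrow(sem))) {
    if (!sem$valid[k]) next
    grow <- which(corr$group_id == sem$group_id[k])
    bspan <- group_span(base_seg, corr$base_labels[[grow]])
    tspan <- group_span(tseg, corr$test_labels[[grow]])
    db_lm <- sort(stats::na.omit(vapply(landmarks_base$s, span_locate,
                                        numeric(1), span = bspan)))
    dt_lm <- sort(stats::na.omit(vapply(lt_s, span_locate,
                                        numeric(1), span = tspan)))
    if (length(db_lm) == 0 || length(db_lm) != length(dt_lm)) next
    DB <- span_total(bspan); DT <- span_total(tspan)
    xs <- c(0, db_lm, DB); ys <- c(0, dt_lm, DT)
    if (any(diff(xs) <= 0) || any(diff(ys) <= 0)) next
    db <- span_locate(bspan, sem$probe_s[k])
    dt <- stats::approx(xs, ys, xout = db, ties = "ordered")$y
    s_pred <- span_point(tspan, dt)
    if (heading == "reversed") s_pred <- (1 - s_pred) %% 1
    pred[k] <- s_pred
  }
  sem$predicted_s <- pred
  sem$model <- "combined"
  sem
}
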
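#' Specification of a synthetic labeled animal-like shape
#'
#' The shape is an elliptical body with labeled appendages welded onto its
#' outline. Appendages are described per row of `parts`:
#'
#' * `label` — part label from [part_label_vocabulary()];
#' * `position` — attachment point as a fraction of the body outline
#'   parameterization in `[0, 1)`;
#' * `width` — attachment arc width, same units (fraction of the body
#'   parameterization);
#' * `length` — how far the appendage extends outward, in body units
#'   (the body semi-minor axis is 1);
#' * `angle` — rotation of the appendage away from the outward normal,
#'   radians.
#'
#' The body itself carries the mandatory `"Body"` label. Attachment arcs
#' must not overlap. The same seed always yields the same shape.
#'
#' @param parts Data frame with columns `label`, `position`, `width`,
#'   `length`, `angle` (angle optional, default 0). `NULL` for a body-only
#'   shape.
#' @param body_aspect Semi-major axis of the body ellipse. Default 1.8.
#' @param smooth Amplitude of low-frequency seeded radial modulation of
#'   the body outline (organic look). Default 0.02.
#' @param n_body Body outline samples. Default 240.
#' @param seed RNG seed.
#' @return List of class `shape_spec`.
#' @export
shape_spec <- function(parts = NULL, body_aspect = 1.8, smooth = 0.02,
                       n_body = 240, seed = 1) {
  if (!is.null(parts)) {
    parts <- tibble::as_tibble(parts)
    if (!"angle" %in% names(parts)) parts$angle <- 0
    stopifnot(all(c("label", "position", "width", "length") %in% names(parts)))
    if (any(parts$width <= 0) || any(parts$length <= 0)) {
      stop("invalid-spec: non-positive appendage size")
    }
    parts <- parts[order(parts$position), ]
    a0 <- parts$position - parts$width / 2
    a1 <- parts$position + parts$width / 2
    if (any(a0 < 0) || any(a1 > 1)) {
      stop("invalid-spec: attachment arcs must not wrap through position 0")
    }
    if (nrow(parts) > 1 && any(a0[-1] < a1[-nrow(parts)])) {
      stop("invalid-spec: overlapping appendage attachments")
    }
  }
  structure(list(parts = parts, body_aspect = body_aspect, smooth = smooth,
                 n_body = as.integer(n_body), seed = as.integer(seed)),
            class = "shape_spec")
}

#' A ready-made quadruped shape specification
#'
#' Body with head, two front and two hind legs (shared labels), and a
#' tail — the default synthetic stand-in for an animal outline.
#'
#' @inheritParams shape_spec
#' @export
quadruped_spec <- function(seed = 1, body_aspect = 1.8, smooth = 0.02) {
  shape_spec(tibble::tibble(
    label = c("Head", "Front leg/s", "Front leg/s", "Hind leg/s",
              "Hind leg/s", "Tail"),
    position = c(0.06, 0.28, 0.36, 0.55, 0.63, 0.80),
    width = c(0.06, 0.035, 0.035, 0.035, 0.035, 0.04),
    length = c(0.9, 1.1, 1.1, 1.1, 1.1, 0.8),
    angle = c(0, 0.15, 0.15, -0.15, -0.15, 0)
  ), body_aspect = body_aspect, smooth = smooth, seed = seed)
}

# body outline point + outward normal at parameterization u (before smoothing)
body_frame <- function(u, a, b, smooth_fun) {
  t <- 2 * pi * u
  r <- smooth_fun(u)
  x <- a * cos(t) * r
  y <- b * sin(t) * r
  nx <- cos(t) / a; ny <- sin(t) / b
  nl <- sqrt(nx^2 + ny^2)
  list(x = x, y = y, nx = nx / nl, ny = ny / nl)
}

#' Generate a labeled synthetic shape
#'
#' Builds the welded body + appendage polygon of a [shape_spec()] and the
#' ground-truth part segmentation of its outline.
#'
#' @param spec A [shape_spec()].
#' @return List of class `labeled_shape`: `contour` (a
#'   [closed_contour()]), `segmentation` (a [part_segmentation()]),
#'   `spec`.
#' @export
generate_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  a <- spec$body_aspect; b <- 1
  phases <- with_seed(spec$seed, stats::runif(3, 0, 2 * pi))
  smooth_fun <- function(u) {
    1 + spec$smooth * (sin(2 * pi * 2 * u + phases[1]) +
                         0.6 * sin(2 * pi * 3 * u + phases[2]) +
                         0.4 * sin(2 * pi * 5 * u + phases[3]))
  }
  u_body <- (seq_len(spec$n_body) - 1) / spec$n_body
  verts <- list(); labels <- character(0)
  add <- function(x, y, lab) {
    verts[[length(verts) + 1]] <<- cbind(x, y)
    labels <<- c(labels, rep(lab, length(x)))
  }
  parts <- spec$parts
  cuts <- if (is.null(parts)) numeric(0) else parts$position
  u_prev <- 0
  if (is.null(parts) || nrow(parts) == 0) {
    f <- body_frame(u_body, a, b, smooth_fun)
    add(f$x, f$y, "Body")
  } else {
    for (k in seq_len(nrow(parts))) {
      u0 <- parts$position[k] - parts$width[k] / 2
      u1 <- parts$position[k] + parts$width[k] / 2
      ub <- u_body[u_body >= u_prev & u_body < u0]
      fb <- body_frame(ub, a, b, smooth_fun)
      add(fb$x, fb$y, "Body")
      # appendage: A (weld start) -> out -> rounded tip -> back -> B (weld end)
      fa <- body_frame(u0, a, b, smooth_fun)
      fb2 <- body_frame(u1, a, b, smooth_fun)
      fc <- body_frame(parts$position[k], a, b, smooth_fun)
      d <- rotate2d(cbind(fc$nx, fc$ny), parts$angle[k])
      L <- parts$length[k]
      n_side <- max(3, round(L * 12))
      tfrac <- seq(0, 1, length.out = n_side + 1)[-1]
      ax <- fa$x + tfrac * L * d[1]; ay <- fa$y + tfrac * L * d[2]
      bx <- fb2$x + rev(tfrac) * L * d[1]; by <- fb2$y + rev(tfrac) * L * d[2]
      t1 <- c(ax[n_side], ay[n_side]); t2 <- c(bx[1], by[1])
      mid <- (t1 + t2) / 2
      rad <- sqrt(sum((t2 - t1)^2)) / 2
      ang0 <- atan2(t1[2] - mid[2], t1[1] - mid[1])
      tip_ang <- ang0 - seq_len(4) / 5 * pi  # half-circle bulging outward
      tipx <- mid[1] + rad * cos(tip_ang); tipy <- mid[2] + rad * sin(tip_ang)
      # outward half-circle: flip if the tip bulges inward
      tip_dir <- sum((c(mean(tipx), mean(tipy)) - mid) * d)
      if (tip_dir < 0) {
        tip_ang <- ang0 + seq_len(4) / 5 * pi
        tipx <- mid[1] + rad * cos(tip_ang); tipy <- mid[2] + rad * sin(tip_ang)
      }
      add(c(fa$x, ax), c(fa$y, ay), parts$label[k])
      add(tipx, tipy, parts$label[k])
      add(c(bx, fb2$x), c(by, fb2$y), parts$label[k])
      u_prev <- u1
    }
    ub <- u_body[u_body >= u_prev]
    fb <- body_frame(ub, a, b, smooth_fun)
    add(fb$x, fb$y, "Body")
  }
  v <- do.call(rbind, verts)
  xy <- tibble::tibble(x = v[, 1], y = v[, 2])
  # drop coincident consecutive vertices, keeping labels in sync
  keep <- c(TRUE, diff(xy$x) != 0 | diff(xy$y) != 0)
  if (xy$x[1] == xy$x[nrow(xy)] && xy$y[1] == xy$y[nrow(xy)]) keep[nrow(xy)] <- FALSE
  xy <- xy[keep, ]; labels <- labels[keep]
  # canonicalize manually so vertex labels stay aligned
  if (signed_area(xy) < 0) {
    ord <- rev(seq_len(nrow(xy)))
    xy <- xy[ord, ]; labels <- labels[ord]
  }
  i0 <- reference_start_index(xy)
  if (i0 > 1) {
    ord <- c(i0:nrow(xy), 1:(i0 - 1))
    xy <- xy[ord, ]; labels <- labels[ord]
  }
  ct <- closed_contour(xy, canonicalize = FALSE)
  sv <- vertex_arc_positions(ct)
  runs <- which(labels != c(labels[-1], labels[1]))  # run ends
  seg <- if (length(runs) == 0) {
    part_segmentation(tibble::tibble(label = labels[1], s_start = 0, s_end = 0))
  } else {
    starts_idx <- (runs %% nrow(ct)) + 1  # first vertex of each run
    part_segmentation(tibble::tibble(
      label = labels[starts_idx],
      s_start = sv[starts_idx],
      s_end = sv[c(starts_idx[-1], starts_idx[1])]))
  }
  structure(list(contour = ct, segmentation = seg, spec = spec),
            class = "labeled_shape")
}

#' @export
print.labeled_shape <- function(x, ...) {
  cat(sprintf("<labeled_shape: %d vertices, %d segment(s): %s>\n",
              nrow(x$contour), nrow(x$segmentation),
              paste(unique(x$segmentation$label), collapse = ", ")))
  invisible(x)
}

#' Generate a base/test shape pair with ground truth
#'
#' Two pair types mirror the two experimental designs the analysis
#' targets:
#'
#' * `"different_geometry"` — the test shape is the base with per-part
#'   appendage lengths rescaled (`part_transforms`, a named vector of
#'   positive factors); labels correspond identically and the dense
#'   ground-truth map is the part-proportional one.
#' * `"ambiguous"` — the test contour is vertex-identical to the base
#'   but its arcs are relabeled (`relabel`, a named character vector,
#'   e.g. `c(Head = "Tail", Tail = "Head")`), with the heading optionally
#'   reversed — same geometry, different part organization.
#'
#' @param spec A [shape_spec()] for the base shape.
#' @param part_transforms Named numeric vector of per-label length scale
#'   factors (different-geometry mode).
#' @param mode `"different_geometry"` or `"ambiguous"`.
#' @param relabel Named character vector mapping base labels to test
#'   labels (ambiguous mode).
#' @param test_body_aspect Body aspect of the test shape
#'   (different-geometry mode); defaults to the base aspect.
#' @param heading Heading of the pair (`"same"` or `"reversed"`).
#' @return List of class `shape_pair`: `base`, `test` (`labeled_shape`s),
#'   `corr` (ground-truth [label_correspondence()]), `heading`, `mode`.
#' @export
generate_pair <- function(spec, part_transforms = NULL,
                          mode = c("different_geometry", "ambiguous"),
                          relabel = NULL, heading = c("same", "reversed"),
                          test_body_aspect = NULL) {
  mode <- match.arg(mode)
  heading <- match.arg(heading)
  base <- generate_shape(spec)
  if (mode == "different_geometry") {
    parts2 <- spec$parts
    if (!is.null(part_transforms)) {
      if (any(part_transforms <= 0)) stop("invalid-spec: non-positive transform")
      hit <- parts2$label %in% names(part_transforms)
      parts2$length[hit] <- parts2$length[hit] *
        part_transforms[parts2$label[hit]]
    }
    # the pair emulates two different animals sharing a part inventory, so
    # the test shape gets its own outline detail (independent smoothing seed)
    spec2 <- shape_spec(parts2,
                        body_aspect = test_body_aspect %||% spec$body_aspect,
                        smooth = spec$smooth, n_body = spec$n_body,
                        seed = spec$seed + 7919L)
    test <- generate_shape(spec2)
  } else {
    # two interpretations of one geometry: the arcs keep their positions but
    # carry the mirrored interpretation's labels; identical label sets mean
    # the label correspondence is the identity (Head matches Head), so the
    # predicted correspondences differ even though the contours are the same
    if (is.null(relabel)) {
      relabel <- c(Head = "Tail", Tail = "Head",
                   "Front leg/s" = "Hind leg/s", "Hind leg/s" = "Front leg/s")
    }
    test <- base
    new_lab <- ifelse(test$segmentation$label %in% names(relabel),
                      relabel[test$segmentation$label],
                      test$segmentation$label)
    test$segmentation <- part_segmentation(tibble::tibble(
      label = unname(new_lab),
      s_start = test$segmentation$s_start,
      s_end = test$segmentation$s_end))
  }
  labs <- unique(base$segmentation$label)
  corr <- label_correspondence(tibble::tibble(
    base_labels = as.list(labs), test_labels = as.list(labs)))
  structure(list(base = base, test = test, corr = corr,
                 heading = heading, mode = mode),
            class = "shape_pair")
}

#' @export
print.shape_pair <- function(x, ...) {
  cat(sprintf("<shape_pair (%s, heading %s): base %d vertices, test %d vertices>\n",
              x$mode, x$heading, nrow(x$base$contour), nrow(x$test$contour)))
  invisible(x)
}

#' Ground-truth correspondence map of a synthetic pair
#'
#' The part-proportional map induced by the pair's ground-truth
#' segmentations, labels and heading.
#'
#' @param pair A [generate_pair()] result.
#' @param probes Probe arc positions (vector or `index`/`s` tibble).
#' @return Prediction tibble.
#' @export
ground_truth_predict <- function(pair, probes) {
  semantic_predict(probes, pair$base$segmentation, pair$test$segmentation,
                   pair$corr, pair$heading)
}

#' Simulated observer specification
#'
#' @param n_participants Number of simulated participants. Default 15.
#' @param model Which correspondence signal the observers follow
#'   (`"ground_truth"`, i.e. the part-proportional map).
#' @param kappa_resp Concentration of the wrapped response noise. The
#'   noise is wrapped normal with arc s.d. `1/sqrt(kappa_resp)`
#'   (matching a von Mises of the same concentration for large kappa).
#'   Default 900 (s.d. about 3.3% of perimeter, the agreement regime of well-matched animal pairs).
#' @param reversal_prob Probability that a participant responds in the
#'   reversed cyclic order (heading-reversal subgroup). Default 0.
#' @param lapse Probability a response is replaced by a uniform draw.
#' @param seed RNG seed.
#' @return List of class `observer_spec`.
#' @export
observer_spec <- function(n_participants = 15, model = "ground_truth",
                          kappa_resp = 900, reversal_prob = 0, lapse = 0,
                          seed = 1) {
  stopifnot(kappa_resp > 0, reversal_prob >= 0, reversal_prob <= 1,
            lapse >= 0, lapse <= 1, n_participants >= 1)
  structure(list(n_participants = as.integer(n_participants), model = model,
                 kappa_resp = kappa_resp, reversal_prob = reversal_prob,
                 lapse = lapse, seed = as.integer(seed)),
            class = "observer_spec")
}

#' Simulate a dot-matching response table for a shape pair
#'
#' Each participant's response at each probe is the model signal (the
#' pair's ground-truth correspondence, with the heading flipped for
#' reversal-group participants) plus wrapped noise; lapses are replaced
#' by uniform draws. Fully seeded: the same seed reproduces the table
#' exactly.
#'
#' @param pair A [generate_pair()] result.
#' @param observer An [observer_spec()].
#' @param n_probes Number of equidistant probes. Default 50.
#' @param probe_start Arc position of the first probe; `NULL` draws it
#'   from the seeded RNG.
#' @param pair_id Identifier copied into the table.
#' @return Long tibble: `pair_id`, `participant`, `probe_index`,
#'   `probe_s`, `response_s`, `group` (planted heading subgroup);
#'   attribute `probes`.
#' @export
simulate_responses <- function(pair, observer = observer_spec(),
                               n_probes = 50, probe_start = NULL,
                               pair_id = "pair1") {
  with_seed(observer$seed, {
    if (is.null(probe_start)) probe_start <- stats::runif(1)
    probes <- resample_equidistant(pair$base$contour, n_probes, probe_start)
    flip <- function(h) if (h == "same") "reversed" else "same"
    sig_same <- ground_truth_predict(pair, probes)
    pair_rev <- pair; pair_rev$heading <- flip(pair$heading)
    sig_rev <- ground_truth_predict(pair_rev, probes)
    sd_resp <- 1 / sqrt(observer$kappa_resp)
    out <- purrr::map_dfr(seq_len(observer$n_participants), function(p) {
      reversed <- stats::runif(1) < observer$reversal_prob
      sig <- if (reversed) sig_rev else sig_same
      noise <- stats::rnorm(n_probes, 0, sd_resp)
      resp <- (sig$predicted_s + noise) %% 1
      lapses <- stats::runif(n_probes) < observer$lapse
      resp[lapses] <- stats::runif(sum(lapses))
      resp[!sig$valid] <- NA_real_
      tibble::tibble(pair_id = pair_id, participant = p,
                     probe_index = probes$index, probe_s = probes$s,
                     response_s = resp,
                     group = if (reversed) "reversed" else "same")
    })
    structure(out[!is.na(out$response_s), ], probes = probes)
  })
}

#' Simulate part-label votes from noisy labelers
#'
#' Each labeler sees the ground-truth segmentation with every boundary
#' shifted by seeded noise truncated at `boundary_jitter`, and labels all
#' of `m` equidistant contour points accordingly. Points farther than the
#' jitter from every true boundary are voted unanimously.
#'
#' @param segmentation A [part_segmentation()].
#' @param n_labelers Number of labelers. Default 12.
#' @param boundary_jitter Maximal boundary shift, fraction of perimeter;
#'   must be smaller than half the smallest segment.
#' @param m Number of equidistant contour points. Default 200.
#' @param seed RNG seed.
#' @return Long vote tibble: `point_index`, `s`, `labeler`, `label`.
#' @export
simulate_labelers <- function(segmentation, n_labelers = 12,
                              boundary_jitter = 0.005, m = 200, seed = 1) {
  min_len <- min(segment_lengths(segmentation))
  if (boundary_jitter >= min_len / 2) {
    stop("invalid-spec: boundary_jitter must be below half the smallest segment")
  }
  s_grid <- (seq_len(m) - 1) / m
  nb <- nrow(segmentation)
  with_seed(seed, purrr::map_dfr(seq_len(n_labelers), function(l) {
    shift <- if (boundary_jitter > 0) {
      pmin(pmax(stats::rnorm(nb, 0, boundary_jitter / 2),
                -boundary_jitter), boundary_jitter)
    } else rep(0, nb)
    seg_l <- part_segmentation(tibble::tibble(
      label = segmentation$label,
      s_start = (segmentation$s_start + shift) %% 1,
      s_end = (segmentation$s_end + c(shift[-1], shift[1])) %% 1))
    lab <- vapply(s_grid, function(s) seg_l$label[segment_at(seg_l, s)],
                  character(1))
    tibble::tibble(point_index = seq_len(m) - 1L, s = s_grid,
                   labeler = l, label = lab)
  }))
}
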
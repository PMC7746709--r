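#' The fixed part-label vocabulary
#'
#' The 16 animal part labels offered to labelers, in canonical order, plus
#' the residual label `"None of these"`. Vocabulary order is the
#' deterministic tie-break everywhere labels compete.
#'
#' @param include_none Append `"None of these"`.
#' @return Character vector.
#' @export
part_label_vocabulary <- function(include_none = TRUE) {
  v <- c("Head", "Body", "Eye/s", "Neck", "Front leg/s", "Hind leg/s",
         "Foot/Feet", "Ear/s", "Trunk", "Mouth", "Antenna", "Horn/s",
         "Beak", "Wing/s", "Tail", "Fin/s")
  if (include_none) c(v, "None of these") else v
}

vocab_index <- function(label) {
  i <- match(label, part_label_vocabulary())
  ifelse(is.na(i), length(part_label_vocabulary()) + 1L, i)
}

#' Modal part label per contour point
#'
#' Aggregates a long table of per-point label votes into one label per
#' point: the label assigned by the most labelers. Ties are broken by
#' vocabulary order ([part_label_vocabulary()]) with a warning.
#'
#' @param votes Long tibble with columns `point_index`, `s`, `labeler`
#'   (or `participant`), `label`.
#' @return Tibble with columns `point_index`, `s`, `label`, `n_votes`,
#'   `tied`.
#' @export
majority_labels <- function(votes) {
  if (is.null(votes) || nrow(votes) == 0) stop("invalid-input: empty vote table")
  counts <- votes |>
    dplyr::count(.data$point_index, .data$s, .data$label, name = "n_votes")
  out <- counts |>
    dplyr::group_by(.data$point_index, .data$s) |>
    dplyr::summarise(
      tied = sum(.data$n_votes == max(.data$n_votes)) > 1,
      label = .data$label[.data$n_votes == max(.data$n_votes)][
        order(vocab_index(.data$label[.data$n_votes == max(.data$n_votes)]))][1],
      n_votes = max(.data$n_votes),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$s) |>
    dplyr::select("point_index", "s", "label", "n_votes", "tied")
  if (any(out$tied)) {
    warning(sprintf("%d point(s) had tied label votes; vocabulary order used",
                    sum(out$tied)))
  }
  out
}

#' Part segmentation of a closed contour
#'
#' A cyclically ordered set of half-open arc intervals `[s_start, s_end)`
#' tagged with part labels. Intervals are pairwise disjoint and jointly
#' cover the contour; `s_end <= s_start` denotes an interval wrapping
#' through arc position 0, and `s_end == s_start` a full-circle segment.
#'
#' @param segments Data frame with columns `label`, `s_start`, `s_end`.
#' @return Tibble of class `part_segmentation`, ordered by `s_start`.
#' @export
part_segmentation <- function(segments) {
  seg <- tibble::as_tibble(segments)[, c("label", "s_start", "s_end")]
  seg$s_start <- seg$s_start %% 1
  seg$s_end <- seg$s_end %% 1
  seg <- seg[order(seg$s_start), ]
  len <- segment_lengths(seg)
  if (any(len <= 0)) stop("invalid-segmentation: empty segment")
  if (abs(sum(len) - 1) > 1e-8) {
    stop("invalid-segmentation: intervals must cover the contour exactly")
  }
  structure(seg, class = c("part_segmentation", class(tibble::tibble())))
}

#' @rdname part_segmentation
#' @param seg A `part_segmentation`.
#' @return For `segment_lengths()`, the arc length of each interval.
#' @export
segment_lengths <- function(seg) {
  len <- (seg$s_end - seg$s_start) %% 1
  len[len == 0] <- 1
  len
}

# index of the segment containing arc position s (cyclic half-open)
segment_at <- function(seg, s) {
  len <- segment_lengths(seg)
  hit <- which(((s - seg$s_start) %% 1) < len | len == 1)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Segmentation from per-point modal labels
#'
#' Turns modal labels at equidistant contour samples into maximal labeled
#' arcs, with interval boundaries midway between neighboring samples that
#' carry different labels (wrap-around runs are merged across arc 0).
#'
#' @param point_labels Tibble with columns `s` (equidistant, ascending) and
#'   `label`.
#' @return A [part_segmentation()].
#' @export
segment_parts <- function(point_labels) {
  pl <- point_labels[order(point_labels$s), ]
  n <- nrow(pl)
  if (n == 0) stop("invalid-input: no labeled points")
  if (length(unique(pl$label)) == 1) {
    return(part_segmentation(tibble::tibble(
      label = pl$label[1], s_start = 0, s_end = 0)))
  }
  lab <- pl$label
  s <- pl$s
  nxt <- c(2:n, 1)
  # boundary after sample i: cyclic midpoint between s[i] and s[next]
  gap <- (s[nxt] - s) %% 1
  boundary <- (s + gap / 2) %% 1
  change <- which(lab[nxt] != lab)  # run ends at sample i
  starts <- boundary[change[c(length(change), seq_len(length(change) - 1))]]
  ends <- boundary[change]
  part_segmentation(tibble::tibble(
    label = lab[change],  # label of the run ending at each change point
    s_start = starts, s_end = ends))
}

#' Label correspondence between the parts of a shape pair
#'
#' Groups of part labels judged to correspond across the two shapes of a
#' pair. Many-to-one groupings are allowed in either direction but
#' many-to-many is not: in every group at least one side has exactly one
#' label.
#'
#' @param groups Tibble with list-columns `base_labels` and `test_labels`
#'   (character vectors).
#' @return Tibble of class `label_correspondence` with columns `group_id`,
#'   `base_labels`, `test_labels`.
#' @export
label_correspondence <- function(groups) {
  g <- tibble::as_tibble(groups)
  if (!all(c("base_labels", "test_labels") %in% names(g))) {
    stop("invalid-input: need base_labels and test_labels columns")
  }
  nb <- lengths(g$base_labels); nt <- lengths(g$test_labels)
  if (any(nb == 0 | nt == 0)) stop("invalid-input: empty correspondence group")
  if (any(nb > 1 & nt > 1)) {
    stop("invalid-input: many-to-many correspondence group")
  }
  all_b <- unlist(g$base_labels); all_t <- unlist(g$test_labels)
  if (anyDuplicated(all_b) || anyDuplicated(all_t)) {
    stop("invalid-input: a label appears in more than one group")
  }
  g$group_id <- seq_len(nrow(g))
  structure(g[, c("group_id", "base_labels", "test_labels")],
            class = c("label_correspondence", class(tibble::tibble())))
}

#' Aggregate participant label sortings into a label correspondence
#'
#' Each participant sorted the part labels of the two shapes into groups
#' (many-to-one allowed, many-to-many not). For each base label the test
#' label it was most frequently grouped with is selected; base labels
#' sharing a modal test label merge into one group, and test labels left
#' unassigned join the group of their own modal base label where that does
#' not create a many-to-many group. Ties are broken by highest total
#' co-occurrence, then vocabulary order (with a warning).
#'
#' @param sortings Long tibble with columns `participant`, `group`, `side`
#'   (`"base"` or `"test"`), `label`.
#' @return A [label_correspondence()].
#' @export
correspond_labels <- function(sortings) {
  if (is.null(sortings) || nrow(sortings) == 0) {
    stop("invalid-input: no sorting data")
  }
  # per-participant validity: no many-to-many group
  chk <- sortings |>
    dplyr::count(.data$participant, .data$group, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n", values_fill = 0L)
  if (any(chk$base > 1 & chk$test > 1)) {
    stop("invalid-input: a participant grouping is many-to-many")
  }
  base_labels <- sort(unique(sortings$label[sortings$side == "base"]))
  test_labels <- sort(unique(sortings$label[sortings$side == "test"]))
  co <- matrix(0L, length(base_labels), length(test_labels),
               dimnames = list(base_labels, test_labels))
  pairs <- sortings |>
    dplyr::distinct(.data$participant, .data$group, .data$side, .data$label)
  split_pg <- split(pairs, interaction(pairs$participant, pairs$group, drop = TRUE))
  for (pg in split_pg) {
    b <- pg$label[pg$side == "base"]; t <- pg$label[pg$side == "test"]
    if (length(b) && length(t)) co[b, t] <- co[b, t] + 1L
  }
  tied <- FALSE
  pick <- function(scores, cand_names, totals) {
    best <- which(scores == max(scores))
    if (length(best) > 1) {
      tied <<- TRUE
      tot <- totals[best]
      best <- best[tot == max(tot)]
      if (length(best) > 1) best <- best[order(vocab_index(cand_names[best]))]
    }
    cand_names[best[1]]
  }
  col_tot <- colSums(co); row_tot <- rowSums(co)
  modal_test <- vapply(base_labels, function(b) {
    pick(co[b, ], test_labels, col_tot)
  }, character(1))
  groups <- split(base_labels, modal_test)
  g <- tibble::tibble(
    base_labels = unname(groups),
    test_labels = lapply(names(groups), identity)
  )
  # attach unassigned test labels to their modal base label's group
  leftover <- setdiff(test_labels, names(groups))
  for (t in leftover) {
    b <- pick(co[, t], base_labels, row_tot)
    gi <- which(vapply(g$base_labels, function(bs) b %in% bs, logical(1)))
    if (length(g$base_labels[[gi]]) == 1) {
      g$test_labels[[gi]] <- c(g$test_labels[[gi]], t)
    } else {
      stop(sprintf(
        "invalid-input: test label '%s' cannot be attached without a many-to-many group", t))
    }
  }
  if (tied) warning("tied sorting frequencies; co-occurrence totals then vocabulary order used")
  label_correspondence(g)
}

# group id owning a label on a given side; NA when uncovered
group_of_label <- function(corr, label, side = c("base", "test")) {
  side <- match.arg(side)
  col <- if (side == "base") corr$base_labels else corr$test_labels
  hit <- which(vapply(col, function(l) label %in% l, logical(1)))
  if (length(hit) == 0) NA_integer_ else corr$group_id[hit[1]]
}

# mirror a segmentation under traversal reversal: rho(s) = (1 - s) mod 1
reverse_segmentation <- function(seg) {
  part_segmentation(tibble::tibble(
    label = seg$label,
    s_start = (1 - seg$s_end) %% 1,
    s_end = (1 - seg$s_start) %% 1))
}

#' Infer the heading direction of a shape pair
#'
#' Evaluates the cyclic order of corresponding part groups under both
#' traversal directions of the test contour and returns the direction
#' preserving more ordered adjacencies between consecutive groups. Ties
#' resolve to `"same"` (with a message).
#'
#' @param base_seg,test_seg [part_segmentation()] objects.
#' @param corr A [label_correspondence()] covering both segmentations.
#' @return `"same"` or `"reversed"`.
#' @export
infer_heading <- function(base_seg, test_seg, corr) {
  # cyclic order of correspondence groups by first occurrence along the
  # contour; a group owning several intervals (legs, say) enters once, so
  # the order comparison is not washed out by interleaved body arcs
  gseq <- function(seg, side) {
    ids <- vapply(seg$label, group_of_label, integer(1), corr = corr, side = side)
    ids <- ids[!is.na(ids)]
    unique(ids)
  }
  b <- gseq(base_seg, "base")
  t_f <- gseq(test_seg, "test")
  t_f <- t_f[t_f %in% b]; b <- b[b %in% t_f]
  if (length(b) == 0 || length(t_f) == 0) {
    stop("invalid-input: no corresponding parts between the segmentations")
  }
  adj <- function(x) {
    if (length(x) < 2) return(character(0))
    paste(x, c(x[-1], x[1]), sep = ">")
  }
  score <- function(tt) sum(adj(b) %in% adj(tt))
  s_same <- score(t_f)
  s_rev <- score(rev(t_f))
  if (s_rev > s_same) "reversed" else {
    if (s_rev == s_same && s_rev > 0) message("heading tie; defaulting to 'same'")
    "same"
  }
}

# ordered intervals of a label group with cumulative offsets within the span
group_span <- function(seg, labels) {
  rows <- which(seg$label %in% labels)
  if (length(rows) == 0) return(NULL)
  sub <- seg[rows, ]
  sub <- sub[order(sub$s_start), ]
  len <- segment_lengths(sub)
  tibble::tibble(s_start = sub$s_start, len = len,
                 offset = cumsum(len) - len)
}

span_total <- function(span) sum(span$len)

# arc offset (Delta-b) of position s within a span; NA if s is outside
span_locate <- function(span, s) {
  within <- ((s - span$s_start) %% 1)
  hit <- which(within < span$len | span$len == 1)
  if (length(hit) == 0) return(NA_real_)
  span$offset[hit[1]] + within[hit[1]]
}

# arc position at offset delta (0 <= delta <= total) along a span
span_point <- function(span, delta) {
  total <- span_total(span)
  delta <- min(max(delta, 0), total)
  row <- max(which(span$offset <= delta + 1e-12))
  if (delta >= span$offset[row] + span$len[row]) {  # delta == total edge
    return((span$s_start[row] + span$len[row]) %% 1)
  }
  (span$s_start[row] + (delta - span$offset[row])) %% 1
}

#' Semantic part organization correspondence model
#'
#' For each probe on the base contour: identify the semantic part it lies
#' on, find the corresponding part (group) on the test contour, express the
#' probe as a proportion `p = Delta-b / Delta-B` of the base part's contour
#' span, and predict the test location at offset `Delta-t = Delta-T * p`
#' into the corresponding test span, traversed along the pair's heading.
#' When a correspondence group owns several contour intervals (for example
#' two legs sharing one label), the intervals are concatenated in contour
#' order from the group's first boundary into a single span before the
#' proportion is computed.
#'
#' @param probes Numeric vector of probe arc positions on the base contour,
#'   or a tibble with columns `index` and `s` (as from
#'   [resample_equidistant()]).
#' @param base_seg,test_seg [part_segmentation()] objects.
#' @param corr A [label_correspondence()].
#' @param heading `"same"` or `"reversed"`.
#' @return Tibble with columns `probe_index`, `probe_s`, `predicted_s`,
#'   `p`, `group_id`, `model` (`"semantic"`), `valid`. Probes on arcs whose
#'   label has no correspondence are flagged `valid = FALSE`, not dropped.
#' @export
semantic_predict <- function(probes, base_seg, test_seg, corr,
                             heading = c("same", "reversed")) {
  heading <- match.arg(heading)
  if (is.data.frame(probes)) {
    idx <- probes$index; ps <- probes$s
  } else {
    ps <- as.numeric(probes) %% 1; idx <- seq_along(ps) - 1L
  }
  tseg <- if (heading == "reversed") reverse_segmentation(test_seg) else test_seg
  n <- length(ps)
  pred <- rep(NA_real_, n); pp <- rep(NA_real_, n)
  gid <- rep(NA_integer_, n); valid <- rep(FALSE, n)
  for (k in seq_len(n)) {
    si <- segment_at(base_seg, ps[k])
    if (is.na(si)) next
    g <- group_of_label(corr, base_seg$label[si], "base")
    if (is.na(g)) next
    grow <- which(corr$group_id == g)
    bspan <- group_span(base_seg, corr$base_labels[[grow]])
    tspan <- group_span(tseg, corr$test_labels[[grow]])
    if (is.null(bspan) || is.null(tspan)) next
    db <- span_locate(bspan, ps[k])
    if (is.na(db)) next
    p <- db / span_total(bspan)
    s_pred <- span_point(tspan, span_total(tspan) * p)
    if (heading == "reversed") s_pred <- (1 - s_pred) %% 1
    pred[k] <- s_pred; pp[k] <- p; gid[k] <- g; valid[k] <- TRUE
  }
  tibble::tibble(probe_index = idx, probe_s = ps, predicted_s = pred,
                 p = pp, group_id = gid, model = "semantic", valid = valid)
}
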
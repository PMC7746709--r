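#' Read a closed contour from CSV
#'
#' Two float columns x,y, one vertex per row in traversal order, no
#' closing duplicate; `#` comment lines allowed; a `x,y` header row is
#' optional. The contour is canonicalized on load (clockwise in screen
#' coordinates, reference start at the leftmost vertex).
#'
#' @param path File path.
#' @return A [closed_contour()].
#' @export
read_contour_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("invalid-contour: empty file")
  first <- strsplit(trimws(lines[keep[1]]), "\\s*,\\s*")[[1]]
  if (suppressWarnings(anyNA(as.numeric(first[1:2])))) keep <- keep[-1]
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s*,\\s*")[[1]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2 || anyNA(v)) {
      stop(sprintf("parse error at line %d of %s: '%s'", i, path, lines[i]))
    }
    v
  }
  m <- t(vapply(keep, parse_row, numeric(2)))
  closed_contour(tibble::tibble(x = m[, 1], y = m[, 2]))
}

#' @rdname read_contour_csv
#' @param contour A `closed_contour`.
#' @param comment Optional comment line written at the top.
#' @export
write_contour_csv <- function(contour, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("x,y", con)
  writeLines(sprintf("%.17g,%.17g", contour$x, contour$y), con)
  invisible(path)
}

# ---- minimal SVG path support -------------------------------------------

svg_path_tokens <- function(d) {
  toks <- regmatches(d, gregexpr("[MmLlHhVvCcSsQqZzAaTt]|-?\\d*\\.?\\d+(?:[eE][-+]?\\d+)?", d))[[1]]
  toks
}

flatten_cubic <- function(p0, p1, p2, p3, tol) {
  # recursive de Casteljau subdivision until control points hug the chord
  flat <- function(p0, p1, p2, p3) {
    d <- function(p) {
      v <- p3 - p0
      l <- sqrt(sum(v^2))
      if (l == 0) return(sqrt(sum((p - p0)^2)))
      abs(v[1] * (p0[2] - p[2]) - v[2] * (p0[1] - p[1])) / l
    }
    max(d(p1), d(p2))
  }
  if (flat(p0, p1, p2, p3) <= tol) return(rbind(p3))
  m01 <- (p0 + p1) / 2; m12 <- (p1 + p2) / 2; m23 <- (p2 + p3) / 2
  m012 <- (m01 + m12) / 2; m123 <- (m12 + m23) / 2
  mid <- (m012 + m123) / 2
  rbind(flatten_cubic(p0, m01, m012, mid, tol),
        flatten_cubic(mid, m123, m23, p3, tol))
}

#' Read the first closed path of an SVG file as a contour
#'
#' Supports path commands M/m, L/l, H/h, V/v, C/c, S/s, Q/q, Z/z; curves
#' are flattened to a polyline by recursive subdivision until the control
#' points lie within `tolerance` of the chord. Elliptical-arc commands
#' (`A`) are not supported.
#'
#' @param path SVG file path.
#' @param tolerance Chord-error tolerance in user units. Default 0.01.
#' @return A [closed_contour()].
#' @export
read_contour_svg <- function(path, tolerance = 0.01) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='path']")
  d <- NULL
  for (nd in nodes) {
    dd <- xml2::xml_attr(nd, "d")
    if (!is.na(dd) && grepl("[Zz]", dd)) { d <- dd; break }
  }
  if (is.null(d)) stop("invalid-contour: no closed path in SVG")
  toks <- svg_path_tokens(d)
  pts <- list(); cur <- c(0, 0); start <- c(0, 0); prev_ctrl <- NULL
  i <- 1; cmd <- ""
  num <- function() { v <- as.numeric(toks[i]); i <<- i + 1; v }
  push <- function(p) pts[[length(pts) + 1]] <<- rbind(p)
  while (i <= length(toks)) {
    if (grepl("^[A-Za-z]$", toks[i])) { cmd <- toks[i]; i <- i + 1 }
    rel <- cmd %in% c("m", "l", "h", "v", "c", "s", "q")
    base <- if (rel) cur else c(0, 0)
    switch(tolower(cmd),
      m = { cur <- base + c(num(), num()); start <- cur; push(cur)
            cmd <- if (cmd == "m") "l" else "L"; prev_ctrl <- NULL },
      l = { cur <- base + c(num(), num()); push(cur); prev_ctrl <- NULL },
      h = { cur <- c((if (rel) cur[1] else 0) + num(), cur[2]); push(cur)
            prev_ctrl <- NULL },
      v = { cur <- c(cur[1], (if (rel) cur[2] else 0) + num()); push(cur)
            prev_ctrl <- NULL },
      c = { p1 <- base + c(num(), num()); p2 <- base + c(num(), num())
            p3 <- base + c(num(), num())
            pts[[length(pts) + 1]] <- flatten_cubic(cur, p1, p2, p3, tolerance)
            prev_ctrl <- p2; cur <- p3 },
      s = { p1 <- if (is.null(prev_ctrl)) cur else 2 * cur - prev_ctrl
            p2 <- base + c(num(), num()); p3 <- base + c(num(), num())
            pts[[length(pts) + 1]] <- flatten_cubic(cur, p1, p2, p3, tolerance)
            prev_ctrl <- p2; cur <- p3 },
      q = { q1 <- base + c(num(), num()); q3 <- base + c(num(), num())
            p1 <- cur + 2 / 3 * (q1 - cur); p2 <- q3 + 2 / 3 * (q1 - q3)
            pts[[length(pts) + 1]] <- flatten_cubic(cur, p1, p2, q3, tolerance)
            prev_ctrl <- NULL; cur <- q3 },
      z = { cur <- start; prev_ctrl <- NULL; break },
      stop(sprintf("unsupported SVG path command '%s'", cmd))
    )
  }
  m <- do.call(rbind, pts)
  closed_contour(tibble::tibble(x = m[, 1], y = m[, 2]))
}

# ---- tabular formats -----------------------------------------------------

#' Readers and writers for the pipeline's tabular formats
#'
#' Long response tables (`pair_id, participant, probe_index, probe_s,
#' response_s, group`), label-vote tables (`point_index, s, labeler,
#' label`), prediction tables (`pair_id, model, probe_index, probe_s,
#' predicted_s, valid`) and surprisal profiles (`s, theta, u_raw, u_norm,
#' u_signed`) round-trip through CSV; segmentations and label
#' correspondences through JSON.
#'
#' @param x The object to write. @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_responses_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_responses_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant = readr::col_character(),
                    probe_index = readr::col_integer()))
}

#' @rdname pipeline_io
#' @export
write_segmentation_json <- function(x, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(x)), function(i) list(
      label = x$label[i], s_start = x$s_start[i], s_end = x$s_end[i])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_segmentation_json <- function(path) {
  j <- jsonlite::read_json(path)
  part_segmentation(tibble::tibble(
    label = vapply(j, `[[`, character(1), "label"),
    s_start = vapply(j, `[[`, numeric(1), "s_start"),
    s_end = vapply(j, `[[`, numeric(1), "s_end")))
}

#' @rdname pipeline_io
#' @export
write_correspondence_json <- function(x, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(x)), function(i) list(
      base_labels = as.list(x$base_labels[[i]]),
      test_labels = as.list(x$test_labels[[i]]))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_correspondence_json <- function(path) {
  j <- jsonlite::read_json(path)
  label_correspondence(tibble::tibble(
    base_labels = lapply(j, function(g) unlist(g$base_labels)),
    test_labels = lapply(j, function(g) unlist(g$test_labels))))
}

#' @rdname pipeline_io
#' @export
write_profile_csv <- function(x, path) {
  readr::write_csv(x[, c("s", "theta", "u_raw", "u_norm", "u_signed")], path)
  invisible(path)
}

# ---- pipeline ------------------------------------------------------------

#' Default pipeline configuration
#'
#' Parameters of the synthetic battery and the analysis: number of pairs
#' of each type, probes, participants, labelers, profile density, von
#' Mises concentration, window size, response noise, Bayes-factor scale,
#' and the master seed. The defaults mirror the scale of the dot-matching
#' study the package models: 6 different-geometry pairs and 5 ambiguous
#' pairs, 15 participants, 50 probes, 12 labelers.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_pairs_geometry = 6L,
    n_pairs_ambiguous = 5L,
    n_probes = 50L,
    n_participants = 15L,
    n_labelers = 12L,
    boundary_jitter = 0.005,
    kappa_resp = 900,
    reversal_prob = 0,
    lapse = 0,
    m = 200,
    window_w = 0.05,
    kappa = 1,
    bf_scale = 0.707,
    models = c("semantic", "uniform", "curvature", "combined"),
    heading_policy = "auto",
    out_dir = NULL
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Predictions from all requested models for one pair
#'
#' Runs the semantic, uniform, curvature and combined models with shared
#' inputs (segmentations, correspondence, heading, probes).
#'
#' @param base,test [closed_contour()]s. @param base_seg,test_seg
#'   [part_segmentation()]s. @param corr [label_correspondence()].
#' @param probes Probe tibble (`index`, `s`). @param heading `"same"`,
#'   `"reversed"` or `"auto"` (inferred from part ordering).
#' @param models Character subset of
#'   `c("semantic", "uniform", "curvature", "combined")`.
#' @param m,window_w,kappa Profile parameters.
#' @return Prediction tibble with a `model` column; attribute `heading`.
#' @export
predict_all_models <- function(base, test, base_seg, test_seg, corr, probes,
                               heading = "auto",
                               models = c("semantic", "uniform",
                                          "curvature", "combined"),
                               m = 200, window_w = 0.05, kappa = 1) {
  if (identical(heading, "auto")) heading <- infer_heading(base_seg, test_seg, corr)
  out <- list()
  if ("semantic" %in% models) {
    out$semantic <- semantic_predict(probes, base_seg, test_seg, corr, heading)
  }
  if ("uniform" %in% models) {
    sb <- align_start_to_leftmost_part(base, base_seg)
    st <- align_start_to_leftmost_part(test, test_seg)
    sgn <- if (heading == "same") 1 else -1
    # continuous form of the equidistant rule: the arc offset from the
    # aligned base start is replicated from the aligned test start
    out$uniform <- tibble::tibble(
      probe_index = probes$index, probe_s = probes$s,
      predicted_s = (st + sgn * ((probes$s - sb) %% 1)) %% 1,
      model = "uniform", valid = TRUE)
  }
  if ("curvature" %in% models) {
    out$curvature <- curvature_model(base, test, base_seg, test_seg, probes,
                                     m = m, window_w = window_w,
                                     kappa = kappa, heading = heading)
  }
  if ("combined" %in% models) {
    lb <- detect_landmarks(contour_surprisal(base, m = m, window_w = window_w,
                                             kappa = kappa))
    lt <- detect_landmarks(contour_surprisal(test, m = m, window_w = window_w,
                                             kappa = kappa))
    out$combined <- combined_predict(probes, base_seg, test_seg, corr,
                                     heading, lb, lt)
  }
  res <- dplyr::bind_rows(out)
  common <- c("probe_index", "probe_s", "predicted_s", "model", "valid")
  structure(res[, c(common, setdiff(names(res), common))], heading = heading)
}

#' Run the full synthetic simulate-label-predict-evaluate pipeline
#'
#' Generates the synthetic shape-pair battery, simulates labelers and
#' observers, recovers segmentations from the simulated votes, runs all
#' correspondence models, and evaluates congruity, order preservation
#' and model-human distance statistics per pair. All randomness derives
#' from the config seed; rerunning with the same config reproduces the
#' outputs exactly. When `out_dir` is set, contours, responses,
#' predictions and per-pair results (JSON) are written there together
#' with the effective config and its hash.
#'
#' @param config A [run_config()] (or a list of overrides).
#' @return List of class `pipeline_result`: `pairs`, `responses`,
#'   `predictions`, `evaluation` (per pair × model stats tibble),
#'   `congruity` (per pair), `ordering` (per pair), `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config
  pair_specs <- list()
  for (k in seq_len(cfg$n_pairs_geometry)) {
    pair_specs[[length(pair_specs) + 1]] <- list(
      id = sprintf("geom%02d", k), mode = "different_geometry", k = k)
  }
  for (k in seq_len(cfg$n_pairs_ambiguous)) {
    pair_specs[[length(pair_specs) + 1]] <- list(
      id = sprintf("ambi%02d", k), mode = "ambiguous", k = k)
  }
  results <- list(responses = list(), predictions = list(),
                  evaluation = list(), congruity = list(), ordering = list())
  pairs <- list()
  for (ps in pair_specs) {
    pseed <- cfg$seed * 1000L + ps$k + ifelse(ps$mode == "ambiguous", 500L, 0L)
    pair <- if (ps$mode == "different_geometry") {
      # two different animals with a shared part inventory: every appendage
      # rescaled independently and the body proportions changed
      draws <- with_seed(pseed, stats::runif(5, 0, 1))
      tf <- 0.55 + draws[1:4] * (2 - 0.55)
      aspect2 <- 1.8 * (0.8 + draws[5] * 0.5)
      generate_pair(quadruped_spec(seed = pseed),
                    part_transforms = c("Head" = tf[1], "Front leg/s" = tf[2],
                                        "Hind leg/s" = tf[3], "Tail" = tf[4]),
                    test_body_aspect = aspect2)
    } else {
      generate_pair(quadruped_spec(seed = pseed), mode = "ambiguous",
                    heading = "reversed")
    }
    pairs[[ps$id]] <- pair
    # recover segmentations from simulated labeler votes
    seg_from_votes <- function(seg, off) {
      votes <- simulate_labelers(seg, n_labelers = cfg$n_labelers,
                                 boundary_jitter = cfg$boundary_jitter,
                                 m = cfg$m, seed = pseed + off)
      segment_parts(suppressWarnings(majority_labels(votes)))
    }
    base_seg <- seg_from_votes(pair$base$segmentation, 1L)
    test_seg <- seg_from_votes(pair$test$segmentation, 2L)
    obs <- observer_spec(n_participants = cfg$n_participants,
                         kappa_resp = cfg$kappa_resp,
                         reversal_prob = cfg$reversal_prob,
                         lapse = cfg$lapse, seed = pseed + 3L)
    resp <- simulate_responses(pair, obs, n_probes = cfg$n_probes,
                               pair_id = ps$id)
    probes <- attr(resp, "probes")
    heading <- if (identical(cfg$heading_policy, "auto")) "auto" else cfg$heading_policy
    preds <- predict_all_models(pair$base$contour, pair$test$contour,
                                base_seg, test_seg, pair$corr, probes,
                                heading = heading, models = cfg$models,
                                m = cfg$m, window_w = cfg$window_w,
                                kappa = cfg$kappa) |>
      dplyr::mutate(pair_id = ps$id)
    comp <- compare_models(resp, preds, bf_scale = cfg$bf_scale)
    med <- resp |>
      dplyr::group_by(.data$probe_index) |>
      dplyr::summarise(median_s = circular_median(.data$response_s),
                       .groups = "drop")
    results$responses[[ps$id]] <- resp
    results$predictions[[ps$id]] <- preds
    results$evaluation[[ps$id]] <- dplyr::mutate(tidy(comp), pair_id = ps$id)
    results$congruity[[ps$id]] <- dplyr::mutate(congruity(resp), pair_id = ps$id)
    results$ordering[[ps$id]] <-
      dplyr::mutate(ordering_preservation(med$median_s), pair_id = ps$id)
  }
  out <- structure(list(
    pairs = pairs,
    responses = dplyr::bind_rows(results$responses),
    predictions = dplyr::bind_rows(results$predictions),
    evaluation = dplyr::bind_rows(results$evaluation),
    congruity = dplyr::bind_rows(results$congruity),
    ordering = dplyr::bind_rows(results$ordering),
    config = cfg,
    # the hash covers the scientific parameters, not the output location
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  ), class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d pair(s), %d response rows, config %s>\n",
              length(x$pairs), nrow(x$responses), x$config_hash))
  print(x$evaluation)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  meta <- list(config = unclass(cfg), config_hash = res$config_hash,
               seed = cfg$seed)
  yaml::write_yaml(meta, file.path(out_dir, "config.yaml"))
  readr::write_csv(res$responses, file.path(out_dir, "responses.csv"))
  readr::write_csv(res$predictions, file.path(out_dir, "predictions.csv"))
  results <- list(config_hash = res$config_hash, seed = cfg$seed,
                  congruity = res$congruity, ordering = res$ordering,
                  evaluation = res$evaluation)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (id in names(res$pairs)) {
    write_contour_csv(res$pairs[[id]]$base$contour,
                      file.path(out_dir, sprintf("%s_base.csv", id)),
                      comment = sprintf("config %s", res$config_hash))
    write_contour_csv(res$pairs[[id]]$test$contour,
                      file.path(out_dir, sprintf("%s_test.csv", id)))
  }
  invisible(out_dir)
}
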
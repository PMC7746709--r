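test_that("shape generation is deterministic and fully labeled", {
  sh <- generate_shape(quadruped_spec(seed = 3))
  sh2 <- generate_shape(quadruped_spec(seed = 3))
  expect_identical(sh$contour$x, sh2$contour$x)
  expect_identical(sh$segmentation$s_start, sh2$segmentation$s_start)
  expect_equal(sum(segment_lengths(sh$segmentation)), 1, tolerance = 1e-9)
  expect_setequal(unique(sh$segmentation$label),
                  c("Body", "Head", "Front leg/s", "Hind leg/s", "Tail"))
  # outlines are simple polygons
  expect_equal(shapecorr:::count_self_intersections(sh$contour), 0)

  # body-only spec: a single full-circle Body segment
  blob <- generate_shape(shape_spec(NULL, seed = 2))
  expect_equal(nrow(blob$segmentation), 1)
  expect_equal(blob$segmentation$label, "Body")
  expect_equal(segment_lengths(blob$segmentation), 1)
})

test_that("segment arc lengths match the welded appendage geometry", {
  spec <- shape_spec(tibble::tibble(
    label = c("Head", "Tail"), position = c(0.2, 0.7),
    width = c(0.05, 0.05), length = c(1.2, 0.6)), smooth = 0, seed = 1)
  sh <- generate_shape(spec)
  expect_setequal(unique(sh$segmentation$label), c("Body", "Head", "Tail"))
  per <- contour_perimeter(sh$contour)
  seg <- sh$segmentation
  len <- segment_lengths(seg)
  # geometric oracle: appendage outline = two straight sides of length L
  # plus the rounded tip over the weld chord |A - B|
  for (k in which(seg$label != "Body")) {
    A <- arc_point(sh$contour, seg$s_start[k])
    B <- arc_point(sh$contour, seg$s_end[k])
    chord <- sqrt((A$x - B$x)^2 + (A$y - B$y)^2)
    L <- spec$parts$length[spec$parts$label == seg$label[k]]
    expected <- 2 * L + pi * chord / 2
    expect_equal(len[k] * per, expected, tolerance = 0.05 * expected)
  }
  # doubling an appendage scales its arc length accordingly
  spec2 <- shape_spec(dplyr::mutate(spec$parts,
                                    length = ifelse(label == "Head", 2.4, length)),
                      smooth = 0, seed = 1)
  sh2 <- generate_shape(spec2)
  head1 <- segment_lengths(sh$segmentation)[sh$segmentation$label == "Head"] *
    contour_perimeter(sh$contour)
  head2 <- segment_lengths(sh2$segmentation)[sh2$segmentation$label == "Head"] *
    contour_perimeter(sh2$contour)
  expect_equal(head2 / head1, 2, tolerance = 0.15)

  expect_error(shape_spec(tibble::tibble(
    label = c("A", "B"), position = c(0.2, 0.22), width = c(0.1, 0.1),
    length = c(1, 1))), "overlapping")
})

test_that("pair generation provides ground truth for both designs", {
  pair <- generate_pair(quadruped_spec(seed = 5),
                        part_transforms = c("Head" = 2))
  expect_equal(pair$mode, "different_geometry")
  # identity transforms on a shared smoothing seed keep the map exact
  spec <- quadruped_spec(seed = 5)
  base <- generate_shape(spec)
  gt <- ground_truth_predict(pair, c(0.1, 0.4, 0.9))
  expect_true(all(gt$valid))

  amb <- generate_pair(quadruped_spec(seed = 5), mode = "ambiguous",
                       heading = "reversed")
  expect_identical(amb$base$contour$x, amb$test$contour$x)
  expect_false(identical(amb$base$segmentation$label,
                         amb$test$segmentation$label))
  # identical label sets, identity correspondence
  expect_setequal(unique(amb$base$segmentation$label),
                  unique(amb$test$segmentation$label))
  expect_true(all(mapply(identical, amb$corr$base_labels, amb$corr$test_labels)))
  # the mirrored interpretation reverses the part order
  expect_equal(infer_heading(amb$base$segmentation, amb$test$segmentation,
                             amb$corr), "reversed")

  expect_error(generate_pair(quadruped_spec(seed = 5),
                             part_transforms = c("Head" = -1)), "invalid-spec")
})

test_that("noiseless observers reproduce the model signal exactly", {
  pair <- generate_pair(quadruped_spec(seed = 8))
  obs <- observer_spec(n_participants = 5, kappa_resp = 1e12, seed = 2)
  resp <- simulate_responses(pair, obs, n_probes = 40)
  probes <- attr(resp, "probes")
  gt <- ground_truth_predict(pair, probes)
  joined <- dplyr::left_join(resp, gt[, c("probe_index", "predicted_s")],
                             by = "probe_index")
  expect_lt(max(arc_distance(joined$response_s, joined$predicted_s)), 1e-5)
  expect_equal(congruity(resp)$congruity, 1, tolerance = 1e-4)
})

test_that("response tables are seeded deterministically", {
  pair <- generate_pair(quadruped_spec(seed = 8))
  obs <- observer_spec(n_participants = 6, kappa_resp = 500, lapse = 0.05,
                       reversal_prob = 0.3, seed = 13)
  r1 <- simulate_responses(pair, obs, n_probes = 30)
  r2 <- simulate_responses(pair, obs, n_probes = 30)
  expect_identical(r1$response_s, r2$response_s)
  expect_identical(r1$group, r2$group)
})

test_that("wrapped response noise has the analytic mean deviation", {
  pair <- generate_pair(quadruped_spec(seed = 9))
  kappa <- 400  # sd = 0.05, far from the wrap
  obs <- observer_spec(n_participants = 100, kappa_resp = kappa, seed = 3)
  resp <- simulate_responses(pair, obs, n_probes = 50)
  gt <- ground_truth_predict(pair, attr(resp, "probes"))
  joined <- dplyr::left_join(resp, gt[, c("probe_index", "predicted_s")],
                             by = "probe_index")
  mad_obs <- mean(arc_distance(joined$response_s, joined$predicted_s))
  mad_expected <- sqrt(2 / pi) / sqrt(kappa)  # E|N(0, sd)|
  expect_equal(mad_obs, mad_expected, tolerance = 0.05)
})

test_that("labeler votes recover the segmentation outside the jitter zone", {
  sh <- generate_shape(quadruped_spec(seed = 4))
  seg <- sh$segmentation

  # zero jitter: unanimity everywhere, exact recovery
  v0 <- simulate_labelers(seg, n_labelers = 12, boundary_jitter = 0, m = 120,
                          seed = 5)
  ml0 <- majority_labels(v0)
  expect_true(all(ml0$n_votes == 12))
  truth <- vapply(ml0$s, function(s) seg$label[shapecorr:::segment_at(seg, s)],
                  character(1))
  expect_identical(ml0$label, truth)

  # seeded determinism
  v1 <- simulate_labelers(seg, boundary_jitter = 0.004, m = 120, seed = 6)
  v2 <- simulate_labelers(seg, boundary_jitter = 0.004, m = 120, seed = 6)
  expect_identical(v1$label, v2$label)

  # disagreement confined to +/- jitter around the true boundaries
  jit <- 0.004
  ml <- suppressWarnings(majority_labels(v1))
  lab <- vapply(ml$s, function(s) seg$label[shapecorr:::segment_at(seg, s)],
                character(1))
  boundaries <- seg$s_start
  near <- vapply(ml$s, function(s) min(arc_distance(s, boundaries)) <= jit,
                 logical(1))
  mismatch <- ml$label != lab
  expect_true(all(!mismatch | near))

  expect_error(simulate_labelers(seg, boundary_jitter = 0.2, m = 60, seed = 1),
               "invalid-spec")
})

test_that("planted heading subgroups are recovered from the data", {
  pair <- generate_pair(quadruped_spec(seed = 10))
  obs <- observer_spec(n_participants = 20, kappa_resp = 900,
                       reversal_prob = 0.5, seed = 17)
  resp <- simulate_responses(pair, obs, n_probes = 50)
  planted <- dplyr::distinct(resp, .data$participant, .data$group)
  sp <- split_heading_groups(resp)
  joined <- dplyr::inner_join(planted, sp, by = "participant")
  expect_gte(mean(joined$group == joined$direction), 0.95)
})
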
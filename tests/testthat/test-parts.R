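test_that("modal labels follow majority with vocabulary-order tie-break", {
  votes <- tibble::tibble(
    point_index = rep(0:2, times = c(12, 12, 12)),
    s = rep(c(0, 1 / 3, 2 / 3), times = c(12, 12, 12)),
    labeler = rep(1:12, 3),
    label = c(rep("Head", 7), rep("Neck", 5),      # strict majority
              rep("Tail", 12),                     # unanimous
              rep("Head", 6), rep("Neck", 6)))     # tie
  expect_warning(out <- majority_labels(votes), "tied")
  expect_equal(out$label, c("Head", "Tail", "Head"))
  expect_equal(out$tied, c(FALSE, FALSE, TRUE))
  expect_error(majority_labels(votes[0, ]), "invalid-input")
})

test_that("per-point labels become maximal segments with midpoint boundaries", {
  # six samples at cell centers; runs H H H T T H merge across the wrap
  pl <- tibble::tibble(s = (0:5 + 0.5) / 6,
                       label = c("H", "H", "H", "T", "T", "H"))
  seg <- segment_parts(pl)
  expect_equal(nrow(seg), 2)
  h <- seg[seg$label == "H", ]; t <- seg[seg$label == "T", ]
  expect_equal(c(h$s_start, h$s_end), c(5 / 6, 3 / 6), tolerance = 1e-12)
  expect_equal(c(t$s_start, t$s_end), c(3 / 6, 5 / 6), tolerance = 1e-12)

  # alternating labels: four segments of length 1/4
  alt <- segment_parts(tibble::tibble(s = (0:3) / 4,
                                      label = c("A", "B", "A", "B")))
  expect_equal(nrow(alt), 4)
  expect_equal(segment_lengths(alt), rep(0.25, 4))

  # constant labels: one full-circle segment
  one <- segment_parts(tibble::tibble(s = (0:5) / 6, label = rep("X", 6)))
  expect_equal(nrow(one), 1)
  expect_equal(segment_lengths(one), 1)
})

test_that("segment lengths always sum to the full contour", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      pl <- tibble::tibble(s = (seq_len(n) - 1) / n,
                           label = sample(c("A", "B", "C"), n, replace = TRUE))
      seg <- segment_parts(pl)
      expect_equal(sum(segment_lengths(seg)), 1, tolerance = 1e-9)
    }
  })
})

test_that("label sorting aggregates to modal correspondences", {
  mk <- function(participant, groups) {
    purrr::imap_dfr(groups, function(g, i) {
      tibble::tibble(participant = participant, group = i,
                     side = rep(c("base", "test"), c(length(g$b), length(g$t))),
                     label = c(g$b, g$t))
    })
  }
  # identical label sets: everyone sorts identically -> identity mapping
  idn <- purrr::map_dfr(1:9, function(p) mk(p, list(
    list(b = "Head", t = "Head"), list(b = "Body", t = "Body"),
    list(b = "Tail", t = "Tail"))))
  ci <- correspond_labels(idn)
  expect_equal(nrow(ci), 3)
  expect_true(all(mapply(identical, ci$base_labels, ci$test_labels)))

  # many-to-one: Neck and Body most often grouped with Body
  m21 <- purrr::map_dfr(1:9, function(p) mk(p, list(
    list(b = c("Neck", "Body"), t = "Body"), list(b = "Head", t = "Head"))))
  cm <- correspond_labels(m21)
  gi <- which(vapply(cm$test_labels, function(t) identical(t, "Body"), logical(1)))
  expect_setequal(cm$base_labels[[gi]], c("Neck", "Body"))

  # cross-label pairing: Beak sorted with Mouth by most participants
  cross <- purrr::map_dfr(1:9, function(p) mk(p, list(
    list(b = "Beak", t = if (p <= 6) "Mouth" else "Ear/s"),
    list(b = "Head", t = "Head"),
    list(b = "Body", t = c("Body", if (p <= 6) "Ear/s" else "Mouth")))))
  cc <- correspond_labels(cross)
  gb <- which(vapply(cc$base_labels, function(b) "Beak" %in% b, logical(1)))
  expect_true("Mouth" %in% cc$test_labels[[gb]])

  # a many-to-many participant grouping is rejected
  bad <- mk(1, list(list(b = c("Head", "Neck"), t = c("Head", "Body"))))
  expect_error(correspond_labels(bad), "many-to-many")
})

test_that("label correspondence invariants are enforced", {
  expect_error(label_correspondence(tibble::tibble(
    base_labels = list(c("A", "B")), test_labels = list(c("X", "Y")))),
    "many-to-many")
  expect_error(label_correspondence(tibble::tibble(
    base_labels = list("A", "A"), test_labels = list("X", "Y"))),
    "more than one group")
})

test_that("heading is inferred from the cyclic order of corresponding parts", {
  seg3 <- part_segmentation(tibble::tibble(
    label = c("A", "B", "C"), s_start = c(0, 0.3, 0.6), s_end = c(0.3, 0.6, 0)))
  corr <- identity_corr(c("A", "B", "C"))
  expect_equal(infer_heading(seg3, seg3, corr), "same")
  expect_equal(infer_heading(seg3, shapecorr:::reverse_segmentation(seg3), corr),
               "reversed")

  # 5-part case with one transposition: brute-force adjacency count oracle
  base5 <- part_segmentation(tibble::tibble(
    label = c("A", "B", "C", "D", "E"),
    s_start = (0:4) / 5, s_end = c((1:4) / 5, 0)))
  swapped <- part_segmentation(tibble::tibble(
    label = c("A", "C", "B", "D", "E"),  # B and C transposed
    s_start = (0:4) / 5, s_end = c((1:4) / 5, 0)))
  corr5 <- identity_corr(c("A", "B", "C", "D", "E"))
  adj <- function(x) paste(x, c(x[-1], x[1]), sep = ">")
  fwd <- sum(adj(c("A", "B", "C", "D", "E")) %in% adj(c("A", "C", "B", "D", "E")))
  rev_ <- sum(adj(c("A", "B", "C", "D", "E")) %in% adj(rev(c("A", "C", "B", "D", "E"))))
  expect_true(fwd > rev_)  # oracle: forward preserves more adjacencies
  expect_equal(infer_heading(base5, swapped, corr5), "same")

  uncovered <- part_segmentation(tibble::tibble(label = "Z", s_start = 0, s_end = 0))
  expect_error(infer_heading(uncovered, seg3, corr), "invalid-input")
})

test_that("semantic prediction maps part proportions across the pair", {
  # identity pair: predictions equal probes everywhere
  seg <- two_part_seg()
  corr <- identity_corr(c("A", "B"))
  probes <- seq(0, 0.95, by = 0.05)
  pr <- semantic_predict(probes, seg, seg, corr, "same")
  expect_true(all(pr$valid))
  expect_equal(pr$predicted_s, probes, tolerance = 1e-12)

  # p = 0.5 of a part mapping into test span [0.2, 0.6)
  bseg <- part_segmentation(tibble::tibble(
    label = c("A", "B"), s_start = c(0, 0.5), s_end = c(0.5, 0)))
  tseg <- part_segmentation(tibble::tibble(
    label = c("X", "A", "B"), s_start = c(0, 0.2, 0.6), s_end = c(0.2, 0.6, 0)))
  cr <- label_correspondence(tibble::tibble(
    base_labels = list("A", "B"), test_labels = list("A", c("B", "X"))))
  pr2 <- semantic_predict(0.25, bseg, tseg, cr, "same")
  expect_equal(pr2$predicted_s, 0.4, tolerance = 1e-12)
  expect_equal(pr2$p, 0.5)

  # concatenated multi-interval span: {Neck [0,0.1), Body [0.1,0.5)} -> Body [0,0.8)
  b3 <- part_segmentation(tibble::tibble(
    label = c("Neck", "Body", "Rest"), s_start = c(0, 0.1, 0.5),
    s_end = c(0.1, 0.5, 0)))
  t3 <- part_segmentation(tibble::tibble(
    label = c("Body", "Rest"), s_start = c(0, 0.8), s_end = c(0.8, 0)))
  c3 <- label_correspondence(tibble::tibble(
    base_labels = list(c("Neck", "Body"), "Rest"),
    test_labels = list("Body", "Rest")))
  pr3 <- semantic_predict(0.05, b3, t3, c3, "same")
  expect_equal(pr3$p, 0.1)
  expect_equal(pr3$predicted_s, 0.08, tolerance = 1e-12)

  # probe on an uncovered arc is flagged invalid, not dropped
  c_part <- label_correspondence(tibble::tibble(
    base_labels = list("A"), test_labels = list("A")))
  pr4 <- semantic_predict(c(0.25, 0.75), bseg, tseg, c_part, "same")
  expect_equal(pr4$valid, c(TRUE, FALSE))
  expect_equal(nrow(pr4), 2)
})

test_that("semantic prediction is monotone within parts and invertible", {
  bseg <- part_segmentation(tibble::tibble(
    label = c("A", "B"), s_start = c(0, 0.35), s_end = c(0.35, 0)))
  tseg <- part_segmentation(tibble::tibble(
    label = c("A", "B"), s_start = c(0, 0.7), s_end = c(0.7, 0)))
  corr <- identity_corr(c("A", "B"))
  for (heading in c("same", "reversed")) {
    probes <- seq(0.01, 0.34, by = 0.03)  # inside part A
    pr <- semantic_predict(probes, bseg, tseg, corr, heading)
    dd <- pr$p
    expect_true(all(diff(dd) > 0))  # strictly monotone proportions
    # round trip back through the inverted pair
    back <- semantic_predict(pr$predicted_s, tseg, bseg, corr, heading)
    expect_equal(back$predicted_s, probes, tolerance = 1e-9)
  }
})
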
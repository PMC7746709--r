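test_that("congruity anchors at 1 for identical responses", {
  m <- matrix(rep(runif(10), 4), nrow = 10)  # 4 participants, identical
  cg <- congruity(long_responses(m))
  expect_equal(cg$congruity, 1)
  expect_equal(cg$mean_distance, 0)
  expect_error(congruity(long_responses(m[, 1, drop = FALSE])), "invalid-input")
})

test_that("congruity is invariant to relabeling and joint rotation", {
  withr::with_seed(21, {
    m <- matrix(runif(50 * 6), nrow = 50)
    base <- congruity(long_responses(m))$congruity
    expect_equal(congruity(long_responses(m[, sample(6)]))$congruity, base)
    expect_equal(congruity(long_responses((m + 0.37) %% 1))$congruity, base)
  })
})

test_that("congruity decreases as wrapped noise grows", {
  withr::with_seed(22, {
    truth <- runif(50)
    cgs <- vapply(c(0.005, 0.02, 0.06, 0.15), function(sd) {
      m <- (matrix(truth, 50, 15) + matrix(rnorm(750, 0, sd), 50, 15)) %% 1
      congruity(long_responses(m))$congruity
    }, numeric(1))
    expect_true(all(diff(cgs) < 0))
  })
})

test_that("random placement baseline is 1/4 of the perimeter", {
  expect_equal(random_response_baseline(), 0.25)
  # brute-force grid integration of E[arc_distance(U, V)]
  g <- (seq_len(400) - 0.5) / 400
  grid_mean <- mean(outer(g, g, arc_distance))
  expect_equal(grid_mean, 0.25, tolerance = 1e-4)
  mc <- random_response_baseline("monte-carlo", n_draws = 2e5, seed = 4)
  expect_equal(mc, 0.25, tolerance = 2e-3)
})

test_that("circular median matches brute force, including wrap cases", {
  expect_equal(circular_median(0.3), 0.3)
  expect_equal(circular_median(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(circular_median(c(0.95, 0.0, 0.05)), 0.0)
  expect_error(circular_median(numeric(0)), "invalid-input")
  withr::with_seed(31, {
    for (rep in 1:300) {
      s <- runif(sample(2:9, 1))
      expect_equal(circular_median(s), brute_force_circular_median(s))
    }
  })
})

test_that("ordering preservation is direction-sensitive", {
  n <- 12
  ident <- (seq_len(n) - 1) / n
  expect_equal(ordering_preservation(ident)$percent_preserved, 100)
  expect_equal(ordering_preservation(rev(ident))$percent_preserved, 0)
  expect_equal(ordering_preservation(rev((seq_len(4) - 1) / 4))$percent_preserved, 0)
  expect_error(ordering_preservation(c(0.1, 0.2)), "invalid-input")
  # rotation does not break preservation
  expect_equal(ordering_preservation((ident + 0.4) %% 1)$percent_preserved, 100)
  # duplicates fall back to stable input order, with a message
  expect_message(ordering_preservation(c(0.1, 0.2, 0.2, 0.4)), "duplicate")
})

test_that("random medians preserve order at the simulated chance rate", {
  base <- ordering_baseline_mc(10, reps = 400, seed = 2)
  # independent simulation with a different seed agrees within MC error
  check <- ordering_baseline_mc(10, reps = 400, seed = 9)
  expect_equal(base, check, tolerance = 0.25 * base)
  expect_lt(base, 30)  # chance is far below systematic preservation
})

test_that("distance to median matches a hand-computed toy table", {
  # P = 3, n = 4: responses constructed around known medians
  m <- rbind(c(0.10, 0.15, 0.20),
             c(0.40, 0.40, 0.40),
             c(0.60, 0.65, 0.70),
             c(0.95, 0.00, 0.05))
  resp <- long_responses(m)
  pred <- tibble::tibble(probe_index = 0:3,
                         predicted_s = c(0.15, 0.50, 0.60, 0.00),
                         valid = TRUE)
  dm <- distance_to_median(resp, pred)
  expect_equal(dm$median_s, c(0.15, 0.40, 0.65, 0.00))
  expect_equal(dm$human_dist, 100 * c(mean(c(0.05, 0, 0.05)), 0,
                                      mean(c(0.05, 0, 0.05)),
                                      mean(c(0.05, 0, 0.05))))
  expect_equal(dm$model_dist, 100 * c(0, 0.10, 0.05, 0))

  # predictions identical to medians give zero model distance
  pred2 <- tibble::tibble(probe_index = 0:3, predicted_s = dm$median_s,
                          valid = TRUE)
  expect_equal(distance_to_median(resp, pred2)$model_dist, rep(0, 4))

  # invalid predictions are excluded pairwise with a message
  pred3 <- pred; pred3$valid[2] <- FALSE
  expect_message(dm3 <- distance_to_median(resp, pred3), "excluding 1")
  expect_equal(nrow(dm3), 3)
})

test_that("wilcoxon signed rank reproduces exact and approximate forms", {
  # all ten differences positive: W = 55, exact p = 2/1024
  out <- wilcoxon_signed_rank(seq(1, 10) + 0.5, 0.5)
  expect_equal(out$w, 55)
  expect_equal(out$p, 2 / 1024, tolerance = 1e-12)
  expect_gt(out$z, 0)

  # symmetric differences: Z near zero
  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3, 4, -4), 0)
  expect_equal(sym$z, 0, tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "undefined-statistic")

  # agreement with stats::wilcox.test on random data
  withr::with_seed(41, {
    for (rep in 1:10) {
      x <- rnorm(15); y <- rnorm(15)
      ours <- wilcoxon_signed_rank(x, y)
      ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("paired t-test matches the closed form", {
  out <- paired_ttest(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(out$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(out$t, 3.873, tolerance = 1e-3)
  expect_equal(out$df, 3)
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), "undefined-statistic")
  withr::with_seed(42, {
    x <- rnorm(20); y <- rnorm(20)
    d <- x - y
    expect_equal(paired_ttest(x, y)$t,
                 mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  })
})

test_that("JZS Bayes factor behaves like a default Bayes factor should", {
  # null-favoring at t = 0
  expect_lt(jzs_bayes_factor(0, 50), 1)
  # monotone increasing in |t|
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 4), jzs_bayes_factor, numeric(1), n1 = 50)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bayes_factor(2, 30), jzs_bayes_factor(-2, 30),
               tolerance = 1e-9)
  expect_error(jzs_bayes_factor(NaN, 50), "invalid-input")
  # quadrature agrees with the seeded Monte-Carlo oracle within 1%
  bf1 <- jzs_bayes_factor(2.2, 40)
  expect_equal(bf1, mc_jzs_bf(2.2, 40, 39, n_draws = 2e5, seed = 3),
               tolerance = 0.01)
  bf2 <- jzs_bayes_factor(2.85, 50, 50)
  expect_equal(bf2, mc_jzs_bf(2.85, 25, 98, n_draws = 2e5, seed = 3),
               tolerance = 0.01)
})

test_that("evidence categories follow the published thresholds", {
  th <- bf10_thresholds()
  expect_equal(unname(th[c("some_h1", "strong_h1", "very_strong_h1")]),
               c(3, 10, 30))
  expect_equal(interpret_bf10(c(50, 15, 5, 1, 0.2, 0.05, 0.01)),
               c("very strong evidence for H1", "strong evidence for H1",
                 "some evidence for H1", "inconclusive",
                 "some evidence for H0", "strong evidence for H0",
                 "very strong evidence for H0"))
})

test_that("model comparison yields tidy per-model statistics", {
  withr::with_seed(51, {
    truth <- runif(50)
    m <- (matrix(truth, 50, 15) + matrix(rnorm(750, 0, 0.03), 50, 15)) %% 1
    resp <- long_responses(m)
    preds <- dplyr::bind_rows(
      tibble::tibble(probe_index = 0:49, predicted_s = truth,
                     model = "good", valid = TRUE),
      tibble::tibble(probe_index = 0:49, predicted_s = (truth + 0.3) %% 1,
                     model = "bad", valid = TRUE))
    cmp <- compare_models(resp, preds)
    td <- tidy(cmp)
    expect_equal(nrow(td), 2)
    expect_lt(td$model_dist[td$model == "good"],
              td$model_dist[td$model == "bad"])
    expect_equal(td$df, rep(49, 2))
    expect_gt(td$bf10[td$model == "bad"], 30)
    gl <- glance(cmp)
    expect_equal(gl$best_model, "good")
    expect_equal(gl$n_probes, 50)
  })
})

test_that("participants split into heading subgroups by forward fraction", {
  probes <- (0:19) / 20
  fwd <- (probes + 0.1) %% 1
  bwd <- (0.9 - probes) %% 1
  resp <- dplyr::bind_rows(
    tibble::tibble(participant = 1, probe_index = 0:19, response_s = fwd),
    tibble::tibble(participant = 2, probe_index = 0:19, response_s = bwd))
  sp <- split_heading_groups(resp)
  expect_equal(sp$direction[sp$participant == 1], "same")
  expect_equal(sp$direction[sp$participant == 2], "reversed")
})
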
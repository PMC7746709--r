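#' Expected along-contour distance of two independent uniform positions
#'
#' The analytic random-placement baseline: for two independent uniform
#' arc positions the expected circular distance is 1/4 of the perimeter.
#' A seeded Monte-Carlo version is available for exact emulation of a
#' finite random model.
#'
#' @param method `"analytic"` (0.25) or `"monte-carlo"`.
#' @param n_draws Number of random pairs for the Monte-Carlo estimate.
#' @param seed Seed for the Monte-Carlo estimate.
#' @return Expected distance as a fraction of perimeter.
#' @export
random_response_baseline <- function(method = c("analytic", "monte-carlo"),
                                     n_draws = 10000, seed = 1) {
  method <- match.arg(method)
  if (method == "analytic") return(0.25)
  with_seed(seed, mean(arc_distance(stats::runif(n_draws), stats::runif(n_draws))))
}

# mean circular distance over all unordered pairs of a response set
mean_pairwise_arc_distance <- function(v) {
  p <- length(v)
  if (p < 2) return(NA_real_)
  d <- outer(v, v, arc_distance)
  sum(d[upper.tri(d)]) / (p * (p - 1) / 2)
}

#' Between-participant response congruity
#'
#' For each probe, the mean circular distance between all unordered pairs
#' of participants' responses; the grand mean over probes is projected
#' onto a 0-1 scale against the random baseline:
#' `congruity = 1 - grand_mean / baseline`. A value of 1 means all
#' responses coincide; 0 means random-level agreement.
#'
#' @param responses Long tibble with columns `probe_index`, `participant`,
#'   `response_s`, and optionally `pair_id`.
#' @param baseline Random baseline, a fraction of perimeter
#'   (default the analytic 0.25; see [random_response_baseline()]).
#' @return Tibble (one row per `pair_id`, or a single row) with columns
#'   `n_probes`, `n_participants`, `mean_distance`, `baseline`,
#'   `congruity`.
#' @export
congruity <- function(responses, baseline = random_response_baseline()) {
  if (dplyr::n_distinct(responses$participant) < 2) {
    stop("invalid-input: congruity needs at least 2 participants")
  }
  grp <- if ("pair_id" %in% names(responses)) c("pair_id") else character(0)
  per_probe <- responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "probe_index")))) |>
    dplyr::summarise(mean_dist = mean_pairwise_arc_distance(.data$response_s),
                     n_participants = dplyr::n(), .groups = "drop")
  per_probe |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_probes = dplyr::n(),
                     n_participants = max(.data$n_participants),
                     mean_distance = mean(.data$mean_dist),
                     baseline = baseline,
                     congruity = 1 - mean(.data$mean_dist) / baseline,
                     .groups = "drop")
}

#' Congruity of model predictions with human responses
#'
#' Treats the model as one virtual participant: per probe, the mean
#' circular distance from the prediction to each response, normalized
#' against the same random baseline as [congruity()].
#'
#' @param responses Long response tibble (see [congruity()]).
#' @param predictions Prediction tibble with `probe_index`,
#'   `predicted_s`, `valid`.
#' @inheritParams congruity
#' @return One-row tibble with `mean_distance`, `baseline`, `congruity`.
#' @export
model_congruity <- function(responses, predictions,
                            baseline = random_response_baseline()) {
  joined <- dplyr::inner_join(
    responses,
    predictions[predictions$valid, c("probe_index", "predicted_s")],
    by = "probe_index")
  per_probe <- joined |>
    dplyr::group_by(.data$probe_index) |>
    dplyr::summarise(
      mean_dist = mean(arc_distance(.data$response_s, .data$predicted_s)),
      .groups = "drop")
  tibble::tibble(n_probes = nrow(per_probe),
                 mean_distance = mean(per_probe$mean_dist),
                 baseline = baseline,
                 congruity = 1 - mean(per_probe$mean_dist) / baseline)
}

#' Circular median (medoid) of arc positions
#'
#' The observed response minimizing the summed circular distance to all
#' responses; ties resolve to the smaller arc position. Restricting the
#' median to observed responses keeps it deterministic and wrap-aware.
#'
#' @param s Numeric vector of arc positions (>= 1).
#' @return A single arc position.
#' @export
circular_median <- function(s) {
  if (length(s) == 0) stop("invalid-input: no responses")
  if (length(s) == 1) return(s %% 1)
  s <- s %% 1
  tot <- rowSums(outer(s, s, arc_distance))
  cand <- s[tot == min(tot)]
  min(cand)
}

#' Order preservation of median responses
#'
#' Sorts the per-probe medians cyclically along the test traversal
#' direction and counts each probe as order-preserving iff its cyclic
#' predecessor and successor in that order are the neighboring probes
#' (i - 1 and i + 1). The rule is direction-sensitive: a fully reversed
#' arrangement scores 0.
#'
#' @param medians Numeric vector of median arc positions, in probe order.
#' @return One-row tibble: `n`, `n_preserved`, `percent_preserved`,
#'   `n_reversals`.
#' @export
ordering_preservation <- function(medians) {
  n <- length(medians)
  if (n < 3) stop("invalid-input: need at least 3 medians")
  if (anyDuplicated(medians)) {
    message("duplicate median positions; stable input order used for ties")
  }
  ord <- order(medians %% 1)  # stable: ties keep probe order
  pos <- match(seq_len(n), ord)
  prv <- ord[((pos - 2) %% n) + 1]
  nxt <- ord[(pos %% n) + 1]
  preserved <- (prv == ((seq_len(n) - 2) %% n) + 1) &
    (nxt == (seq_len(n) %% n) + 1)
  tibble::tibble(n = n, n_preserved = sum(preserved),
                 percent_preserved = 100 * mean(preserved),
                 n_reversals = sum(!preserved))
}

#' Monte-Carlo baseline for order preservation
#'
#' Mean preserved percentage for `n` independently uniform median
#' placements, over seeded replicates.
#'
#' @param n Number of probes. @param reps Replicates. @param seed Seed.
#' @return Mean percent preserved.
#' @export
ordering_baseline_mc <- function(n, reps = 1000, seed = 1) {
  with_seed(seed, mean(vapply(seq_len(reps), function(r) {
    ordering_preservation(stats::runif(n))$percent_preserved
  }, numeric(1))))
}

#' Per-probe distances to the median human response
#'
#' For each probe: the circular median of the responses, the mean
#' participant distance to it, and the prediction's distance to it, both
#' expressed as percentages of the test contour perimeter. Probes whose
#' prediction is invalid are excluded pairwise (with a message).
#'
#' @param responses Long response tibble (`probe_index`, `participant`,
#'   `response_s`).
#' @param predictions Prediction tibble (`probe_index`, `predicted_s`,
#'   `valid`).
#' @return Tibble with columns `probe_index`, `median_s`, `human_dist`,
#'   `model_dist` (percent of perimeter).
#' @export
distance_to_median <- function(responses, predictions) {
  med <- responses |>
    dplyr::group_by(.data$probe_index) |>
    dplyr::summarise(median_s = circular_median(.data$response_s),
                     human_dist = 100 * mean(arc_distance(
                       .data$response_s, circular_median(.data$response_s))),
                     .groups = "drop")
  pr <- predictions[, c("probe_index", "predicted_s", "valid")]
  if (any(!pr$valid)) {
    message(sprintf("excluding %d probe(s) with invalid predictions",
                    sum(!pr$valid)))
    pr <- pr[pr$valid, ]
  }
  dplyr::inner_join(med, pr, by = "probe_index") |>
    dplyr::mutate(model_dist = 100 * arc_distance(.data$predicted_s,
                                                  .data$median_s)) |>
    dplyr::select("probe_index", "median_s", "human_dist", "model_dist")
}

#' Wilcoxon signed-rank test with reported Z
#'
#' Signed-rank test of paired differences with the normal approximation
#' and tie correction for the Z statistic (signed by the direction of the
#' rank sums); the p-value is exact when there are no ties and at most 25
#' nonzero differences, otherwise from the normal approximation.
#'
#' @param x Numeric vector. @param y Paired values or a constant
#'   (default 0).
#' @return One-row tibble: `w` (positive-rank sum), `z`, `p`, `n`
#'   (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = 0) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined-statistic: all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  exact <- n <= 25 && !any(ties > 1)
  if (exact) {
    p_ge <- 1 - stats::psignrank(w_pos - 1, n)
    p_le <- stats::psignrank(w_pos, n)
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(w = w_pos, z = z, p = p, n = n,
                 method = if (exact) "exact" else "normal approximation")
}

#' Paired t-test on matched distance samples
#'
#' One-sample t-test on the paired differences; `df = n - 1`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(x, y) {
  d <- x - y
  if (length(d) < 2) stop("invalid-input: need at least 2 pairs")
  if (stats::sd(d) == 0) stop("undefined-statistic: zero-variance differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' JZS (Cauchy-prior) Bayes factor for a t statistic
#'
#' Evidence for a nonzero effect under a Jeffreys-Zellner-Siow prior: a
#' Cauchy prior with scale `r` on standardized effect size, equivalent to
#' an inverse-gamma(1/2, r^2/2) mixture over the variance ratio g. BF10 is
#' computed by adaptive quadrature of the Rouder integral. With `n2` given
#' the independent two-group form is used (effective sample size
#' `n1 n2 / (n1 + n2)`, df `n1 + n2 - 2`); otherwise the one-sample /
#' paired form (`N = n1`, df `n1 - 1`).
#'
#' @param t Observed t statistic.
#' @param n1 Sample size (first group, or the paired sample).
#' @param n2 Optional second group size.
#' @param r Cauchy prior scale. Default 0.707.
#' @param rel_tol Relative quadrature tolerance.
#' @return BF10 (scalar, > 0).
#' @export
jzs_bayes_factor <- function(t, n1, n2 = NULL, r = 0.707, rel_tol = 1e-8) {
  if (!is.finite(t)) stop("invalid-input: non-finite t")
  stopifnot(n1 >= 2, r > 0)
  if (is.null(n2)) {
    N <- n1; nu <- n1 - 1
  } else {
    stopifnot(n2 >= 2)
    N <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
  }
  f <- function(g) {
    (1 + N * g)^(-0.5) *
      (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) *
      r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
  }
  num <- stats::integrate(f, 0, Inf, rel.tol = rel_tol,
                          subdivisions = 500L)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

#' Interpretive thresholds for BF10
#'
#' Conventional evidence categories: BF10 > 3 'some', > 10 'strong',
#' > 30 'very strong' evidence for H1; mirrored below 1/3, 1/10, 1/30
#' for H0.
#'
#' @return Named numeric vector of thresholds.
#' @export
bf10_thresholds <- function() {
  c(some_h1 = 3, strong_h1 = 10, very_strong_h1 = 30,
    some_h0 = 0.33, strong_h0 = 0.1, very_strong_h0 = 0.03)
}

#' @rdname bf10_thresholds
#' @param bf10 Numeric vector of Bayes factors.
#' @return For `interpret_bf10()`, a character vector of categories.
#' @export
interpret_bf10 <- function(bf10) {
  th <- bf10_thresholds()
  dplyr::case_when(
    bf10 > th["very_strong_h1"] ~ "very strong evidence for H1",
    bf10 > th["strong_h1"] ~ "strong evidence for H1",
    bf10 > th["some_h1"] ~ "some evidence for H1",
    bf10 < th["very_strong_h0"] ~ "very strong evidence for H0",
    bf10 < th["strong_h0"] ~ "strong evidence for H0",
    bf10 < th["some_h0"] ~ "some evidence for H0",
    TRUE ~ "inconclusive"
  )
}

#' Compare correspondence models against human responses
#'
#' For each model: per-probe human and model distances to the median
#' response, a paired t-test across probes, and the JZS Bayes factor.
#' The Bayes factor is reported, by package convention, from the
#' independent two-group formula with both group sizes equal to the
#' number of probes (`bf_design = "two-sample"`); the paired one-sample
#' form is available via `bf_design = "one-sample"`. A
#' Bonferroni-corrected significance level (0.05 divided by the number of
#' models) is included alongside raw p-values.
#'
#' @param responses Long response tibble.
#' @param predictions Prediction tibble for one or several models
#'   (distinguished by the `model` column).
#' @param bf_scale Cauchy prior scale for the Bayes factor.
#' @param bf_design `"two-sample"` or `"one-sample"`.
#' @return Object of class `model_comparison`: list with `per_probe`
#'   (per model and probe distances) and `stats` (per-model t, df, p,
#'   BF10, evidence category). Use [tidy()] / [glance()].
#' @export
compare_models <- function(responses, predictions, bf_scale = 0.707,
                           bf_design = c("two-sample", "one-sample")) {
  bf_design <- match.arg(bf_design)
  models <- unique(predictions$model)
  per_probe <- purrr::map_dfr(models, function(mo) {
    distance_to_median(responses, predictions[predictions$model == mo, ]) |>
      dplyr::mutate(model = mo)
  })
  stats_tbl <- purrr::map_dfr(models, function(mo) {
    dd <- per_probe[per_probe$model == mo, ]
    n <- nrow(dd)
    tt <- tryCatch(paired_ttest(dd$human_dist, dd$model_dist),
                   error = function(e) tibble::tibble(
                     t = NaN, df = n - 1, p = NaN, mean_diff = 0))
    bf <- if (is.finite(tt$t)) {
      if (bf_design == "two-sample") {
        jzs_bayes_factor(tt$t, n, n, r = bf_scale)
      } else {
        jzs_bayes_factor(tt$t, n, r = bf_scale)
      }
    } else NaN
    tibble::tibble(model = mo, n_probes = n,
                   human_dist = mean(dd$human_dist),
                   model_dist = mean(dd$model_dist),
                   t = tt$t, df = tt$df, p = tt$p, bf10 = bf,
                   evidence = ifelse(is.finite(bf), interpret_bf10(bf),
                                     NA_character_))
  })
  structure(list(per_probe = per_probe, stats = stats_tbl,
                 bf_scale = bf_scale, bf_design = bf_design,
                 bonferroni_alpha = 0.05 / length(models)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison: %d model(s), %d probes; BF scale %.3f (%s); Bonferroni alpha %.4f>\n",
              nrow(x$stats), max(x$stats$n_probes), x$bf_scale, x$bf_design,
              x$bonferroni_alpha))
  print(x$stats)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-model comparison statistics
#'
#' @param x A `model_comparison` object. @param ... Unused.
#' @return The per-model stats tibble.
#' @export
tidy.model_comparison <- function(x, ...) x$stats

#' One-row summary of a model comparison
#'
#' @param x A `model_comparison` object. @param ... Unused.
#' @return One-row tibble: number of models and probes, the best model
#'   (smallest mean distance to the median human response).
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$stats),
    n_probes = max(x$stats$n_probes),
    best_model = x$stats$model[which.min(x$stats$model_dist)],
    best_model_dist = min(x$stats$model_dist),
    human_dist = x$stats$human_dist[1],
    bonferroni_alpha = x$bonferroni_alpha)
}

#' Data-driven split of participants into heading subgroups
#'
#' Classifies each participant as responding in the same or reversed
#' cyclic order as the probes, from the fraction of forward steps between
#' their consecutive responses.
#'
#' @param responses Long response tibble ordered by `probe_index` within
#'   participant.
#' @return Tibble: `participant`, `forward_fraction`, `direction`.
#' @export
split_heading_groups <- function(responses) {
  responses |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$probe_index, .by_group = TRUE) |>
    dplyr::summarise(
      forward_fraction = mean((diff(.data$response_s) %% 1) < 0.5),
      .groups = "drop") |>
    dplyr::mutate(direction = ifelse(.data$forward_fraction >= 0.5,
                                     "same", "reversed"))
}
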
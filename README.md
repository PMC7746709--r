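# shapecorr

Point-to-point correspondence between closed 2D contours from semantic
part structure.

When people are asked to mark "the corresponding location" on a second
shape — a dot on an elephant's trunk, where is it on an anteater? — their
answers are highly systematic even when the two outlines are geometrically
very different, or geometrically *identical* but interpreted as different
animals. `shapecorr` is an analysis toolkit for this dot-matching
paradigm, for researchers in visual perception and shape analysis. It
provides:

* **Contour geometry** — arc-length parameterization of closed polygonal
  outlines, equidistant probe sampling, circular distances, bounding-box
  scale normalization, CSV/SVG import.
* **Correspondence models** — four predictors of where responses land on
  the test shape:
  * *semantic part organization*: a probe at proportion
    `p = Δb/ΔB` of its labeled part (Head, legs, Tail, ...) maps to
    `Δt = ΔT·p` into the corresponding part of the test shape, along the
    pair's heading direction — a zero-parameter model driven entirely by
    part-label data;
  * *uniform sampling*: equidistant responses replicating probe order;
  * *curvature*: von Mises turning-angle surprisal
    `u(θ) = log(2π I₀(κ)) − κ cos θ` profiles aligned by dynamic time
    warping;
  * *combined*: semantic parts refined by within-part surprisal
    landmarks (flank prominence ≥ 0.05, magnitude > 0.02).
* **Response statistics** — congruity (`1 − mean distance / random
  baseline`; 1 = perfect agreement, 0 = random), direction-sensitive
  order preservation, circular medians, paired t / Wilcoxon signed-rank
  tests and JZS (Cauchy-prior, scale 0.707) Bayes factors, with
  broom-style `tidy()`/`glance()` accessors.
* **Morphing** — correspondence-driven shape morphs with order-reversal
  filtering.
* **Synthetic data** — seeded generators for labeled animal-like shape
  pairs (different-geometry and ambiguous designs), simulated observers
  with wrapped noise, heading-reversal subgroups and lapses, and noisy
  part labelers, so the whole pipeline is testable without human data.

Everything is tidyverse-native: functions take data frames first and
return tibbles, results plot with `autoplot()`/`plot_*()`.

## Worked example

Simulate an ambiguous pair — one outline, two mirrored interpretations —
with 15 observers responding at the semantically corresponding location
plus wrapped noise, then evaluate all four models:

```r
library(shapecorr)

pair <- generate_pair(quadruped_spec(seed = 5), mode = "ambiguous",
                      heading = "reversed")
resp <- simulate_responses(pair, observer_spec(seed = 11), n_probes = 50,
                           pair_id = "swan_squirrel")
congruity(resp)
#> # A tibble: 1 × 6
#>   pair_id       n_probes n_participants mean_distance baseline congruity
#> 1 swan_squirrel       50             15        0.0375     0.25     0.850

probes <- attr(resp, "probes")
preds <- predict_all_models(pair$base$contour, pair$test$contour,
                            pair$base$segmentation, pair$test$segmentation,
                            pair$corr, probes)
attr(preds, "heading")
#> [1] "reversed"

tidy(compare_models(resp, preds))[, c("model", "human_dist", "model_dist",
                                      "t", "p", "bf10")]
#> # A tibble: 4 × 6
#>   model     human_dist model_dist     t        p    bf10
#> 1 semantic        2.51      0.815 15.1  4.83e-20 7.65e23
#> 2 uniform         2.51     10.2   -9.27 2.37e-12 9.97e11
#> 3 curvature       2.51     10.1   -5.87 3.72e- 7 1.88e 5
#> 4 combined        2.51      1.21   3.97 2.34e- 4 1.67e 2
```

Reading the output: individual observers sit on average 2.5% of the
perimeter from the median response (high congruity, 0.85). The semantic
model predicts the median responses to within 0.8% — better than
individual humans — while uniform sampling and curvature alignment, which
ignore the semantic reinterpretation of the identical geometry, miss by
about 10%; the Bayes factors quantify those misfits. The heading
("reversed") was inferred from the cyclic order of corresponding parts,
and the direction-sensitive order-preservation score is 0% — the medians
run backwards around the test contour, exactly as planted.

`run_pipeline(run_config(...))` chains the full battery
(simulate → label → predict → evaluate) with one master seed and
reproduces its outputs byte-identically; `morph_sequence()` +
`autoplot()` renders correspondence-driven morphs.

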
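# shared fixtures and independent oracles, all built in code

unit_square <- function() {
  closed_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
}

right_triangle <- function() {
  closed_contour(data.frame(x = c(0, 3, 3), y = c(0, 0, 4)))
}

circle_contour <- function(n = 400, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  closed_contour(data.frame(x = r * cos(th), y = r * sin(th)))
}

# two-part segmentation and identity correspondence over labels A, B
two_part_seg <- function() {
  part_segmentation(tibble::tibble(label = c("A", "B"),
                                   s_start = c(0, 0.5), s_end = c(0.5, 0)))
}

identity_corr <- function(labels) {
  label_correspondence(tibble::tibble(base_labels = as.list(labels),
                                      test_labels = as.list(labels)))
}

# wrap a numeric vector as a surprisal profile (u_signed = the vector)
fake_profile <- function(u) {
  structure(tibble::tibble(s = (seq_along(u) - 1) / length(u),
                           theta = u, u_raw = abs(u), u_norm = abs(u),
                           u_signed = u),
            class = c("surprisal_profile", class(tibble::tibble())))
}

long_responses <- function(mat, probes = NULL) {
  # mat: probes x participants matrix of response arc positions
  n <- nrow(mat); p <- ncol(mat)
  tibble::tibble(probe_index = rep(seq_len(n) - 1L, times = p),
                 probe_s = rep(probes %||% ((seq_len(n) - 1) / n), times = p),
                 participant = rep(seq_len(p), each = n),
                 response_s = as.vector(mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# oracle: exhaustive minimum-cost monotone warping path (squared diff cost)
brute_force_dtw_cost <- function(a, b) {
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (acc >= best) return()
    if (i == length(a) && j == length(b)) { best <<- acc; return() }
    if (i < length(a) && j < length(b)) recurse(i + 1, j + 1, acc)
    if (i < length(a)) recurse(i + 1, j, acc)
    if (j < length(b)) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# oracle: direct double-loop circular medoid
brute_force_circular_median <- function(s) {
  s <- s %% 1
  best <- Inf; arg <- NA_real_
  for (c in sort(s)) {
    tot <- 0
    for (v in s) {
      d <- abs(c - v); tot <- tot + min(d, 1 - d)
    }
    if (tot < best - 1e-15) { best <- tot; arg <- c }
  }
  arg
}

# oracle: Monte-Carlo JZS Bayes factor by sampling the g prior
mc_jzs_bf <- function(t, N, nu, r = 0.707, n_draws = 1e6, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- 1 / stats::rgamma(n_draws, shape = 0.5, rate = r^2 / 2)
  num <- mean((1 + N * g)^(-0.5) *
                (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# signed exterior angle sum of a polygon (positive = canonical orientation)
polygon_turning_sum <- function(contour) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  ex <- nx - x; ey <- ny - y
  px <- c(ex[n], ex[-n]); py <- c(ey[n], ey[-n])
  sum(atan2(px * ey - py * ex, px * ex + py * ey))
}
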
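#' Windowed turning-angle profile of a closed contour
#'
#' At each of `m` equidistant arc positions the turning angle is the signed
#' angle between the chord arriving from `window_w / 2` of perimeter behind
#' the sample and the chord leaving towards `window_w / 2` ahead of it
#' (cyclic). Under the canonical clockwise screen orientation, convex
#' turning is positive.
#'
#' @param contour A [closed_contour()].
#' @param m Number of samples (>= 8). Default 200.
#' @param window_w Integration window as a fraction of the perimeter,
#'   centered on the sample (half on each side). Default 0.05.
#' @param start Arc position of the first sample.
#' @param reverse Sample the contour in the reversed traversal direction
#'   (used when a pair's heading is reversed).
#' @return A tibble of class `angular_profile` with columns `s` (arc
#'   position on the contour, in the traversal direction used) and `theta`
#'   (radians, `|theta| <= pi`); attributes `m`, `window_w`.
#' @export
turning_angle_profile <- function(contour, m = 200, window_w = 0.05,
                                  start = 0, reverse = FALSE) {
  if (m < 8) stop("invalid-argument: m must be >= 8")
  if (!(window_w > 0 && window_w < 0.5)) {
    stop("invalid-argument: window_w must lie in (0, 0.5)")
  }
  step <- (seq_len(m) - 1) / m
  s <- if (reverse) (start - step) %% 1 else (start + step) %% 1
  dirn <- if (reverse) -1 else 1
  p0 <- arc_point(contour, s - dirn * window_w / 2)
  pc <- arc_point(contour, s)
  p1 <- arc_point(contour, s + dirn * window_w / 2)
  v1x <- pc$x - p0$x; v1y <- pc$y - p0$y
  v2x <- p1$x - pc$x; v2y <- p1$y - pc$y
  theta <- atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
  structure(tibble::tibble(s = s, theta = theta),
            m = m, window_w = window_w, start = start, reverse = reverse,
            class = c("angular_profile", class(tibble::tibble())))
}

# log I0(kappa), overflow-safe
log_bessel_i0 <- function(kappa) log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa

#' Turning-angle surprisal under a von Mises contour model
#'
#' Turning angles are modeled as draws from a von Mises distribution
#' centered on zero (contours tend to continue straight); the surprisal of
#' a turning angle is its negative log density,
#' `u = log(2 pi I0(kappa)) - kappa cos(theta)`, an even function of the
#' angle (convex and concave turns are treated symmetrically). Three
#' variants are returned:
#'
#' * `u_raw` — the surprisal itself;
#' * `u_norm` — normalized by the maximum surprisal on this contour;
#' * `u_signed` — in `[-1, 1]`: magnitude `u_raw / max(|u_raw|)`, sign
#'   equal to the turning direction (convex positive under the canonical
#'   orientation).
#'
#' @param angles An `angular_profile` from [turning_angle_profile()].
#' @param kappa von Mises concentration, > 0. Default 1.
#' @return A tibble of class `surprisal_profile` with columns `s`, `theta`,
#'   `u_raw`, `u_norm`, `u_signed`; attribute `kappa`.
#' @export
surprisal_profile <- function(angles, kappa = 1) {
  if (!(is.numeric(kappa) && length(kappa) == 1 && kappa > 0)) {
    stop("invalid-argument: kappa must be a positive scalar")
  }
  u <- log_bessel_i0(kappa) + log(2 * pi) - kappa * cos(angles$theta)
  mx <- max(u)
  mxa <- max(abs(u))
  out <- tibble::tibble(
    s = angles$s,
    theta = angles$theta,
    u_raw = u,
    u_norm = if (mx > 0) u / mx else rep(1, length(u)),
    u_signed = if (mxa > 0) sign(angles$theta) * abs(u) / mxa else rep(0, length(u))
  )
  structure(out, kappa = kappa,
            m = attr(angles, "m"), window_w = attr(angles, "window_w"),
            start = attr(angles, "start"), reverse = attr(angles, "reverse"),
            class = c("surprisal_profile", class(tibble::tibble())))
}

#' Convenience wrapper: surprisal profile straight from a contour
#'
#' @inheritParams turning_angle_profile
#' @inheritParams surprisal_profile
#' @export
contour_surprisal <- function(contour, m = 200, window_w = 0.05, kappa = 1,
                              start = 0, reverse = FALSE) {
  surprisal_profile(
    turning_angle_profile(contour, m = m, window_w = window_w,
                          start = start, reverse = reverse),
    kappa = kappa
  )
}
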
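# evaluate code with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

rotate2d <- function(xy, angle) {
  cbind(cos(angle) * xy[, 1] - sin(angle) * xy[, 2],
        sin(angle) * xy[, 1] + cos(angle) * xy[, 2])
}
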
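# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. Keeps every stochastic routine a pure
# function of its seed argument.
withRng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# World-coordinate arrays of a centered grid (orientation identity).
gridCoords <- function(gridShape, spacingMm) {
  lapply(1:3, function(a) {
    (seq_len(gridShape[a]) - 1 - (gridShape[a] - 1) / 2) * spacingMm[a]
  })
}

# Expand axis coordinate vectors into full 3D arrays.
coordArrays <- function(cs, d) {
  list(x = array(rep(cs[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(cs[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(cs[[3]], each = d[1] * d[2]), d))
}
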
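# index reflection with edge duplication: ... 2 1 | 1 2 .. n | n n-1 ...
.mirrorIndex <- function(i, n) {
  i <- as.integer(i) - 1L
  p <- 2L * n
  i <- ((i %% p) + p) %% p
  i[i >= n] <- p - 1L - i[i >= n]
  i + 1L
}

# mirror-pad a matrix by 'pad' pixels on every side
.padMirror <- function(m, pad) {
  ri <- .mirrorIndex(seq.int(1L - pad, nrow(m) + pad), nrow(m))
  ci <- .mirrorIndex(seq.int(1L - pad, ncol(m) + pad), ncol(m))
  m[ri, ci, drop = FALSE]
}

# derive a per-pixel seed from the sampler seed and a linear pixel index,
# kept inside 32-bit integer range; processing order never matters
.pixelSeed <- function(seed, idx) {
  as.integer((as.double(seed) %% 2147483647 + as.double(idx) * 10007) %%
               2147483647)
}

# evaluate a block, preserving the caller's RNG state
.withPreservedRNG <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# coerce to MagnitudeImage where a bare matrix is handy in examples/tests
.asImage <- function(x, spacing = c(1, 1)) {
  if (is(x, "MagnitudeImage")) x else magnitudeImage(x, spacing)
}
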
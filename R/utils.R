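# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed` may be NULL, in which case expr runs on the current
# stream (non-reproducible).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
deriveSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 2654435.0 + stream * 97.0) %% 2147483629)
}

stopIf <- function(cond, ..., class = "fgcnnError") {
  if (cond) {
    stop(errorCondition(paste0(...),
                        class = c(class, "fgcnnError", "error", "condition")))
  }
  invisible(NULL)
}

assertFinite <- function(x, what) {
  stopIf(!all(is.finite(x)), what, " contains non-finite values",
         class = "fgcnnNumericError")
}

# Population standard deviation used by z-scoring helpers; zero-variance
# columns get scale 1 so downstream models never divide by zero.
columnStats <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

applyColumnStats <- function(x, st) {
  sweep(sweep(x, 2L, st$center, "-"), 2L, st$scale, "/")
}
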
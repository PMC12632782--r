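# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# trapezoidal integral of y sampled at spacing dt
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - 0.5 * (y[1] + y[n]))
}
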
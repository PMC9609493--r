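# Internal helpers shared across modules.

# Evaluate expr with a temporary seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.qnorm975 <- stats::qnorm(0.975)

# two-sided p from a z statistic
.p_from_z <- function(z) 2 * stats::pnorm(-abs(z))
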
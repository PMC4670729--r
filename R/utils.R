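# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
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

# Deterministic per-unit seed stream, kept below 2^31.
deriveSeed <- function(seed, k) {
  ((as.numeric(seed) %% 1e6) * 2039 + 7919 * (as.numeric(k) %% 1e5)) %%
    2147483646 + 1
}

# Ordinary least squares of y on t via lm(); returns slope, its SE and R^2.
logLinearFit <- function(tt, y) {
  fit <- lm(y ~ tt)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       r_squared = sm$r.squared)
}

gsStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "growthswitch_error")))
}
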
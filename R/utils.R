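# Internal helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed, kept within 32-bit
# integer range.
childSeeds <- function(seed, n) {
  (as.numeric(seed) * 10007 + 7919 * seq_len(n)) %% .Machine$integer.max
}

stopf <- function(fmt, ..., class = "seizescreen_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

# Empty detected-events table (shared column contract).
emptyEvents <- function() {
  data.frame(start_s = numeric(), end_s = numeric(), duration_s = numeric(),
             peak_amp_mv = numeric(), peak_amp_mult = numeric(),
             n_spikes = integer())
}

# Standard-error of the mean.
sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
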
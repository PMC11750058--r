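# Reproducible substream scheme built on the L'Ecuyer-CMRG generator:
# each (seed, replicate) pair owns an independent stream, and each stage
# of the generator draws from its own substream of that stream. Adding a
# new stage (or drawing more numbers in one stage) therefore never
# perturbs the draws of earlier stages or other replicates.

# Returns the .Random.seed state for (seed, replicate, stage).
rng_state <- function(seed, replicate = 0L, stage = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  if (replicate > 0) for (i in seq_len(replicate)) s <- parallel::nextRNGStream(s)
  if (stage > 0) for (i in seq_len(stage)) s <- parallel::nextRNGSubStream(s)
  s
}

# Evaluates `expr` with the RNG positioned at (seed, replicate, stage),
# restoring the caller's RNG state afterwards.
with_rng_substream <- function(seed, replicate, stage, expr) {
  state <- rng_state(seed, replicate, stage)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  assign(".Random.seed", state, envir = globalenv())
  expr
}
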
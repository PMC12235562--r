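## Evaluate `expr` under a fixed RNG seed, restoring the caller's stream
## afterwards. Keeps seeded stages (simulation, permutation) from
## perturbing each other or the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  expr
}
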
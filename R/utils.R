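# small shared helpers

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round half away from zero for non-negative x (0.5 -> 1), the convention
# used when reconstructing integer confusion counts from printed rates
round_half_up <- function(x) floor(x + 0.5)

# sample() without the length-1 surprise
sample_one <- function(x) x[sample.int(length(x), 1L)]
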
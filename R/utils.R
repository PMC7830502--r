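# Run code with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-stage seed derived from a master seed and a stage name;
# keeps every intermediate product below 2^53 and the result below 2^31.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003
  as.integer((master %% 2147483000 + h * 19441) %% 2147483647)
}
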
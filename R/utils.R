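# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic, enumeration-order-free seed for a searchlight centre:
# mixes the base seed with the integer voxel-grid position of the centre.
centreSeed <- function(seed, centre, voxelSize) {
  idx <- round(centre / voxelSize)
  h <- (idx[1] * 73856093 + idx[2] * 19349663 + idx[3] * 83492791) %%
    1000003
  as.integer((seed + h) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
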
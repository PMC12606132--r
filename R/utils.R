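`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to give
# the synthetic backend per-item RNG seeds that do not depend on batch
# composition.
str_hash <- function(s) {
  x <- utf8ToInt(s)
  h <- 0
  for (c in x) h <- (h * 31 + c) %% 2147480009
  as.integer(h)
}

item_seed <- function(world_seed, ...) {
  key <- paste(..., sep = "|")
  as.integer((as.numeric(world_seed %% 65011) * 33013 + str_hash(key)) %%
               2147483629)
}
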
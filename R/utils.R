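# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# All bitstrings of a given length, as a character vector ordered with the
# first position as the most significant bit ("00", "01", "10", "11").
bitstrings <- function(len) {
  if (len == 0L) return("")
  grid <- expand.grid(rep(list(c("0", "1")), len))[, len:1, drop = FALSE]
  out <- do.call(paste0, grid)
  sort(out)
}
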
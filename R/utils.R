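# Internal helpers shared across modules.

# Base alphabet including the BrdU symbol "B"; alphabetical, BrdU second,
# matching the label vector [f_A, f_BrdU, f_C, f_G, f_T].
BASES5 <- c("A", "B", "C", "G", "T")
BASES4 <- c("A", "C", "G", "T")

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647)
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
  invisible(x)
}
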
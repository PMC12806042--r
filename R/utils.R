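# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards, so seeded functions do not perturb global
# reproducibility. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a sample set (vector, data.frame, matrix) to an n x d numeric matrix.
as_sample_matrix <- function(x, arg = "samples") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop(sprintf("'%s' must contain at least one sample", arg))
  if (!all(is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
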
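# run code under a temporary RNG state so package functions that take an
# explicit seed never disturb the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a bounded child seed from a master seed and a stage counter
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 1009 + 97 * as.numeric(stage)) %% 2147483647
}

# stable small integer from a string (for subject-keyed seed derivation,
# so per-subject streams do not depend on subject order)
seed_from_string <- function(s) {
  v <- utf8ToInt(s)
  sum(v * seq_along(v)) %% 100003
}

row_l2_normalize <- function(x, what = "row") {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop("zero-norm ", what, " (index ", which(nrm == 0)[1L],
         "); cosine distance undefined")
  }
  x / nrm
}
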
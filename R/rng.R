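# Seed plumbing: every stochastic step draws from its own named substream so
# that changing one part of a specification never perturbs unrelated draws.

#' Derive a deterministic substream seed
#'
#' Hashes a master seed together with an arbitrary sequence of labels
#' (strings or integers) into a single integer seed in `[0, 2^31 - 21)`.
#' Used internally so that each draw step of the cohort generator, each
#' cross-validation repetition, each fold-level resampling plan and each
#' permutation has its own reproducible random stream.
#'
#' @param seed Master seed (single number).
#' @param ... Labels identifying the substream (coerced to character).
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "sex") != derive_seed(1, "site")
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
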
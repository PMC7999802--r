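# Deterministic seed fan-out. All randomness in the package flows from one
# master seed through named streams, so that e.g. adding subjects to a
# cohort does not perturb the recordings of earlier subjects, and fold
# assignment is independent of simulation.

.hash_stream <- function(name) {
  acc <- 0
  for (code in utf8ToInt(name)) acc <- (acc * 31 + code) %% 2147483647
  acc
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive child seeds from a master seed
#'
#' Deterministically expands `master` into `n` seeds for the named stream.
#' The first `k` seeds of a stream do not change when `n` grows, and the
#' caller's RNG state is left untouched.
#'
#' @param master Master seed (integer).
#' @param stream Stream name, e.g. `"subjects"`, `"folds"`, `"gmm"`.
#' @param n Number of child seeds.
#' @return An integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, stream, n = 1L) {
  base <- (as.numeric(master) %% 2147483647 + .hash_stream(stream)) %% 2147483647
  .with_seed(as.integer(base), sample.int(2147483646L, n, replace = TRUE))
}
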
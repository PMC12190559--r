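#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`, runs
#' `expr`, and restores the previous state so library internals never disturb
#' user-level randomness.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  expr
}

#' Derive a stage seed from a global seed
#'
#' Stage seeds are pure functions of the global seed so a single `--seed`
#' reproduces every stage. The result always fits in a 32-bit integer.
#'
#' @param seed global integer seed.
#' @param stage stage name (character) or integer offset.
#' @return integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %% 2147483647)
}

# uniform draw in (0, 1]: flips runif's half-open interval
runif_01 <- function(n) 1 - stats::runif(n)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
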
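#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
silu <- function(x) x * sigmoid(x)

#' @keywords internal
siluGrad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb surrounding code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a child seed from a base seed and an index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(index) * 97 + 13) %% 2147483629)
}

#' The five behaviour classes, in fixed reporting order
#'
#' @return character vector `c("cough", "scream", "estrus", "feeding", "normal")`.
#' @export
pigClasses <- function() c("cough", "scream", "estrus", "feeding", "normal")

#' @keywords internal
stopInvalid <- function(...) stop(..., call. = FALSE)
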
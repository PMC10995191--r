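#' Derive a child seed for a pipeline stage
#'
#' All randomness in the package fans out from one integer master seed. Each
#' stage derives its own child seed so stages can be re-run independently and
#' stay reproducible. The derivation is a fixed affine hash of the master seed
#' and the stage label, reduced modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage stage label (character) or integer offset.
#' @return an integer in \code{[1, 2^31 - 2]} usable with \code{set.seed}.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- if (is.character(stage)) {
    sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  } else {
    as.integer(stage)
  }
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m)
  # two rounds of a Lehmer-style mix keep nearby seeds/stages uncorrelated
  x <- (x * 48271 + h * 8191 + 1) %% m
  x <- (x * 16807 + h) %% m
  as.integer(x %% (m - 2)) + 1L
}

# run expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite number in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
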
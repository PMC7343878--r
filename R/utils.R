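# Internal helpers shared across the package.

#' Run code with a locally seeded RNG
#'
#' Evaluates `expr` with `set.seed(seed)` in effect, restoring the caller's
#' RNG state afterwards so library calls never perturb user-level streams.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic replicate seed derivation
#'
#' Replicate seeds are a documented pure function of the master seed, the
#' sweep cell index and the replicate index, so any single replicate can be
#' reproduced in isolation. Kept below 2^31 - 1 (R integers are 32-bit).
#'
#' @param master integer master seed.
#' @param cell 1-based sweep cell index.
#' @param replicate 1-based replicate index.
#' @return an integer seed.
#' @export
replicate_seed <- function(master, cell = 1L, replicate = 1L) {
  as.integer((as.numeric(master) + 999983 * (cell - 1) + (replicate - 1)) %%
               2147483647)
}

# strict ">" with an absolute guard so exact rational ties (1/2 at rho = 0.5,
# 1/5 at rho = 0.2, ...) never activate regardless of double rounding
strictly_exceeds <- function(x, y) x > y + 1e-9

# floor() with the same guard, for the inner-sum limit floor(rho*b/(1-rho))
guarded_floor <- function(x) floor(x + 1e-9)

stop_tip <- function(msg, class) {
  stop(structure(class = c(class, "tipcascade_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
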
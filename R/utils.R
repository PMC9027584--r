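#' @keywords internal
"_PACKAGE"

# Internal validation + RNG helpers shared across modules.

abort_input <- function(msg) stop(structure(
  class = c("dftune_input_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

abort_param <- function(msg) stop(structure(
  class = c("dftune_param_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

abort_contract <- function(msg) stop(structure(
  class = c("dftune_contract_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

check_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_param(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded operations do not perturb the
#' caller's RNG stream. All stochastic operations in the package route their
#' randomness through this helper, which makes every one of them a pure
#' function of its inputs and its `seed` argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_param("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed derivation: one process-wide seed fans out to per-module
# streams so partial pipelines stay reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}
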
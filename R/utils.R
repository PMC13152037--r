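# Internal helpers: scoped RNG and deterministic seed fan-out.

# Run expr under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stage-specific seed from a master seed
#'
#' Fans one master seed out to independent per-stage seeds so that any
#' pipeline stage can be re-run in isolation with the same randomness.
#' The derivation hashes the stage name together with the master seed.
#'
#' @param master Integer master seed.
#' @param stage Character stage name (e.g. "simulate", "fold2").
#' @return A positive integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(master) %% 2147483647 * 31 + h * 2654435) %% 2147483647 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
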
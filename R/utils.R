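## internal helpers

stop_invalid <- function(...) {
  stop(structure(
    class = c("nactct_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state so callers are unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## squared L2 norm of a numeric object
l2sq <- function(x) sum(as.numeric(x)^2)
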
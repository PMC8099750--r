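`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded helpers do
#' not perturb an enclosing simulation.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# Structured one-line log for skipped/rejected tracks; provenance at scale.
log_track_skip <- function(track_id, reason) {
  warning(sprintf("track skipped [%s]: %s", track_id, reason), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
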
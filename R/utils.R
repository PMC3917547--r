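# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's random number generator state afterwards, so that
#' seeded simulation helpers do not perturb the session RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Percentage of n out of total, rounded to `digits` decimals.
pct <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}

# Stop with a message naming the offending configuration field.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Stage-tagged message, silenced unless verbose.
stage_log <- function(verbose, stage, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

# Wrap a pipeline stage so failures carry the stage name.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
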
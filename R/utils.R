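# Internal helpers: deterministic sub-seed derivation, local RNG scope,
# and leveled logging to standard error.

# Mix a master seed with a stream of integers (or strings, hashed per
# character) into a sub-seed in [1, 2^31 - 2]. Linear-congruential mixing
# in double precision; all intermediates stay below 2^53 so the arithmetic
# is exact. Deterministic across platforms and R versions.
mixSeed <- function(master, ...) {
  parts <- list(...)
  h <- (as.numeric(master) %% 2147483647) + 1
  for (p in parts) {
    if (is.character(p)) p <- utf8ToInt(paste(p, collapse = "/"))
    for (v in as.numeric(p)) {
      h <- (h * 48271 + (v %% 2147483647) * 30269 + 11213) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never disturbs user simulations.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.log_levels <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

.log_state <- new.env(parent = emptyenv())
.log_state$threshold <- 20L

#' Set the logging threshold
#'
#' Package messages at or above the chosen level are written to standard
#' error; metric tables and data files are never interleaved with logs.
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- names(.log_levels)[match(.log_state$threshold, .log_levels)]
  .log_state$threshold <- .log_levels[[level]]
  invisible(old)
}

logMsg <- function(level, fmt, ...) {
  if (.log_levels[[level]] >= .log_state$threshold) {
    cat(sprintf("[%s] %s\n", level, sprintf(fmt, ...)), file = stderr())
  }
  invisible(NULL)
}
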
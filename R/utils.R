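#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a pipeline log message when `options(epistrat.verbose = TRUE)`
#' @noRd
es_log <- function(fmt, ...) {
  if (isTRUE(getOption("epistrat.verbose", FALSE))) {
    message("[epistrat] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
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
  force(code)
}
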
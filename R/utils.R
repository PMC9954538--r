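#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the previous RNG state afterwards so callers' random streams are
#' not disturbed. All stochastic operations in the package route through this
#' helper, which is what makes runs reproducible from a single integer.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_eegtrm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "eegtrm_error")))
}
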
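#' Run code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, runs `code`, and restores the state,
#' so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## derive a sub-seed from a base seed; kept below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

stop_if_not_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single finite number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

## first NaN/Inf position in a matrix, as (row, col), or NULL
first_nonfinite <- function(m) {
  bad <- which(!is.finite(m))
  if (length(bad) == 0L) return(NULL)
  i <- bad[1L]
  nr <- nrow(m)
  c(row = ((i - 1L) %% nr) + 1L, col = ((i - 1L) %/% nr) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
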
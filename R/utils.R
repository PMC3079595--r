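#' Run code under a local, restorable RNG seed
#'
#' Evaluates \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so fixture generation never perturbs user
#' simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# rescale a non-negative map to [0, 1] by its maximum; all-zero stays zero
rescale01 <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  m / mx
}

# clamp values into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

stopifnot_mask <- function(m, name = "mask") {
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop(sprintf("'%s' must be a binary {0,1} matrix", name))
  invisible(m)
}
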
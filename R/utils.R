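# Internal helpers shared across modules.

# seconds per minute; rates are min^-1 throughout, frame grids are seconds
SEC_PER_MIN <- 60

#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  force(code)
}

# draw from a normal truncated to [lo, hi] by inverse-CDF
rtruncnorm1 <- function(n, mean, sd, lo = 0, hi = 1) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
}

stop_if_not_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
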
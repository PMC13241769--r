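#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based derivation so streams (per subject, per repeat) are stable:
#' extending a cohort never reshuffles earlier subjects. Result is kept inside
#' the 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param seed master seed (single integer)
#' @param index non-negative stream counter
#' @return an integer seed
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  # splitmix-style odd-constant mixing in double precision, folded mod 2^31-1
  x <- (as.numeric(seed) * 48271 + as.numeric(index) * 69621 + 11) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x)
}

abort_netsig <- function(msg, class) {
  rlang::abort(msg, class = c(class, "netsig_error"))
}

warn_netsig <- function(msg, class) {
  rlang::warn(msg, class = c(class, "netsig_warning"))
}

#' Run code with a local RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded internals never disturb user-level streams.
#' @noRd
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}
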
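# Internal helpers: reproducible named RNG sub-streams, numeric utilities.

#' Derive a child seed from a parent seed and a stream label
#'
#' All randomness in a run flows from one user-supplied seed; module-level
#' sub-streams (trial sequence, interstimulus intervals, respondent behaviour,
#' cohort draws) get independent seeds derived deterministically from the
#' parent seed and a label, so adding draws to one stream never perturbs
#' another.
#'
#' @param seed Integer parent seed.
#' @param label Character stream label.
#' @return A positive integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483629 + 1)
}

# A named RNG stream: an environment carrying its own .Random.seed state.
# rng_eval() swaps the stream state in, evaluates `fn`, and swaps the
# caller's global RNG state back, so streams are isolated from each other
# and from user code.
new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  orig <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  restore_global_seed(orig)
  env
}

restore_global_seed <- function(orig) {
  if (is.null(orig)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", orig, envir = globalenv())
  }
  invisible(NULL)
}

rng_eval <- function(rng, fn) {
  if (is.null(rng)) return(fn())
  orig <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    restore_global_seed(orig)
  })
  fn()
}

# Coerce NULL / integer seed / stream into a stream (NULL stays NULL:
# draws then come from the caller's global RNG).
as_rng <- function(rng) {
  if (is.null(rng) || is.environment(rng)) return(rng)
  if (is.numeric(rng) && length(rng) == 1L) return(new_rng(as.integer(rng)))
  abort("`rng` must be NULL, a single integer seed, or an RNG stream.")
}

#' Round half to even
#'
#' Banker's rounding with a small snap tolerance so that products such as
#' 0.35 * 30 (representable only approximately in binary) land on the exact
#' half before the tie is broken toward the even integer.
#' @keywords internal
round_half_even <- function(x, tol = 1e-9) {
  snapped <- round(x / tol) * tol
  round(snapped)
}

# Truncated-normal sampling by inverse-CDF; exact for the one-dimensional
# case and free of rejection loops.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range.", name, format(x)))
  }
  invisible(x)
}
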
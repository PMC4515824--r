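#' Derive a reproducible child seed
#'
#' A whole cohort is driven by one user-facing seed; every donor, spot and
#' rendered field gets its own stream derived by fixed integer arithmetic so
#' that adding a stage never perturbs the draws of another.
#'
#' @param seed integer master seed.
#' @param index integer index of the child stream (donor number, spot number).
#' @param salt integer namespace for the stage (cohort, capture, render, ...).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index = 1L, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(index) * 16807 + as.numeric(salt) * 69621
  as.integer(s %% 2147483647)
}

#' Truncated normal draws with bounded retries
#'
#' Rejection sampling from Normal(mean, sd) restricted to `[lower, upper]`.
#' Used for donor-to-donor variation in class fractions; errors out rather
#' than looping forever when the band has negligible mass.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @param max_tries retry budget per draw.
#' @return Numeric vector of length `n`.
#' @export
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf, max_tries = 1000L) {
  if (upper <= lower) stop("rtrunc_norm: upper bound must exceed lower bound")
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lower && x <= upper) {
        out[i] <- x
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("rtrunc_norm: no draw inside [", lower, ", ", upper,
                  "] after ", max_tries, " tries")
  }
  out
}

# internal: check a vector is a probability simplex
assert_simplex <- function(p, what = "mixture", tol = 1e-9) {
  if (any(p < -tol)) stop(what, " has negative entries")
  if (abs(sum(p) - 1) > tol) stop(what, " does not sum to 1 (sum = ", sum(p), ")")
  invisible(TRUE)
}
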
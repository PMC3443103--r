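#' Time-strengthening single-bond dissociation law
#'
#' A newly formed receptor-ligand bond under a constant pulling force `F`
#' dissociates at a rate that decreases with bond age,
#' \deqn{k(F, t) = k(F, 0) / (1 + a(F) \, t),}
#' where `k(F, 0)` is the initial off-rate and `a(F)` the bond-strengthening
#' (maturation) rate. `a = 0` recovers a memoryless exponential bond. Both
#' parameters depend on the applied force but are constants within one law.
#'
#' @param k0 Initial off-rate `k(F, 0)` in 1/s; must be positive.
#' @param a Strengthening rate `a(F)` in 1/s; must be non-negative.
#' @param force Optional force in pN at which this law applies (metadata
#'   only; it does not enter any computation).
#'
#' @return An object of class `bond_law`: a list with elements `k0`, `a`,
#'   `force`.
#' @examples
#' law <- bond_law(k0 = 1.277, a = 2.270, force = 15.84)
#' off_rate(law, c(0, 1, 5))
#' bond_survival(law, c(0, 1, 5))
#' @export
bond_law <- function(k0, a = 0, force = NA_real_) {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.finite(k0),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(force), length(force) == 1L)
  if (k0 <= 0) stop("initial off-rate 'k0' must be positive")
  if (a < 0) stop("strengthening rate 'a' must be non-negative")
  structure(list(k0 = k0, a = a, force = force), class = "bond_law")
}

#' @export
print.bond_law <- function(x, ...) {
  cat(sprintf("Bond law: k(F,0) = %.4g /s, a(F) = %.4g /s", x$k0, x$a))
  if (is.finite(x$force)) cat(sprintf("  [F = %.3g pN]", x$force))
  cat("\n")
  invisible(x)
}

#' Instantaneous dissociation rate of a strengthening bond
#'
#' Evaluates `k(F, t) = k0 / (1 + a t)` at bond age `t`.
#'
#' @param law A [bond_law()].
#' @param t Bond age(s) in seconds; must be non-negative.
#' @return Dissociation rate(s) in 1/s, non-increasing in `t`.
#' @export
off_rate <- function(law, t) {
  stopifnot(inherits(law, "bond_law"), is.numeric(t))
  if (any(t < 0)) stop("bond age 't' must be non-negative")
  law$k0 / (1 + law$a * t)
}

#' Survival probability of a strengthening bond
#'
#' Closed-form survivor function of the time-strengthening law:
#' \deqn{s(t) = (1 + a t)^{-k_0 / a},}
#' i.e. `exp(-k0 t)` in the limit `a = 0`. This is exactly
#' `exp(-integral of off_rate from 0 to t)`.
#'
#' @inheritParams off_rate
#' @return Surviving fraction(s) in `[0, 1]`.
#' @export
bond_survival <- function(law, t) {
  stopifnot(inherits(law, "bond_law"), is.numeric(t))
  if (any(t < 0)) stop("bond age 't' must be non-negative")
  if (law$a == 0) exp(-law$k0 * t) else (1 + law$a * t)^(-law$k0 / law$a)
}

#' Quantile transform for bond lifetimes
#'
#' Analytic inverse of [bond_survival()]: maps a uniform(0, 1] variate `u`
#' to the duration `t` with `s(t) = u`,
#' \deqn{t = (u^{-a/k_0} - 1) / a,}
#' or `-log(u)/k0` when `a = 0`. Feeding i.i.d. uniforms through this
#' transform samples bond lifetimes from the law.
#'
#' @param law A [bond_law()].
#' @param u Survival quantile(s) in (0, 1].
#' @return Duration(s) in seconds; `sample_duration(law, 1)` is 0.
#' @seealso [rbond()] for direct random sampling.
#' @export
sample_duration <- function(law, u) {
  stopifnot(inherits(law, "bond_law"), is.numeric(u))
  if (any(u <= 0 | u > 1)) stop("'u' must lie in (0, 1]")
  if (law$a == 0) -log(u) / law$k0 else (u^(-law$a / law$k0) - 1) / law$a
}

#' Random bond lifetimes
#'
#' @param n Number of lifetimes to draw.
#' @param law A [bond_law()].
#' @return `n` lifetimes in seconds, sampled via [sample_duration()].
#' @export
rbond <- function(n, law) {
  sample_duration(law, stats::runif(n))
}

#' Conditional (left-truncated) survivor function
#'
#' Survivor function of a bond given that it already survived to
#' `floor_s`: `s(t) / s(floor_s)` for `t >= floor_s`. This is the curve an
#' arrest detector blind below `floor_s` actually observes.
#'
#' @param law A [bond_law()].
#' @param floor_s Truncation time in s.
#' @return A function of time, evaluable by [log_msd()] and friends.
#' @export
conditional_survival <- function(law, floor_s) {
  stopifnot(inherits(law, "bond_law"), floor_s >= 0)
  s0 <- bond_survival(law, floor_s)
  function(t) bond_survival(law, pmax(t, floor_s)) / s0
}
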
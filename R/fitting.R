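#' Log-time evaluation grid for survival-curve fitting
#'
#' The 19-point grid used throughout the package to compare survival
#' curves: `t = 0` and `t_i = (1.25^i - 1)/10` for `i = 1, ..., 18`,
#' spanning `[0, ~5.45]` s with points concentrated at short times where
#' most rupture events occur.
#'
#' @return A strictly increasing numeric vector of length 19 starting at 0.
#' @export
fit_grid <- function() {
  c(0, (1.25^(1:18) - 1) / 10)
}

#' Mean squared difference between log-survival curves
#'
#' The fitting criterion for all survival-curve comparisons: the mean over
#' grid points of the squared difference between the natural logarithms of
#' the predicted and observed surviving fractions. Grid points where either
#' curve is non-positive are excluded (the log is undefined there; for an
#' empirical curve this happens after the last event).
#'
#' @param predicted A [bond_law()], [survival_curve()], or function of time.
#' @param observed A [survival_curve()] (evaluated as a step function) or
#'   any object accepted for `predicted`.
#' @param grid Evaluation times; defaults to [fit_grid()].
#' @return Non-negative scalar; 0 iff the curves agree at every usable
#'   grid point.
#' @export
log_msd <- function(predicted, observed, grid = fit_grid()) {
  sp <- surv_at(predicted, grid)
  so <- surv_at(observed, grid)
  use <- is.finite(so) & so > 0
  if (!any(use)) stop("no usable grid points (all observed survival <= 0)")
  # a prediction of (numerically) zero survival where events were observed
  # is heavily penalized, not silently dropped
  sp <- pmax(sp[use], 1e-12)
  mean((log(sp) - log(so[use]))^2)
}

#' Fit the two-parameter strengthening law to a survival curve
#'
#' Finds the `(k0, a)` pair minimizing [log_msd()] between the closed-form
#' survivor function and an observed survival curve on the log-time grid.
#' A coarse log-spaced grid search over `(k0, a)` in `[1e-3, 50]^2`
#' (plus the pure-exponential boundary `a = 0`) seeds a Nelder-Mead
#' refinement in log-parameter space.
#'
#' When the observed curve comes from a detector that is blind below a
#' duration floor (see [detection_floor()]), the recorded durations are
#' left-truncated: every observed arrest already survived to the floor.
#' Passing the floor as `truncation` fits the conditional survivor
#' `s(t) / s(truncation)` instead of `s(t)`, which recovers the generating
#' parameters without the bias of renormalizing by an extrapolated initial
#' count.
#'
#' @param observed A [survival_curve()] with at least 5 positive-survival
#'   points.
#' @param grid Evaluation times for the criterion; defaults to [fit_grid()].
#'   With nonzero `truncation`, points below it are dropped.
#' @param truncation Left-truncation time in s (default 0: none).
#' @return An object of class `bond_fit`: list with `law` (the fitted
#'   [bond_law()]), `msd` (minimized criterion), and `grid`.
#' @examples
#' law <- bond_law(1.277, 2.270)
#' curve <- survival_curve(fit_grid(), bond_survival(law, fit_grid()))
#' fit_bond_law(curve)
#' @export
fit_bond_law <- function(observed, grid = fit_grid(), truncation = 0) {
  stopifnot(inherits(observed, "survival_curve"), truncation >= 0)
  if (sum(observed$survival > 0) < 5L)
    stop("need at least 5 points with positive survival")
  if (truncation > 0) grid <- grid[grid >= truncation]

  obj <- function(k0, a) {
    law <- bond_law(k0, a)
    pred <- if (truncation > 0) {
      s0 <- bond_survival(law, truncation)
      function(t) bond_survival(law, t) / s0
    } else law
    log_msd(pred, observed, grid)
  }

  k0s <- exp(seq(log(1e-3), log(50), length.out = 25))
  as_ <- c(0, exp(seq(log(1e-3), log(50), length.out = 24)))
  coarse <- expand.grid(k0 = k0s, a = as_)
  vals <- mapply(obj, coarse$k0, coarse$a)
  best <- coarse[which.min(vals), ]

  # refine in log space; a is floored well below resolvable strengthening
  start <- c(log(best$k0), log(max(best$a, 1e-8)))
  fn <- function(p) {
    p <- pmin(pmax(p, log(1e-10)), log(1e4))
    obj(exp(p[1]), exp(p[2]))
  }
  opt <- stats::optim(start, fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  par <- pmin(pmax(opt$par, log(1e-10)), log(1e4))
  k0 <- exp(par[1]); a <- exp(par[2])
  if (a < 1e-7) a <- 0
  msd <- obj(k0, a)
  structure(list(law = bond_law(k0, a), msd = msd, grid = grid),
            class = "bond_fit")
}

#' @export
print.bond_fit <- function(x, ...) {
  cat(sprintf("Strengthening-law fit: k(F,0) = %.4g /s, a(F) = %.4g /s, MSD = %.3g\n",
              x$law$k0, x$law$a, x$msd))
  invisible(x)
}

#' Bell-type exponential force dependence of a rate
#'
#' Represents `value(F) = value(0) * exp(slope * F)`: the empirical
#' exponential increase of a kinetic rate with applied force.
#'
#' @param zero_force_value Rate at zero force, 1/s; must be positive.
#' @param slope Exponential sensitivity to force, 1/pN.
#' @return An object of class `bell_law`.
#' @export
bell_law <- function(zero_force_value, slope) {
  stopifnot(is.numeric(zero_force_value), length(zero_force_value) == 1L,
            is.numeric(slope), length(slope) == 1L)
  if (zero_force_value <= 0) stop("'zero_force_value' must be positive")
  structure(list(zero_force_value = zero_force_value, slope = slope),
            class = "bell_law")
}

#' @export
print.bell_law <- function(x, ...) {
  cat(sprintf("Bell law: value(F) = %.4g * exp(%.4g * F)  [F in pN]\n",
              x$zero_force_value, x$slope))
  invisible(x)
}

#' Fit a Bell law through (force, rate) pairs
#'
#' Ordinary least squares of `log(value)` on `force`. With all forces
#' identical (including a single point) the slope is defined as 0 and the
#' zero-force value as the geometric mean of the values, so the force-free
#' single-condition case degrades gracefully.
#'
#' @param force Forces in pN.
#' @param value Rates in 1/s, all positive.
#' @return A [bell_law()].
#' @examples
#' # initial off-rates of ICAM-1/anti-ICAM-1 bonds at three flow forces
#' fit_bell(c(8.80, 15.84, 26.4), c(0.519, 1.277, 4.934))
#' @export
fit_bell <- function(force, value) {
  stopifnot(is.numeric(force), is.numeric(value),
            length(force) == length(value), length(force) >= 1L)
  if (any(value <= 0)) stop("all 'value' entries must be positive")
  if (diff(range(force)) == 0)
    return(bell_law(exp(mean(log(value))), 0))
  fit <- stats::lm(log(value) ~ force)
  co <- unname(stats::coef(fit))
  bell_law(exp(co[1]), co[2])
}

#' Evaluate a Bell law at a force
#'
#' @param bell A [bell_law()].
#' @param force Force(s) in pN.
#' @return Rate(s) in 1/s.
#' @export
eval_bell <- function(bell, force) {
  stopifnot(inherits(bell, "bell_law"), is.numeric(force))
  bell$zero_force_value * exp(bell$slope * force)
}

#' Write / read bond-law and Bell-law parameters as JSON
#'
#' Bond laws are stored with keys `k0`, `a`, `force_pN`; Bell laws with
#' keys `k_at_zero_force`, `slope_per_pN`.
#'
#' @param x A [bond_law()] or [bell_law()].
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_law_json <- function(x, path) {
  if (inherits(x, "bond_law")) {
    obj <- list(k0 = x$k0, a = x$a, force_pN = x$force)
  } else if (inherits(x, "bell_law")) {
    obj <- list(k_at_zero_force = x$zero_force_value, slope_per_pN = x$slope)
  } else stop("'x' must be a bond_law or bell_law")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_law_json
#' @export
read_law_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$k0)) {
    force <- if (is.null(obj$force_pN) || is.na(obj$force_pN)) NA_real_ else obj$force_pN
    bond_law(obj$k0, obj$a, force)
  } else if (!is.null(obj$k_at_zero_force)) {
    bell_law(obj$k_at_zero_force, obj$slope_per_pN)
  } else stop("unrecognized law JSON: ", path)
}
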
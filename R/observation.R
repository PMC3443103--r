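#' Detect arrests in a bead trajectory
#'
#' A bead is classified as arrested at frame `i` when its displacement over
#' the following `window` seconds stays below `displacement_threshold`.
#' Maximal runs of consecutive qualifying frames are merged into single
#' arrest events; the apparent duration of an event spans from the first
#' qualifying frame to the end of the last qualifying window. Events whose
#' last qualifying window touches the end of the record are flagged
#' censored (the arrest may continue beyond the recording).
#'
#' @param traj A data frame with columns `time_s` (strictly increasing,
#'   nominally uniform frame spacing) and `x_um` (position along the flow).
#' @param displacement_threshold Maximum displacement in um counted as
#'   "arrested" (default 0.5).
#' @param window Forward time window in s over which displacement is
#'   measured (default 0.2).
#' @return A data frame with one row per event: `start_s`, `d_app_s`
#'   (apparent duration), `censored`.
#' @seealso [correct_duration()] for converting apparent to true durations.
#' @export
detect_arrests <- function(traj, displacement_threshold = 0.5, window = 0.2) {
  stopifnot(is.data.frame(traj), all(c("time_s", "x_um") %in% names(traj)))
  t <- traj$time_s; x <- traj$x_um
  if (is.unsorted(t, strictly = TRUE)) stop("trajectory times must be strictly increasing")
  frame <- stats::median(diff(t))
  w <- max(1L, round(window / frame))
  n <- length(t)
  if (n <= w) stop("trajectory shorter than the detection window")

  starts <- seq_len(n - w)
  quals <- abs(x[starts + w] - x[starts]) < displacement_threshold
  if (!any(quals)) {
    return(data.frame(start_s = numeric(0), d_app_s = numeric(0),
                      censored = logical(0)))
  }
  r <- rle(quals)
  ends_idx <- cumsum(r$lengths)
  begins_idx <- ends_idx - r$lengths + 1L
  keep <- r$values
  b <- begins_idx[keep]; e <- ends_idx[keep]
  data.frame(start_s = t[b],
             d_app_s = t[e] + window - t[b],
             censored = (e == n - w))
}

#' Correct an apparent arrest duration
#'
#' The detection criterion (displacement below `threshold` over `window`)
#' both truncates and pads the measured arrest: the true duration is
#' recovered as
#' \deqn{d_{true} = d_{app} + \delta t - 2 \delta x / u_p,}
#' where `u_p` is the free bead velocity.
#'
#' @param d_app Apparent duration(s) in s.
#' @param window Detection window `delta t` in s (default 0.2).
#' @param threshold Displacement threshold `delta x` in um (default 0.5).
#' @param u_p Free bead velocity in um/s; must be positive.
#' @return Corrected duration(s) in s.
#' @export
correct_duration <- function(d_app, window = 0.2, threshold = 0.5, u_p) {
  stopifnot(is.numeric(d_app), is.numeric(u_p))
  if (any(u_p <= 0)) stop("'u_p' must be positive")
  d_app + window - 2 * threshold / u_p
}

#' Minimum detectable true arrest duration
#'
#' An arrest shorter than `window - 2 threshold / u_p` cannot satisfy the
#' detection criterion at all; the instrument is blind below this floor.
#'
#' @inheritParams correct_duration
#' @return Duration floor in s (may be 0 or negative at low velocity, in
#'   which case every arrest is detectable).
#' @export
detection_floor <- function(window = 0.2, threshold = 0.5, u_p) {
  correct_duration(0, window, threshold, u_p)
}

#' Build an empirical survival curve from arrest durations
#'
#' Kaplan-Meier survivor function evaluated on a time grid, with optional
#' right censoring (arrests still in progress at record end). The per-point
#' uncertainty is the binomial standard deviation
#' `sqrt(s (1 - s) / N_t)` with `N_t` the total number of events.
#'
#' @param durations Arrest durations in s (corrected, see
#'   [correct_duration()]).
#' @param grid Times at which to tabulate the curve; defaults to
#'   [fit_grid()].
#' @param censored Logical vector: `TRUE` where the duration is a lower
#'   bound (event still arrested at record end). Default: none censored.
#' @return A [survival_curve()] with `n_total = length(durations)`.
#' @export
build_survival <- function(durations, grid = fit_grid(), censored = NULL) {
  stopifnot(is.numeric(durations), length(durations) >= 1L)
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  stopifnot(length(censored) == length(durations))
  n <- length(durations)
  # timefix would merge distinct short durations when the sample contains
  # very long ones (heavy-tailed laws); durations here are exact numerics
  fit <- survival::survfit(survival::Surv(durations, !censored) ~ 1,
                           timefix = FALSE)
  s <- summary(fit, times = grid, extend = TRUE)$surv
  sdv <- sqrt(pmax(s * (1 - s), 0) / n)
  survival_curve(grid, s, sd = sdv, n_total = n)
}

#' Extrapolate the true initial number of arrests
#'
#' Arrests shorter than the detection floor are invisible, so the observed
#' count at time zero underestimates the number of bonds formed. The early
#' part of the surviving-count curve (`t <= cutoff`) is nearly linear; an
#' ordinary least-squares line through `(t, s(t) * n_total)` for those
#' points, evaluated at `t = 0`, estimates the true initial count.
#'
#' @param curve A [survival_curve()] with known `n_total`.
#' @param cutoff Use points with `t <= cutoff` (default 0.5 s).
#' @return Extrapolated initial event count (scalar).
#' @seealso [renormalize_initial()] to rescale the curve with this count.
#' @export
extrapolate_true_count <- function(curve, cutoff = 0.5) {
  stopifnot(inherits(curve, "survival_curve"), is.finite(curve$n_total))
  use <- curve$times <= cutoff
  if (sum(use) < 2L) stop("need at least 2 grid points with t <= cutoff")
  t <- curve$times[use]
  count <- curve$survival[use] * curve$n_total
  if (stats::var(t) == 0) stop("degenerate time points below cutoff")
  fit <- stats::lm(count ~ t)
  unname(stats::coef(fit)[1])
}

#' @rdname extrapolate_true_count
#' @param ... Passed to `extrapolate_true_count`.
#' @export
renormalize_initial <- function(curve, ...) {
  n0 <- extrapolate_true_count(curve, ...)
  s <- pmin(curve$survival * curve$n_total / n0, 1)
  survival_curve(curve$times, s,
                 sd = if (is.null(curve$sd)) NULL else
                   sqrt(pmax(s * (1 - s), 0) / n0),
                 n_total = n0)
}

#' Binding frequency per unit path length
#'
#' The number of recorded binding events divided by the total trajectory
#' length scanned by the monitored beads, with Poisson standard deviation
#' `sqrt(n) / L`.
#'
#' @param n_events Number of binding events.
#' @param path_length_mm Total trajectory length in mm; must be positive.
#' @return A list with elements `f` (events/mm) and `sd`.
#' @export
binding_frequency <- function(n_events, path_length_mm) {
  stopifnot(n_events >= 0)
  if (path_length_mm <= 0) stop("'path_length_mm' must be positive")
  list(f = n_events / path_length_mm,
       sd = sqrt(n_events) / path_length_mm)
}

#' Subtract the nonspecific contribution from a survival curve
#'
#' Observed arrests are a two-component mixture: a fraction `p_ns` are
#' nonspecific (measured with isotype-control beads) and the rest specific.
#' The specific survivor function is recovered by de-mixing:
#' \deqn{s_{spec}(t) = \frac{s_{obs}(t) - p_{NS} \, s_{NS}(t)}{1 - p_{NS}},}
#' clamped to `[0, 1]`. The event count is scaled by `1 - p_ns`.
#'
#' @param observed A [survival_curve()] of all arrests.
#' @param ns_curve A [survival_curve()] (or [bond_law()]) describing
#'   nonspecific arrests, evaluated on the observed grid.
#' @param p_ns Nonspecific fraction in `[0, 1)`.
#' @return A [survival_curve()] for specific arrests only.
#' @export
subtract_nonspecific <- function(observed, ns_curve, p_ns) {
  stopifnot(inherits(observed, "survival_curve"), p_ns >= 0)
  if (p_ns >= 1) stop("'p_ns' must be below 1")
  s_ns <- surv_at(ns_curve, observed$times)
  s <- pmin(pmax((observed$survival - p_ns * s_ns) / (1 - p_ns), 0), 1)
  survival_curve(observed$times, s,
                 sd = if (is.null(observed$sd)) NULL else observed$sd / (1 - p_ns),
                 n_total = observed$n_total * (1 - p_ns))
}

#' Specific fraction from a fold increase in arrest frequency
#'
#' If replacing control beads by ligand-specific beads multiplies the
#' arrest frequency by `fold_increase`, the fraction of arrests on the
#' specific beads that are ligand-mediated is
#' `(fold - 1) / fold`.
#'
#' @param fold_increase Ratio of specific-bead to control-bead arrest
#'   frequency; must be >= 1.
#' @return Fraction in `[0, 1)`.
#' @examples
#' specific_fraction(3.45) # ~0.71
#' @export
specific_fraction <- function(fold_increase) {
  stopifnot(is.numeric(fold_increase))
  if (any(fold_increase < 1)) stop("'fold_increase' must be >= 1")
  (fold_increase - 1) / fold_increase
}

#' Average dissociation rate over an initial time window
#'
#' Summarizes early bond stability as the constant rate that would produce
#' the observed survival at the horizon: `-log(s(horizon)) / horizon`.
#' For a pure exponential bond this equals its off-rate at any horizon.
#'
#' @param x A [bond_law()] or [survival_curve()].
#' @param horizon Averaging window in s (default 0.5).
#' @return Rate in 1/s.
#' @export
mean_off_rate <- function(x, horizon = 0.5) {
  stopifnot(horizon > 0)
  s <- surv_at(x, horizon)
  if (s <= 0) stop("survival at the horizon is not positive")
  -log(s) / horizon
}
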
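#' Survival curve container
#'
#' Holds the fraction of attachments still intact as a function of time
#' since formation, together with per-point uncertainty and the number of
#' events underlying the curve.
#'
#' @param times Times in seconds, strictly increasing, first value 0.
#' @param survival Surviving fraction at each time, in `[0, 1]`.
#' @param sd Optional per-point standard deviation (binomial, see
#'   [build_survival()]); `NULL` for theoretical curves.
#' @param n_total Number of events underlying the curve (`NA` for
#'   theoretical curves).
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(times, survival, sd = NULL, n_total = NA_real_) {
  stopifnot(is.numeric(times), is.numeric(survival),
            length(times) == length(survival), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (times[1] < 0) stop("'times' must start at or after 0")
  if (any(survival < -1e-12 | survival > 1 + 1e-12))
    stop("'survival' values must lie in [0, 1]")
  survival <- pmin(pmax(survival, 0), 1)
  if (!is.null(sd)) stopifnot(length(sd) == length(times), all(sd >= 0))
  structure(list(times = as.numeric(times), survival = as.numeric(survival),
                 sd = sd, n_total = n_total),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d points on [%.3g, %.3g] s",
              length(x$times), min(x$times), max(x$times)))
  if (is.finite(x$n_total)) cat(sprintf(", n = %.6g events", x$n_total))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(time_s = x$times, survival = x$survival,
             sd = if (is.null(x$sd)) NA_real_ else x$sd,
             n_total = x$n_total)
}

# Evaluate a survival model or empirical curve at arbitrary times.
# Empirical curves are step functions: the value at t is the recorded value
# at the largest tabulated time <= t (1 before the first point).
surv_at <- function(x, t) {
  if (inherits(x, "bond_law")) return(bond_survival(x, t))
  if (inherits(x, "survival_curve")) {
    # step evaluation: value at the largest tabulated time <= t, with a
    # relative tolerance so serialization round-off cannot shift a grid
    # point past its own tabulated time
    eps <- 1e-9 * pmax(1, abs(t))
    idx <- findInterval(t + eps, x$times)
    return(ifelse(idx == 0L, 1, x$survival[pmax(idx, 1L)]))
  }
  if (is.function(x)) return(x(t))
  stop("cannot evaluate survival for object of class ", class(x)[1])
}

#' Write / read a survival curve as TSV
#'
#' Plain-text serialization with columns `time_s`, `survival`, `sd`,
#' `n_total` (UTF-8, '.' decimal separator).
#'
#' @param curve A [survival_curve()].
#' @param path File path.
#' @return `read_survival_tsv` returns a [survival_curve()];
#'   `write_survival_tsv` returns `path` invisibly.
#' @export
write_survival_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("time_s", "survival")
  if (!all(req %in% names(d)))
    stop("survival TSV must have columns 'time_s' and 'survival'")
  sd <- if ("sd" %in% names(d) && !all(is.na(d$sd))) d$sd else NULL
  n_total <- if ("n_total" %in% names(d)) d$n_total[1] else NA_real_
  survival_curve(d$time_s, d$survival, sd = sd, n_total = n_total)
}
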
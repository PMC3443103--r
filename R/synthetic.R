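#' Ground truth for synthetic flow-chamber datasets
#'
#' Defines the generating model for synthetic arrest-duration datasets:
#' per-condition specific bond laws (monomer) or force levels plus
#' rebinding rate (dimer), per-condition nonspecific laws, the pooled
#' nonspecific fraction, event counts, and the detection geometry.
#'
#' The defaults emulate the regime of the ICAM-1/anti-ICAM-1 flow-chamber
#' study: three monomer conditions at the reference shear rates with the
#' loaded rows of [icam1_reference_parameters()] as specific laws;
#' nonspecific laws with strengthening rate 2/s whose first-500-ms average
#' off-rates are 2.53, 1.74 and 1.75 1/s; and a pooled nonspecific
#' fraction of 0.22.
#'
#' @param conditions Data frame with columns `shear_per_s` and `tether`
#'   (`"monomer"` or `"dimer"`), one row per condition.
#' @param specific_laws List, one element per condition: a [bond_law()]
#'   for monomer conditions, or a list `list(levels = force_levels,
#'   k_r = rate)` for dimer conditions.
#' @param nonspecific_laws List of [bond_law()], one per condition.
#' @param p_ns Pooled nonspecific fraction of arrests, in `[0, 1)`.
#' @param n_events Events generated per condition (before detectability
#'   filtering); scalar or one per condition.
#' @param detection List with `window` (s), `threshold` (um), `frame` (s).
#' @param geometry A [chamber_geometry()].
#' @param seed Integer seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(conditions = NULL, specific_laws = NULL,
                         nonspecific_laws = NULL, p_ns = 0.22,
                         n_events = 1000,
                         detection = list(window = 0.2, threshold = 0.5,
                                          frame = 0.02),
                         geometry = chamber_geometry(), seed = 1L) {
  if (is.null(conditions)) {
    tab <- icam1_reference_parameters()[-1, ]
    conditions <- data.frame(shear_per_s = tab$shear_per_s,
                             tether = "monomer")
    specific_laws <- Map(bond_law, tab$k0, tab$a, tab$force_pN)
    # nonspecific strengthening fixed at 2/s; k0 chosen so that the mean
    # off-rate over the first 0.5 s, -log s(0.5)/0.5 = k0 log(2), matches
    # the reference nonspecific rates
    ns_rate <- c(2.53, 1.74, 1.75)
    nonspecific_laws <- lapply(ns_rate / log(2), bond_law, a = 2)
  }
  stopifnot(is.data.frame(conditions),
            all(c("shear_per_s", "tether") %in% names(conditions)),
            all(conditions$tether %in% c("monomer", "dimer")),
            length(specific_laws) == nrow(conditions),
            length(nonspecific_laws) == nrow(conditions),
            p_ns >= 0, p_ns < 1, all(n_events >= 1))
  n_events <- rep_len(n_events, nrow(conditions))
  structure(list(conditions = conditions, specific_laws = specific_laws,
                 nonspecific_laws = nonspecific_laws, p_ns = p_ns,
                 n_events = n_events, detection = detection,
                 geometry = geometry, seed = as.integer(seed)),
            class = "ground_truth")
}

# durations for one condition's specific events
.draw_specific <- function(spec, n) {
  if (inherits(spec, "bond_law")) return(rbond(n, spec))
  cfg <- dimer_sim_config(rebinding_rate = spec$k_r, force_sharing = TRUE,
                          initial_bonds = 1, n_runs = n, horizon = 60,
                          seed = NULL)
  simulate_rupture_times(cfg, spec$levels)
}

#' Generate synthetic arrest-duration datasets
#'
#' For each condition, draws `n_events` arrest durations from the
#' specific/nonspecific mixture (specific with probability `1 - p_ns`),
#' discards events shorter than the detection floor
#' (`window - 2 threshold / u_p`; the instrument cannot see them), and
#' returns the detected durations together with hidden per-event labels
#' kept strictly apart from the analysis inputs.
#'
#' @param truth A [ground_truth()].
#' @return A list with one element per condition, each a list of:
#'   `arrests` (data frame `d_true_s`, `shear_per_s`, `censored`),
#'   `labels` (logical, `TRUE` = specific; evaluation only), and
#'   `u_p` (free bead velocity, um/s).
#' @export
generate_arrests <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  out <- vector("list", nrow(truth$conditions))
  for (i in seq_len(nrow(truth$conditions))) {
    g <- truth$conditions$shear_per_s[i]
    u_p <- peak_velocity(truth$geometry, g)
    floor_s <- detection_floor(truth$detection$window,
                               truth$detection$threshold, u_p)
    n <- truth$n_events[i]
    specific <- stats::runif(n) >= truth$p_ns
    d <- numeric(n)
    n_spec <- sum(specific)
    if (n_spec > 0)
      d[specific] <- .draw_specific(truth$specific_laws[[i]], n_spec)
    if (n_spec < n)
      d[!specific] <- rbond(n - n_spec, truth$nonspecific_laws[[i]])
    detected <- d >= max(floor_s, 0) & is.finite(d)
    out[[i]] <- list(
      arrests = data.frame(d_true_s = d[detected], shear_per_s = g,
                           censored = FALSE),
      labels = specific[detected],
      u_p = u_p)
  }
  names(out) <- sprintf("%s_G%g", truth$conditions$tether,
                        truth$conditions$shear_per_s)
  out
}

#' Generate synthetic bead trajectories
#'
#' Beads translate at the peak velocity for the condition's shear rate
#' with Gaussian positional noise (SD 40 nm) at the frame interval.
#' Arrests are planted with exponentially distributed spacing matching a
#' target binding frequency; during an arrest the position is static plus
#' noise. The planted arrest times and durations are returned as an
#' attribute for evaluation only.
#'
#' @param truth A [ground_truth()].
#' @param condition Condition index (row of `truth$conditions`).
#' @param n_beads Number of trajectories.
#' @param duration_s Length of each recording in s (default 20).
#' @param binding_freq_per_mm Planted arrests per mm of free path
#'   (default 2).
#' @param noise_sd_um Positional noise SD in um (default 0.04).
#' @return A list of data frames (`time_s`, `x_um`), each carrying a
#'   `planted` attribute (data frame `start_s`, `duration_s`).
#' @export
generate_trajectory <- function(truth, condition = 1, n_beads = 1,
                                duration_s = 20, binding_freq_per_mm = 2,
                                noise_sd_um = 0.04) {
  stopifnot(inherits(truth, "ground_truth"),
            condition %in% seq_len(nrow(truth$conditions)))
  g <- truth$conditions$shear_per_s[condition]
  u_p <- peak_velocity(truth$geometry, g)
  frame <- truth$detection$frame
  arrest_rate <- binding_freq_per_mm * u_p / 1000  # arrests per s of motion

  law <- truth$specific_laws[[condition]]
  draw_dur <- function() {
    if (inherits(law, "bond_law")) rbond(1, law) else .draw_specific(law, 1)
  }

  lapply(seq_len(n_beads), function(b) {
    times <- seq(0, duration_s, by = frame)
    moving_step <- u_p * frame
    planted <- data.frame(start_s = numeric(0), duration_s = numeric(0))
    x <- numeric(length(times))
    t_next <- if (arrest_rate > 0) stats::rexp(1, arrest_rate) else Inf
    arrest_left <- 0
    for (j in seq_along(times)[-1]) {
      if (arrest_left > 0) {
        arrest_left <- arrest_left - frame
        x[j] <- x[j - 1]
      } else {
        x[j] <- x[j - 1] + moving_step
        t_next <- t_next - frame
        if (t_next <= 0) {
          dur <- draw_dur()
          if (is.finite(dur) && dur > 0) {
            planted <- rbind(planted,
                             data.frame(start_s = times[j], duration_s = dur))
            arrest_left <- dur
          }
          t_next <- stats::rexp(1, arrest_rate)
        }
      }
    }
    xn <- x + stats::rnorm(length(x), sd = noise_sd_um)
    traj <- data.frame(time_s = times, x_um = xn)
    attr(traj, "planted") <- planted
    traj
  })
}
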
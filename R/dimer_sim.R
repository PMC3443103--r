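#' Bond parameters at the three load levels of a divalent attachment
#'
#' A divalent attachment exposes each bond to one of three constant loads:
#' the full tension `F` (single remaining bond, or the loaded bond when
#' force is not shared), half tension `F/2` (both bonds when force is
#' shared), or zero (the slack bond when force is not shared). Each load
#' level carries its own strengthening law, typically obtained from the
#' monomer Bell regressions via [eval_bell()].
#'
#' @param full [bond_law()] at tension `F`.
#' @param half [bond_law()] at tension `F/2`.
#' @param unloaded [bond_law()] at zero force.
#' @return An object of class `force_levels`.
#' @examples
#' # highest-force flow condition of the ICAM-1/anti-ICAM-1 dataset
#' force_levels(full = bond_law(4.934, 6.126),
#'              half = bond_law(0.911, 1.772),
#'              unloaded = bond_law(0.168, 0.512))
#' @export
force_levels <- function(full, half, unloaded) {
  stopifnot(inherits(full, "bond_law"), inherits(half, "bond_law"),
            inherits(unloaded, "bond_law"))
  if (!(full$k0 >= half$k0 && half$k0 >= unloaded$k0))
    warning("expected full >= half >= unloaded initial off-rates")
  structure(list(full = full, half = half, unloaded = unloaded),
            class = "force_levels")
}

#' Write / read force levels as JSON
#'
#' Serialized as `{"full": {"k0":..,"a":..}, "half": {...}, "unloaded": {...}}`.
#'
#' @param levels A [force_levels()].
#' @param path File path.
#' @return Reader returns a [force_levels()]; writer returns `path`
#'   invisibly.
#' @export
write_levels_json <- function(levels, path) {
  stopifnot(inherits(levels, "force_levels"))
  obj <- lapply(unclass(levels), function(l) list(k0 = l$k0, a = l$a))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_levels_json
#' @export
read_levels_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(l) bond_law(l$k0, l$a)
  force_levels(mk(obj$full), mk(obj$half), mk(obj$unloaded))
}

#' Configuration of the dimer-attachment simulator
#'
#' @param rebinding_rate Rate `k_r` (1/s) at which an attachment held by a
#'   single bond of a divalent ligand forms its second bond.
#' @param force_sharing If `TRUE`, the tension is split equally between the
#'   two bonds of a doubly bonded attachment (both use the half-force law);
#'   if `FALSE`, the elder bond carries the full tension and the other is
#'   unloaded.
#' @param initial_bonds 1 or 2 bonds at time zero.
#' @param dt Time step in s (default 0.001). Per-step rupture is a
#'   Bernoulli trial with probability `k dt`; the step must satisfy
#'   `k dt < 1` for every reachable rate and should satisfy `k dt < 0.1`
#'   for acceptable discretization bias.
#' @param n_runs Number of independent attachment histories to average
#'   (default 5000).
#' @param horizon Simulated time span in s (default 6); attachments still
#'   intact at the horizon are censored.
#' @param seed Integer seed making runs reproducible.
#' @return An object of class `dimer_sim_config`.
#' @export
dimer_sim_config <- function(rebinding_rate, force_sharing = TRUE,
                             initial_bonds = 1, dt = 0.001, n_runs = 5000,
                             horizon = 6, seed = NULL) {
  stopifnot(rebinding_rate >= 0, is.logical(force_sharing),
            initial_bonds %in% c(1, 2), dt > 0, n_runs >= 1, horizon > 0)
  structure(list(rebinding_rate = rebinding_rate,
                 force_sharing = force_sharing,
                 initial_bonds = as.integer(initial_bonds), dt = dt,
                 n_runs = as.integer(n_runs), horizon = horizon,
                 seed = seed),
            class = "dimer_sim_config")
}

# One vectorized pass of the fixed-step rupture/rebinding process for all
# runs simultaneously. State per live run: age of the elder bond (age1),
# age of the second bond (age2, NA when absent). Load assignment:
#   sharing ON : two bonds -> both half; one bond -> full.
#   sharing OFF: two bonds -> elder full, other unloaded; one bond -> full.
# On rupture of one bond of two, the survivor becomes the elder, keeps its
# age, and takes the full load. Within a step, rupture trials for existing
# bonds come first; the rebinding trial applies only to runs that entered
# the step with a single bond and whose bond survived the step.
simulate_rupture_times <- function(config, levels) {
  stopifnot(inherits(config, "dimer_sim_config"),
            inherits(levels, "force_levels"))
  dt <- config$dt
  max_rate <- max(levels$full$k0, levels$half$k0, levels$unloaded$k0,
                  config$rebinding_rate)
  if (max_rate * dt >= 1)
    stop("time step too coarse: rate * dt >= 1")

  n <- config$n_runs
  steps <- ceiling(config$horizon / dt)
  rupture <- rep(Inf, n)

  idx <- seq_len(n)
  age1 <- rep(0, n)
  age2 <- if (config$initial_bonds == 2L) rep(0, n) else rep(NA_real_, n)
  kr_dt <- config$rebinding_rate * dt

  haz <- function(law, age) law$k0 / (1 + law$a * age) * dt

  for (step in seq_len(steps)) {
    m <- length(idx)
    two <- !is.na(age2)
    if (config$force_sharing) {
      h1 <- ifelse(two, haz(levels$half, age1), haz(levels$full, age1))
    } else {
      h1 <- haz(levels$full, age1)
    }
    h2 <- ifelse(two, haz(if (config$force_sharing) levels$half else
                            levels$unloaded, age2), 0)

    r1 <- stats::runif(m) < h1
    r2 <- two & (stats::runif(m) < h2)
    rb <- !two & !r1 & (stats::runif(m) < kr_dt)

    dead <- (two & r1 & r2) | (!two & r1)
    if (any(dead)) rupture[idx[dead]] <- step * dt

    # survivor of a doubly bonded attachment becomes the elder bond
    s1died <- two & r1 & !r2
    age1[s1died] <- age2[s1died]
    age2[s1died | (two & !r1 & r2)] <- NA_real_

    age1 <- age1 + dt
    age2 <- age2 + dt
    age2[rb] <- 0  # second bond formed this step starts unstrengthened

    keep <- !dead
    if (!all(keep)) {
      if (!any(keep)) break
      idx <- idx[keep]; age1 <- age1[keep]; age2 <- age2[keep]
    }
  }
  rupture
}

#' Simulate the rupture time of one dimer-mediated attachment
#'
#' Runs a single history of the fixed-step stochastic process: at every
#' step each existing bond ruptures with probability `k(load, age) dt`
#' under the strengthening law of its current load level, and a singly
#' bonded attachment forms a second (unstrengthened, age-zero) bond with
#' probability `k_r dt`. Returns the first time with zero bonds, or `Inf`
#' if the attachment outlives the horizon.
#'
#' @param config A [dimer_sim_config()]; `n_runs` is ignored (one run).
#' @param levels A [force_levels()].
#' @return Rupture time in s, or `Inf` when censored at the horizon.
#' @seealso [simulate_survival()] for the averaged curve over many runs.
#' @export
simulate_rupture_time <- function(config, levels) {
  cfg <- config
  cfg$n_runs <- 1L
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_rupture_times(cfg, levels)
}

#' Simulated survival curve of dimer-mediated attachments
#'
#' Averages `n_runs` independent attachment histories into the fraction
#' still attached at each grid time. Identical seeds give bit-identical
#' curves.
#'
#' @param config A [dimer_sim_config()].
#' @param levels A [force_levels()].
#' @param grid Times at which to tabulate survival; defaults to
#'   [fit_grid()].
#' @return A [survival_curve()] with binomial per-point standard
#'   deviations and `n_total = n_runs`.
#' @export
simulate_survival <- function(config, levels, grid = fit_grid()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  times <- simulate_rupture_times(config, levels)
  s <- vapply(grid, function(t) mean(times > t), numeric(1))
  survival_curve(grid, s, sd = sqrt(pmax(s * (1 - s), 0) / config$n_runs),
                 n_total = config$n_runs)
}

#' Fit the rebinding rate to an observed dimer survival curve
#'
#' `k_r` is the only free parameter of the dimer model: the three bond
#' laws come from monomer measurements. Each candidate `k_r` on a
#' log-spaced grid is simulated with a common seed and scored with
#' [log_msd()] against the observed curve; the winner's neighborhood is
#' then rescanned once at finer spacing.
#'
#' @param observed A [survival_curve()].
#' @param levels A [force_levels()].
#' @param config A [dimer_sim_config()] providing sharing flag, initial
#'   bonds, step, run count, and seed; its `rebinding_rate` is ignored.
#' @param k_r_grid Candidate rebinding rates in 1/s (default 25 log-spaced
#'   values on `[0.05, 50]`).
#' @param refine If `TRUE` (default), rescan between the grid neighbors of
#'   the coarse winner with 7 points.
#' @return A list with `k_r` (best value), `msd`, and `scanned` (data
#'   frame of all evaluated pairs).
#' @export
fit_rebinding <- function(observed, levels, config,
                          k_r_grid = exp(seq(log(0.05), log(50),
                                             length.out = 25)),
                          refine = TRUE) {
  stopifnot(inherits(observed, "survival_curve"), length(k_r_grid) >= 1L)
  score <- function(kr) {
    cfg <- config
    cfg$rebinding_rate <- kr
    log_msd(simulate_survival(cfg, levels), observed)
  }
  k_r_grid <- sort(k_r_grid)
  msds <- vapply(k_r_grid, score, numeric(1))
  scanned <- data.frame(k_r = k_r_grid, msd = msds)
  i <- which.min(msds)
  if (refine && length(k_r_grid) > 1L) {
    lo <- if (i > 1L) k_r_grid[i - 1L] else k_r_grid[1L] / 2
    hi <- if (i < length(k_r_grid)) k_r_grid[i + 1L] else k_r_grid[i] * 2
    fine <- exp(seq(log(lo), log(hi), length.out = 7))
    fine <- setdiff(fine, k_r_grid)
    if (length(fine)) {
      fmsds <- vapply(fine, score, numeric(1))
      scanned <- rbind(scanned, data.frame(k_r = fine, msd = fmsds))
    }
  }
  best <- which.min(scanned$msd)
  list(k_r = scanned$k_r[best], msd = scanned$msd[best], scanned = scanned)
}

#' Decompose the mechanisms protecting a divalent attachment
#'
#' Simulates the 5-s survival of a divalent attachment with all three
#' protective mechanisms enabled (force sharing, rebinding, bond
#' strengthening), then with each mechanism removed in turn:
#' \describe{
#'   \item{all_on}{sharing, rebinding at `k_r`, strengthening.}
#'   \item{no_sharing}{the doubly bonded state loads one bond fully and
#'     leaves the other slack.}
#'   \item{no_rebinding}{`k_r = 0`; with one initial bond this is exactly
#'     the monomer model.}
#'   \item{no_strengthening}{all strengthening rates set to 0
#'     (memoryless bonds).}
#' }
#' Every variant uses the same seed, run count, and time step.
#'
#' @param levels A [force_levels()].
#' @param k_r Rebinding rate in 1/s for the variants that include
#'   rebinding.
#' @param config A [dimer_sim_config()] template (its `rebinding_rate` and
#'   `force_sharing` are overridden per variant).
#' @param at Evaluation time in s (default 5).
#' @return Named numeric vector of surviving fractions at `at` for
#'   `all_on`, `no_sharing`, `no_rebinding`, `no_strengthening`.
#' @export
mechanism_decomposition <- function(levels, k_r, config, at = 5) {
  variant <- function(kr, sharing, lv) {
    cfg <- config
    cfg$rebinding_rate <- kr
    cfg$force_sharing <- sharing
    surv_at(simulate_survival(cfg, lv, grid = c(0, at)), at)
  }
  strip <- function(l) bond_law(l$k0, 0)
  lv0 <- force_levels(strip(levels$full), strip(levels$half),
                      strip(levels$unloaded))
  c(all_on = variant(k_r, TRUE, levels),
    no_sharing = variant(k_r, FALSE, levels),
    no_rebinding = variant(0, TRUE, levels),
    no_strengthening = variant(k_r, TRUE, lv0))
}
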
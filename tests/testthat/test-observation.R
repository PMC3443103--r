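# straight-line track at velocity u with a full stop inserted
make_track <- function(u, duration = 4, frame = 0.02, stop_at = NULL,
                       stop_len = 0, noise_sd = 0) {
  t <- seq(0, duration, by = frame)
  step <- rep(u * frame, length(t) - 1)
  if (!is.null(stop_at)) {
    j <- which(t[-1] > stop_at & t[-1] <= stop_at + stop_len)
    step[j] <- 0
  }
  x <- cumsum(c(0, step))
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  data.frame(time_s = t, x_um = x)
}

test_that("detect_arrests finds planted stops and ignores motion", {
  # no pauses: no events
  expect_equal(nrow(detect_arrests(make_track(22.5))), 0L)
  # a 1.0-s full stop: exactly one event with apparent duration ~1.0 s
  # (boundary windows containing a single moving frame may extend the
  # event by up to two frames on either side)
  tr <- make_track(22.5, stop_at = 1.5, stop_len = 1.0)
  ev <- detect_arrests(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$d_app_s, 1.0, tolerance = 0.06)
  expect_false(ev$censored)
  # a 0.1-s pause is below the 0.2-s window: invisible by construction
  expect_equal(nrow(detect_arrests(make_track(22.5, stop_at = 1.5,
                                              stop_len = 0.1))), 0L)
  # a stop running into the end of the record is censored
  tr2 <- make_track(22.5, duration = 3, stop_at = 2.0, stop_len = 2.0)
  ev2 <- detect_arrests(tr2)
  expect_equal(nrow(ev2), 1L)
  expect_true(ev2$censored)
  expect_error(detect_arrests(data.frame(time_s = c(1, 0.5), x_um = c(0, 1))),
               "increasing")
})

test_that("detector recovers planted arrests on noisy synthetic tracks", {
  truth <- ground_truth(seed = 33)
  set.seed(33)
  trajs <- generate_trajectory(truth, condition = 2, n_beads = 20,
                               duration_s = 30, binding_freq_per_mm = 0.8)
  detected <- vapply(trajs, function(tr) nrow(detect_arrests(tr)), integer(1))
  # every track's long arrests are found (short ones may be missed)
  n_long <- vapply(trajs, function(tr) {
    p <- attr(tr, "planted")
    sum(p$duration_s >= 0.4)
  }, integer(1))
  expect_gte(sum(detected), 0.95 * sum(n_long))
  # pause-free tracks yield no events
  quiet <- generate_trajectory(truth, condition = 2, n_beads = 3,
                               duration_s = 10, binding_freq_per_mm = 0)
  expect_true(all(vapply(quiet, function(tr) nrow(detect_arrests(tr)),
                         integer(1)) == 0L))
  # free velocity estimated from a pause-free track matches 0.54 a G
  tr <- quiet[[1]]
  v <- coef(lm(x_um ~ time_s, tr))[2]
  expect_equal(unname(v), peak_velocity(chamber_geometry(), 18.5),
               tolerance = 0.01)
})

test_that("correct_duration applies the detection-window correction", {
  expect_equal(correct_duration(0.5, 0.2, 0.5, 22.5), 0.6556, tolerance = 1e-4)
  expect_equal(correct_duration(0.7, 0.2, 0.5, 5.0), 0.7)
  expect_equal(correct_duration(0, 0.2, 0.5, 22.5), 0.15556, tolerance = 1e-4)
  # affine in d_app with unit slope
  d <- c(0.1, 0.9, 2.4)
  expect_equal(diff(correct_duration(d, u_p = 22.5)), diff(d))
  expect_error(correct_duration(0.5, u_p = 0), "positive")
  expect_equal(detection_floor(u_p = 22.5), correct_duration(0, u_p = 22.5))
})

test_that("build_survival tabulates the empirical survivor function", {
  grid <- c(0, 0.2, 0.4, 0.6, 0.8)
  cv <- build_survival(c(0.1, 0.3, 0.5, 0.7), grid)
  expect_equal(cv$survival, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(cv$n_total, 4)
  expect_equal(cv$sd, sqrt(cv$survival * (1 - cv$survival) / 4))
  # all durations beyond the grid: flat at 1 with zero sd
  cv1 <- build_survival(c(10, 12), grid)
  expect_equal(cv1$survival, rep(1, 5))
  expect_equal(cv1$sd, rep(0, 5))
  expect_error(build_survival(numeric(0)), "length")
})

test_that("empirical survival converges to the generating law", {
  law <- bond_law(1.277, 2.270)
  g <- fit_grid()
  set.seed(14)
  cv <- build_survival(rbond(10000, law), g)
  expect_lt(max(abs(cv$survival - bond_survival(law, g))), 0.02)
})

test_that("right-censored durations enter through the risk set", {
  # censoring at 1 s keeps the curve above the fully observed one
  set.seed(15)
  d <- rbond(2000, bond_law(1.0, 1.0))
  cens <- d > 1
  d_obs <- pmin(d, 1)
  g <- fit_grid()
  cv <- build_survival(d_obs, g, censored = cens)
  ref <- build_survival(d, g)
  expect_equal(cv$survival[g <= 1], ref$survival[g <= 1], tolerance = 1e-10)
  expect_true(all(cv$survival >= ref$survival - 1e-10))
})

test_that("initial-count extrapolation is the OLS line at t = 0", {
  # collinear counts 100, 90, 80 at 0.1, 0.3, 0.5 s -> 105 at t = 0
  cv <- survival_curve(c(0.1, 0.3, 0.5, 1), c(1, 90 / 100, 80 / 100, 0.5),
                       n_total = 100)
  expect_equal(extrapolate_true_count(cv, 0.5), 105, tolerance = 1e-10)
  # constant counts: intercept equals the constant
  cv2 <- survival_curve(c(0.1, 0.3, 0.5), rep(1, 3), n_total = 50)
  expect_equal(extrapolate_true_count(cv2, 0.5), 50, tolerance = 1e-10)
  rn <- renormalize_initial(cv2)
  expect_equal(rn$survival, rep(1, 3))
  expect_error(extrapolate_true_count(cv, 0.05), "at least 2")
})

test_that("binding frequency carries a Poisson uncertainty", {
  expect_equal(binding_frequency(0, 100), list(f = 0, sd = 0))
  expect_equal(binding_frequency(400, 200), list(f = 2.0, sd = 0.1))
  expect_equal(binding_frequency(100, 100), list(f = 1.0, sd = 0.1))
  expect_error(binding_frequency(10, 0), "positive")
})

test_that("nonspecific subtraction de-mixes the survival curve", {
  g <- fit_grid()
  spec_law <- bond_law(1.277, 2.270)
  ns_law <- bond_law(2.51, 2.0)
  s_spec <- bond_survival(spec_law, g)
  s_ns <- bond_survival(ns_law, g)
  obs <- survival_curve(g, 0.8 * s_spec + 0.2 * s_ns, n_total = 1000)
  # p_ns = 0 is the identity
  same <- subtract_nonspecific(obs, survival_curve(g, s_ns), 0)
  expect_equal(same$survival, obs$survival)
  # exact de-mixing with the true model
  out <- subtract_nonspecific(obs, survival_curve(g, s_ns), 0.2)
  expect_equal(out$survival, s_spec, tolerance = 1e-10)
  expect_equal(out$n_total, 800)
  # spot value
  one <- subtract_nonspecific(survival_curve(c(0, 1), c(1, 0.6)),
                              survival_curve(c(0, 1), c(1, 0.9)), 0.2)
  expect_equal(one$survival[2], 0.525)
  # subtraction preserves monotonicity when ns decays no faster
  expect_true(all(diff(out$survival) <= 0))
  expect_error(subtract_nonspecific(obs, survival_curve(g, s_ns), 1), "below 1")
})

test_that("specific fraction follows from the frequency fold increase", {
  expect_equal(specific_fraction(3.45), 0.7101, tolerance = 1e-4)
  expect_equal(specific_fraction(1.0), 0)
  expect_equal(specific_fraction(2.0), 0.5)
  expect_error(specific_fraction(0.9), ">= 1")
})

test_that("mean_off_rate summarizes early decay", {
  expect_equal(mean_off_rate(bond_law(0.7, 0), 0.5), 0.7, tolerance = 1e-12)
  expect_equal(mean_off_rate(bond_law(0.7, 0), 2.0), 0.7, tolerance = 1e-12)
  expect_equal(mean_off_rate(bond_law(0.519, 1.171), 0.5), 0.4086,
               tolerance = 1e-3)
  expect_equal(mean_off_rate(survival_curve(c(0, 0.5), c(1, 1)), 0.5), 0)
  expect_error(mean_off_rate(survival_curve(c(0, 0.5), c(1, 0)), 0.5),
               "not positive")
})
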
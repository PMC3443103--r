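# Boltzmann constant, J/K
.kB <- 1.380649e-23

#' Flow-chamber geometry and near-wall hydrodynamic constants
#'
#' Describes a sedimented microsphere driven along the chamber floor by a
#' laminar shear flow. In the contact limit (gap much smaller than the
#' radius) the flow exerts on a non-rotating translating sphere a force
#' `F = 6 pi mu a^2 C_F G` and torque `Gamma = 4 pi mu a^3 C_T G`, with
#' dimensionless wall corrections `C_F` and `C_T` from near-wall Stokes
#' theory, and the freely moving sphere translates at a peak velocity
#' `u_p ~ 0.54 a G`.
#'
#' @param bead_radius_nm Microsphere radius in nm (default 2250, a 4.5-um
#'   diameter bead).
#' @param viscosity_Pa_s Medium viscosity in Pa s (default 1e-3, aqueous
#'   buffer).
#' @param drag_coefficient Wall correction for the drag force (default
#'   1.7005).
#' @param torque_coefficient Wall correction for the torque (default
#'   0.9440).
#' @param velocity_coefficient Ratio of peak bead velocity to `a G`
#'   (default 0.54).
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(bead_radius_nm = 2250, viscosity_Pa_s = 1e-3,
                             drag_coefficient = 1.7005,
                             torque_coefficient = 0.9440,
                             velocity_coefficient = 0.54) {
  vals <- c(bead_radius_nm, viscosity_Pa_s, drag_coefficient,
            torque_coefficient, velocity_coefficient)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals > 0))
  structure(list(bead_radius_nm = bead_radius_nm,
                 viscosity_Pa_s = viscosity_Pa_s,
                 drag_coefficient = drag_coefficient,
                 torque_coefficient = torque_coefficient,
                 velocity_coefficient = velocity_coefficient),
            class = "chamber_geometry")
}

#' Molecular tether between bead and surface
#'
#' The bond anchoring a bead acts through a tether of contour length `L`
#' (the lever arm entering the tension formula) which, for stiffness and
#' thermal-force estimates, is modeled as a freely jointed chain of
#' `n_links` rigid links of length `link_length_nm`.
#'
#' @param length_nm Tether length `L` in nm. 68 nm for the monomeric
#'   ICAM-1 chain, 76 nm for the Fc(ICAM-1)2 dimer construct.
#' @param n_links Number of FJC links (default 4).
#' @param link_length_nm FJC link length in nm (default 15).
#' @return An object of class `tether_model`.
#' @export
tether_model <- function(length_nm = 68, n_links = 4, link_length_nm = 15) {
  stopifnot(length_nm > 0, n_links >= 1, link_length_nm > 0)
  structure(list(length_nm = length_nm, n_links = n_links,
                 link_length_nm = link_length_nm),
            class = "tether_model")
}

#' @rdname tether_model
#' @export
monomer_tether <- function() tether_model(length_nm = 68)

#' @rdname tether_model
#' @export
dimer_tether <- function() tether_model(length_nm = 76)

#' Peak translational velocity of a freely moving bead
#'
#' `u_p = 0.54 a G` for a sphere hovering near the wall; with the default
#' 2250-nm radius this is 1.215 um/s per unit shear rate.
#'
#' @param geom A [chamber_geometry()].
#' @param shear_rate Wall shear rate(s) `G` in 1/s.
#' @return Velocity in um/s.
#' @export
peak_velocity <- function(geom, shear_rate) {
  stopifnot(inherits(geom, "chamber_geometry"), all(shear_rate >= 0))
  geom$velocity_coefficient * (geom$bead_radius_nm / 1000) * shear_rate
}

#' Hydrodynamic drag force on the bead
#'
#' `F = 6 pi mu a^2 C_F G`, converted to pN. With the default geometry this
#' is 1.62 pN at `G = 10` 1/s.
#'
#' @inheritParams peak_velocity
#' @return Force in pN.
#' @export
drag_force <- function(geom, shear_rate) {
  stopifnot(inherits(geom, "chamber_geometry"), all(shear_rate >= 0))
  a_m <- geom$bead_radius_nm * 1e-9
  f_N <- 6 * pi * geom$viscosity_Pa_s * a_m^2 * geom$drag_coefficient *
    shear_rate
  f_N * 1e12
}

#' Bond tension per unit shear rate
#'
#' A bead held at rest by a single tether of length `L` experiences, by
#' moment balance about the anchoring point (frictionless contact), a bond
#' tension
#' \deqn{T = (F + \Gamma/a) \sqrt{a / 2L},}
#' where `F` and `Gamma` are the flow force and torque on the arrested
#' sphere. Since both are linear in `G`, tension is `coefficient * G`;
#' this returns the coefficient in pN per unit shear rate. Defaults give
#' 0.904 (L = 68 nm) and 0.855 (L = 76 nm).
#'
#' @param geom A [chamber_geometry()].
#' @param tether A [tether_model()].
#' @return Coefficient in pN s (pN per 1/s of shear).
#' @export
tension_coefficient <- function(geom, tether) {
  stopifnot(inherits(geom, "chamber_geometry"), inherits(tether, "tether_model"))
  a_m <- geom$bead_radius_nm * 1e-9
  mu <- geom$viscosity_Pa_s
  # force + torque/a per unit shear, in N s
  fg <- 6 * pi * mu * a_m^2 * geom$drag_coefficient +
    4 * pi * mu * a_m^2 * geom$torque_coefficient
  lever <- sqrt(geom$bead_radius_nm / (2 * tether$length_nm))
  fg * lever * 1e12
}

#' Bond tension at a given wall shear rate
#'
#' @inheritParams tension_coefficient
#' @param shear_rate Wall shear rate(s) in 1/s.
#' @return Tension in pN.
#' @examples
#' tension(chamber_geometry(), dimer_tether(), 30.9) # 26.4 pN
#' @export
tension <- function(geom, tether, shear_rate) {
  stopifnot(all(shear_rate >= 0))
  tension_coefficient(geom, tether) * shear_rate
}

#' Entropic stiffness of a freely jointed chain tether
#'
#' For an FJC of link length `a`, the small-extension spring constant is
#' `s = 3 kT / (4 a^2)` (per degree of freedom of the anchored bead).
#'
#' @param tether A [tether_model()].
#' @param temperature Absolute temperature in K (default 298).
#' @return Stiffness in N/m.
#' @export
fjc_stiffness <- function(tether, temperature = 298) {
  stopifnot(inherits(tether, "tether_model"), temperature > 0)
  link_m <- tether$link_length_nm * 1e-9
  3 * .kB * temperature / (4 * link_m^2)
}

#' Mean thermal force on a tethered bead
#'
#' The average force a Brownian particle bound to a spring of stiffness `s`
#' exerts along one degree of freedom, `<F> = sqrt(2 s kT / pi)`. Used as a
#' control that thermal agitation (about 0.19 pN for the default 15-nm-link
#' FJC at 298 K) is negligible against the flow forces of a few pN.
#'
#' @param stiffness Spring constant in N/m.
#' @param temperature Absolute temperature in K (default 298).
#' @return Force in pN.
#' @export
thermal_force <- function(stiffness, temperature = 298) {
  stopifnot(stiffness >= 0, temperature > 0)
  sqrt(2 * stiffness * .kB * temperature / pi) * 1e12
}
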
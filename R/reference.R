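#' Reference rupture parameters for ICAM-1/anti-ICAM-1 bonds under flow
#'
#' Fitted strengthening-law parameters for single ICAM-1/anti-ICAM-1 bonds
#' pulled by a flow-driven 4.5-um microsphere, at the three wall shear
#' rates of the dimer-tether flow-chamber conditions plus the zero-force
#' Bell extrapolation. `k0` and `a` are the initial off-rate and
#' strengthening rate at the full bond tension `force_pN`; `k0_half` and
#' `a_half` are the same quantities at half tension, obtained from the
#' Bell regressions through the three loaded rows (see [fit_bell()]).
#'
#' These values parameterize the default synthetic ground truth
#' ([ground_truth()]) and the divalent-attachment force levels
#' ([reference_force_levels()]).
#'
#' @return A data frame with columns `shear_per_s`, `force_pN`, `k0`, `a`,
#'   `k0_half`, `a_half` (rates in 1/s).
#' @export
icam1_reference_parameters <- function() {
  data.frame(
    shear_per_s = c(0, 10.3, 18.5, 30.9),
    force_pN = c(0, 8.80, 15.84, 26.4),
    k0 = c(0.168, 0.519, 1.277, 4.934),
    a = c(0.512, 1.171, 2.270, 6.126),
    k0_half = c(0.168, 0.295, 0.463, 0.911),
    a_half = c(0.512, 0.775, 1.078, 1.772)
  )
}

#' Force levels for a reference flow condition
#'
#' Assembles the [force_levels()] (full-, half-, and zero-force bond laws)
#' for one of the loaded rows of [icam1_reference_parameters()].
#'
#' @param shear_rate One of 10.3, 18.5, 30.9 (1/s).
#' @return A [force_levels()].
#' @examples
#' reference_force_levels(30.9)
#' @export
reference_force_levels <- function(shear_rate) {
  tab <- icam1_reference_parameters()
  i <- match(shear_rate, tab$shear_per_s)
  if (is.na(i) || shear_rate == 0)
    stop("'shear_rate' must be one of ", paste(tab$shear_per_s[-1], collapse = ", "))
  force_levels(
    full = bond_law(tab$k0[i], tab$a[i], force = tab$force_pN[i]),
    half = bond_law(tab$k0_half[i], tab$a_half[i], force = tab$force_pN[i] / 2),
    unloaded = bond_law(tab$k0[1], tab$a[1], force = 0)
  )
}
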
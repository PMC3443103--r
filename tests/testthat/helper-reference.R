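# Reference monomer bond parameters at the three loaded flow conditions
# (wall shear rate, bond tension, fitted k(F,0) and a(F), and the
# Bell-regression half-force values) plus the zero-force Bell row.
ref_tab <- function() icam1_reference_parameters()

ref_loaded <- function() icam1_reference_parameters()[-1, ]

# Independent 3-state continuous-time Markov chain oracle for the dimer
# simulator when all strengthening rates are zero (memoryless bonds).
# States: 1 = two bonds, 2 = one bond (full load), 3 = detached.
# Sharing ON : 2 -> 1 at 2 * k_half.
# Sharing OFF: 2 -> 1 at k_full + k_unloaded (either bond's rupture leaves
#              one fully loaded bond).
# 1-bond state: rupture at k_full, rebinding at k_r.
# Survival = 1 - P(absorbed), via the matrix exponential of the generator.
ctmc_survival <- function(t, k_full, k_half, k_unloaded, k_r, sharing,
                          initial_bonds = 1) {
  q12 <- if (sharing) 2 * k_half else k_full + k_unloaded
  Q <- matrix(0, 3, 3)
  Q[1, 1] <- -q12; Q[1, 2] <- q12
  Q[2, 1] <- k_r; Q[2, 2] <- -(k_r + k_full); Q[2, 3] <- k_full
  p0 <- if (initial_bonds == 2) c(1, 0, 0) else c(0, 1, 0)
  vapply(t, function(s) {
    1 - (p0 %*% as.matrix(Matrix::expm(Q * s)))[3]
  }, numeric(1))
}
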
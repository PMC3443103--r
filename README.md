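# flowbond

Kinetics of single and divalent receptor–ligand bond rupture under
hydrodynamic force, for laminar flow-chamber experiments.

## The problem

In a flow chamber, ligand-coated microspheres driven along a sparsely
receptor-coated floor stop when a single molecular bond forms; the
distribution of arrest durations at a known wall shear rate G is the
rupture statistics of that bond under a constant, calculable tension.
Two complications dominate the analysis:

1. **Bonds strengthen with age.** A single off-rate does not fit the
   data. `flowbond` uses the two-parameter law
   `k(F,t) = k(F,0) / (1 + a(F) t)`, whose survivor function is the
   closed form `s(t) = (1 + a t)^(-k0/a)`; `k(F,0)` is the initial
   off-rate and `a(F)` the bond-strengthening rate. Both rise
   exponentially with force (Bell behaviour), so a log-linear regression
   extrapolates them to half force and zero force.
2. **Divalent ligands resist force far better than monovalent ones.**
   A kinetic Monte Carlo model of 1- and 2-bond attachments — per-bond
   strengthening clocks, rebinding at rate `k_r` when a single bond
   holds, and optional equal force sharing — predicts dimer survival
   curves from monomer-derived parameters with `k_r` as the only free
   parameter, and quantifies how much strengthening, rebinding and
   sharing each contribute.

Around this core the package provides the shear-to-force hydrodynamic
mapping for a tethered sphere near a wall (`T = (F + Γ/a) sqrt(a/2L)`),
arrest detection and duration correction for bead trajectories,
Kaplan–Meier survival curves with binomial errors, nonspecific-arrest
subtraction, and a synthetic flow-chamber data generator so the entire
pipeline is testable with no external data.

Intended users: single-molecule biophysicists analyzing flow-chamber (or
similar constant-force) bond-rupture data, and anyone needing a tested
reference implementation of time-strengthening bond kinetics and
multivalent attachment simulation.

## Worked example

```r
library(flowbond)

# Reference monomer parameters at three flow forces (8.8-26.4 pN)
tab <- icam1_reference_parameters()
loaded <- tab[tab$force_pN > 0, ]

# Bell regression of the initial off-rate on force
bell_k <- fit_bell(loaded$force_pN, loaded$k0)
bell_k
#> Bell law: value(F) = 0.1683 * exp(0.128 * F)  [F in pN]
eval_bell(bell_k, 0)     # zero-force off-rate: 0.168 /s
eval_bell(bell_k, 13.2)  # per-bond rate under shared load at 26.4 pN: 0.911 /s

# Shear rate to bond tension for the dimer-construct tether (L = 76 nm)
tension(chamber_geometry(), dimer_tether(), 30.9)
#> [1] 26.43133   # pN

# Dimer attachment at the highest force: which mechanism matters most?
lv <- reference_force_levels(30.9)
cfg <- dimer_sim_config(rebinding_rate = 6, force_sharing = TRUE,
                        initial_bonds = 1, n_runs = 5000, seed = 42)
round(mechanism_decomposition(lv, 6, cfg), 3)
#>           all_on       no_sharing     no_rebinding no_strengthening
#>            0.478            0.401            0.059            0.016
```

Reading the output: with all three protective mechanisms enabled, 48% of
divalent attachments survive 5 s under a 26.4 pN load. Removing bond
strengthening collapses survival to 1.6% and removing rebinding to 5.9%,
while removing force sharing only trims it to 40% — strengthening and
rebinding, not load splitting, are what make divalent attachments
durable.

To fit a monomer survival curve or recover `k_r` from dimer data:

```r
fit <- fit_bond_law(build_survival(durations))        # (k0, a) + MSD
res <- fit_rebinding(observed_curve, lv, cfg)         # k_r scan + refine
```

A thin command-line wrapper over these functions is installed at
`inst/cli/flowbond.R` (subcommands `fit-monomer`, `bell`, `force`,
`detect`, `survive`, `simulate`, `fit-rebinding`, `decompose`, `synth`).

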
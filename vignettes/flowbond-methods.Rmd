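---
title: "Bond rupture under flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond rupture under flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowbond)
```

## The experimental system

A laminar flow chamber drives antibody-coated microspheres (radius
a = 2.25 µm) along a floor coated with a very low density of ligand —
here monomeric ICAM-1 or its divalent Fc(ICAM-1)₂ construct binding
anti-ICAM-1. A bead that forms a bond stops; the distribution of arrest
durations at a controlled wall shear rate G is the rupture statistics of
single (or paired) molecular bonds under a constant, known tension.
`flowbond` implements the full quantitative chain from raw bead
trajectories to force-dependent bond parameters and a stochastic model of
divalent attachments.

## The time-strengthening dissociation law

Classical single-rate kinetics fail for most receptor–ligand pairs: the
measured off-rate falls with bond age as the complex settles into deeper
states of its energy landscape. Rather than a multi-state model (which
needs many parameters per curve), the package uses a two-parameter
empirical law for a bond under constant force F,

$$k(F, t) = \frac{k(F,0)}{1 + a(F)\,t},$$

where $k(F,0)$ is the initial off-rate and $a(F)$ the *bond-strengthening
rate*. Integrating the hazard gives the closed-form survivor function

$$s(t) = (1 + a t)^{-k_0/a},$$

with the exponential bond recovered as $a \to 0$ (`bond_survival()`
switches to `exp(-k0 t)` exactly at `a = 0`; tests verify pointwise
convergence at `a = 1e-8`). Two properties matter in practice:

* for $k_0/a \le 1$ the lifetime distribution is heavy-tailed with
  infinite mean — summary statistics should use survival fractions or
  median-type quantities, never sample means;
* the quantile transform $t(u) = (u^{-a/k_0} - 1)/a$ (`sample_duration()`)
  inverts the survivor function analytically, so synthetic lifetimes are
  exact draws.

The law is unit-agnostic: the flow-chamber path works in seconds, and a
force-free variant in per-minute units is just a rescaled parameter pair.

## Fitting: mean squared difference of log-survival

Curves are compared on a fixed 19-point grid, $t_0 = 0$ and
$t_i = (1.25^i - 1)/10$ for $i = 1,\dots,18$ (about 25 ms to 5.45 s,
log-spaced where most ruptures happen). The criterion is the mean squared
difference between the logarithms of predicted and observed survival
(`log_msd()`). Numerical choices:

* observed empirical curves are step functions; grid points where the
  observed survival is zero (after the last event) are excluded — the log
  is undefined and the point carries no information;
* a *predicted* survival of numerical zero at a point where events were
  observed is floored at 1e-12, i.e. heavily penalized rather than
  dropped. (Dropping it would let an optimizer "win" by predicting
  instant rupture everywhere, leaving only the perfect $t=0$ point in the
  mean.)

`fit_bond_law()` minimizes this criterion with a coarse log-spaced scan of
$(k_0, a) \in [10^{-3}, 50]^2$ (plus the $a = 0$ boundary) followed by
Nelder–Mead refinement in log-parameter space (relative tolerance
1e-14). The surface is smooth and the scan makes the procedure
insensitive to starting values; noiseless curves are recovered to 1e-4
relative error.

### Left truncation by the detector

The arrest detector cannot see arrests shorter than
$\delta t - 2\delta x / u_p$ (about 0.12–0.17 s at the study's shear
rates), so recorded durations are left-truncated. Renormalizing the curve
by a linearly extrapolated initial count (`extrapolate_true_count()`, the
classical approach, kept for event-count accounting) is accurate only
when the survivor function is nearly linear below 0.5 s; for the fastest
law here ($k_0 \approx 4.9\,\mathrm{s^{-1}}$) the curvature makes it
underestimate the initial count by roughly a third, which propagates
multiplicative errors into both parameters. `fit_bond_law(truncation =
floor)` therefore fits the *conditional* survivor $s(t)/s(\mathrm{floor})$
on the grid points above the floor. This is unbiased (verified against
large-sample recovery) at the cost of wider sampling spread, since the
data below the floor are genuinely lost: at the highest force nearly half
the specific events fall below the detection floor, and the per-condition
spread of the refitted parameters grows to tens of percent at a few
thousand events per condition. The package's tests assert recovery at the
measured ~3-sigma spread of the estimator rather than at nominal bands.

## Force dependence: Bell regression

Across conditions both parameters rise exponentially with force
(Bell-type behaviour). `fit_bell()` is an ordinary least-squares
regression of $\ln(\mathrm{rate})$ on force; `eval_bell()` evaluates the
law anywhere, in particular at half force $F/2$ (the load per bond of a
force-sharing pair) and at $F = 0$. The degenerate all-forces-equal case
returns slope 0 and the geometric-mean rate, so a single force-free
condition degrades gracefully. Note that re-deriving tabulated half-force
values from *rounded* three-digit inputs reproduces them only to about
one unit in the last digit; the package's checks allow exactly that.

## Hydrodynamics: shear rate to tension

For a sphere held at rest on the floor by a tether of length L, moment
balance (frictionless contact) gives the bond tension

$$T = (F_{flow} + \Gamma/a)\sqrt{a/2L},$$

with the near-wall Stokes force $F_{flow} = 6\pi\mu a^2 C_F G$ and torque
$\Gamma = 4\pi\mu a^3 C_T G$. The contact-limit wall corrections
$C_F = 1.7005$ and $C_T = 0.9440$ are adopted (the gap dependence at
h ≈ 25 nm is ignored); with $\mu = 10^{-3}$ Pa·s and a = 2250 nm these
reproduce the study coefficients T = 0.904 G (L = 68 nm, monomeric
tether) and T = 0.855 G (L = 76 nm, dimer construct), the 1.62 pN drag at
G = 10 s⁻¹, and the free-bead velocity u_p = 0.54 aG = 1.215 G µm/s.
Temperature defaults to 298 K; the freely-jointed-chain thermal-force
control ($s = 3kT/4a_{link}^2$, $\langle F\rangle = \sqrt{2skT/\pi}
\approx 0.19$ pN for four 15-nm links) is insensitive to ±5 K and serves
to show Brownian loading is negligible against the 1.6–4.9 pN flow
forces.

## Observation pipeline

* **Arrest detection** (`detect_arrests()`): a frame qualifies when the
  forward displacement over the next 200 ms stays below 0.5 µm; maximal
  runs of qualifying frames merge into one event spanning to the end of
  the last qualifying window. Boundary windows that contain a single
  moving frame can stretch an event by up to two frames on either side —
  the round-trip tests allow exactly that. Events whose last window
  touches the record end are flagged censored.
* **Duration correction** (`correct_duration()`):
  $d_{true} = d_{app} + \delta t - 2\delta x/u_p$.
* **Survival curves** (`build_survival()`): Kaplan–Meier via
  `survival::survfit(timefix = FALSE)` — `timefix` must be off because
  its tie tolerance scales with the *largest* duration and heavy-tailed
  laws produce draws of 10¹⁴ s that would collapse all short arrests into
  one tie. Per-point uncertainty is binomial,
  $\sqrt{s(1-s)/N_t}$; censored events leave the risk set at their
  censoring time.
* **Nonspecific subtraction** (`subtract_nonspecific()`): observed
  arrests are a mixture with nonspecific fraction $P_{NS}$ (measured with
  isotype-control beads; ~0.20–0.23 in the reference system), removed by
  the de-mixing identity
  $s_{spec} = (s_{obs} - P_{NS}\,s_{NS})/(1-P_{NS})$, clamped to [0, 1].
  When working above a detection floor, the subtraction is done in
  conditional space with the *detected* nonspecific share, which the
  mixture identity maps exactly onto the conditional specific survivor.
* **Frequencies**: events per mm of scanned path with Poisson SD
  (`binding_frequency()`); the specific share of binding follows from the
  fold increase of arrest frequency over isotype controls,
  $(\mathrm{fold}-1)/\mathrm{fold}$ (3.45-fold → 71%).

## The dimer Monte Carlo

A divalent ligand can hold a bead by one or two bonds. The simulator
(`simulate_survival()`) advances a fixed step dt = 1 ms; at each step
every existing bond ruptures with probability $k(\mathrm{load},
\mathrm{age})\,dt$, and an attachment holding by a single bond forms a
second one with probability $k_r\,dt$. Model choices, each of which the
closed-form and CTMC tests pin down:

* **Per-bond age clocks.** Each bond strengthens according to its own age
  since formation; a rebound second bond starts unstrengthened.
* **Load rule.** Sharing ON: both bonds of a pair use the half-force
  parameters; the survivor of a rupture switches to full force, keeping
  its age. Sharing OFF: the elder bond carries full force, the other is
  unloaded; the survivor always ends fully loaded.
* **Step order.** Rupture trials first; the rebinding trial applies only
  if the single bond survived the step (a detached attachment is not
  rescued within the step). The ordering bias is $O(k k_r dt^2)$ and the
  dt-halving test confirms it is below Monte-Carlo error.
* **Validation.** With all strengthening rates zero the process is a
  3-state continuous-time Markov chain; the test suite compares the
  simulator against an independent matrix-exponential solution for both
  load rules. With $k_r = 0$ and one initial bond it reduces exactly to
  the monomer closed form.

`fit_rebinding()` scans $k_r$ (the model's only free parameter) on a
25-point log grid over 0.05–50 s⁻¹ with a common seed per candidate and
one 7-point refinement pass around the winner.
`mechanism_decomposition()` toggles sharing, rebinding, and strengthening
off one at a time (identical seeds) and reports 5-s survival; under the
highest-force reference parameters with $k_r = 6$ s⁻¹ survival is ~0.48
with everything on, and removing strengthening hurts far more than
removing rebinding, which hurts more than removing sharing — the
hierarchy the model was built to quantify.

## The synthetic-data generator

`ground_truth()` defaults encode the reference study regime: three
monomer conditions at G = 10.3, 18.5, 30.9 s⁻¹ with the tabulated
$(k_0, a)$ per condition, a pooled nonspecific fraction of 0.22, and
nonspecific laws with strengthening rate 2 s⁻¹ whose first-500-ms mean
off-rates equal the reference 2.53 / 1.74 / 1.75 s⁻¹ (solving
$-\ln s(0.5)/0.5 = k_0\ln 2$ gives $k_0$ in closed form). Note the
nonspecific rates are deliberately non-monotone in force — the generator
imposes no slip-bond behaviour on the nonspecific component.
`generate_arrests()` drops events below the detection floor (the
instrument is blind there, mirroring real data), and keeps the
specific/nonspecific labels in a separate element so they cannot leak
into analysis inputs. `generate_trajectory()` produces bead tracks at
u_p with 40-nm Gaussian positional noise at 20-ms frames and planted
arrests for detector round-trip tests.

What the generator does *not* emulate: optical pixelation, bead-height
Brownian dynamics, tether-elasticity transients at arrest onset, slide-
to-slide coating variability, and any force dependence of $k_r$ (in the
reference analysis the fitted $k_r$ grows with force, which the model
treats as an output of per-condition fitting, not an input). Passing
tests therefore demonstrate the correctness of the estimators under the
stated statistical model, not robustness to those instrumental effects.

## Problem sizes and runtimes

The test suite simulates 2,000–20,000 events or runs per check, chosen so
the whole suite completes in a few minutes while keeping Monte-Carlo
standard errors (\~0.007 on a survival fraction at 5,000 runs) well below
the asserted tolerances. The headline dimer simulation uses the study's
own settings: dt = 1 ms, 5,000 replicates, 6-s horizon.

## Known limitations

* The strengthening law is empirical; it fits the data with two
  parameters but implies nothing about the underlying energy landscape.
* The conditional-survivor fit cannot recover information below the
  detection floor; at the highest force this widens parameter spread
  substantially (see above).
* The simulator supports at most two bonds and no spatial geometry of
  receptor positions; rebinding is a single load-independent rate.
* Wall-correction coefficients are contact-limit constants; no
  lubrication-theory gap dependence.
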
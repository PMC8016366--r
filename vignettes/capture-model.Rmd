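---
title: "The capture model: assumptions, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The capture model: assumptions, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porecapture)
```

## The stationary capture problem

`porecapture` treats the molecule as a point particle diffusing in the
half-space outside the pore mouth.  Radial symmetry is assumed about the
entrance: every field the particle feels — the funnel-shaped electric
field, the electroosmotic solvent inflow, and the dielectrophoretic pull
on an aligned permanent dipole — is projected onto the radial coordinate
`r`, measured from the entrance, on the domain `r ∈ [r_e, ∞)`.  The
stationary advection–diffusion equation then has the first integral
`J(r) = -A/r^2`, and the number of particles absorbed per unit time is
`f = 2*pi*A`.

Three assumptions are load-bearing and worth stating plainly:

* **Radial fields.**  The hemispherical-entrance approximation
  `E_r(r) = -I/(2 pi sigma r^2)` (and the analogous `u_f = Q_f/(2 pi r^2)`
  advection) is exact only far from the pore; close to the mouth the true
  field is 3D.  All closed forms inherit this.
* **Aligned rigid dipole.**  The dielectrophoretic term assumes the
  permanent dipole follows the local field instantaneously (rotational
  diffusion neglected) and that induced polarization is negligible, so
  the `r^-3` drift is always attractive and the capture frequency is even
  in the voltage.  Induced-dipole (gradient-of-`E^2`) dielectrophoresis is
  deliberately out of scope.
* **Homogeneous diffusion.**  `D` is constant; hydrodynamic confinement
  corrections near the wall are not modeled.

The entrance (pore docking) is compressed into a single Robin rate
constant `k`: the flux through `r = r_e` is `k C(r_e)`.  `k → ∞` is a
perfectly absorbing pore (capture limited purely by transport), `k = 0` a
reflecting one.  Solving the stationary problem with this boundary
condition splits the mean capture time *exactly* into
`tau = tau_a + tau_e`:

* `f_a = 2 pi D C0 / W(r_e)` with
  `W(r_e) = ∫_{r_e}^∞ e^{-phi(r)} r^{-2} dr`, the approach frequency;
* `f_e = 2 pi r_e^2 k C0 e^{phi(r_e)}`, the entrance frequency.

The `e^{phi(r_e)}` factor in `f_e` is not optional: it is the unique
choice for which `1/f = 1/f_a + 1/f_e` coincides with the direct solution
of the Robin boundary problem.  The test suite pins this with a
consistency anchor (combination vs `2*pi*A` from the profile, relative
tolerance `1e-10`).

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `r_e` | m | pore radius | capture radius; everything scales with it |
| `q_w` | C/m² | 0 | wall charge; sets `G_eo = -sign(q_w) pi r_p^2 abs(q_w) lambda_D/(eta L)` |
| `lambda_D` | m | — | Debye screening length (user supplied, not derived from a salt recipe) |
| `dG0` | kB T | 0 | equilibrium docking barrier |
| `s` | — | 1 | docking field enhancement; multiplies `a3` in the barrier reduction only |
| `l0` | m | `r_e` | jump length of the Eyring prefactor `kappa0 = (kB T/h) l0` |
| `ratio_threshold` | — | 10 | `tau_a/tau_e` cut for the regime label |

Two of these deserve justification:

* **The jump length `l0`.**  The Eyring prefactor `kB T/h` is a frequency
  (1/s), while the Robin constant needs a velocity (m/s).  We
  dimensionalize with a jump length, defaulting to `r_e` — the natural
  length of the docking stage.  Any other microscopic choice only shifts
  `dG0` by a constant number of `kB T`, which is why barrier heights fitted
  through this model should be read as effective values.
* **Barrier coupling.**  With `barrier_coupling = "phi_at_entrance"` the
  docking barrier is lowered by `U = kB T * phi_s(r_e)`, where `phi_s`
  uses `s * a3`.  Since `f_e` itself already carries `e^{phi(r_e)}` from
  the stationary solution, the voltage dependence of `f_e` is then
  `e^{2 phi(r_e)}`-like (for `s = 1`).  Whether the barrier reduction
  should be counted once or twice is physically ambiguous; both couplings
  are selectable (`"none"` switches the `U` term off), and the dumbbell
  scenario uses the coupled form.

The regime threshold of 10 on `tau_a/tau_e` is a labeling convention for
what the theory treats as a continuum; the underlying times are always
reported.

## Numerical evaluation of the approach frequency

After `u = 1/r` the key integral is
`∫_0^{u_e} exp(-(alpha u + beta u^2)) du` with `alpha = a2/D`,
`beta = a3/(2D)`.  Two independent evaluators are provided:

* **Quadrature** (`approach_frequency_quadrature()`): adaptive
  integration on the finite interval, with the integrand rescaled by its
  maximum and accumulated in the log domain, so potentials of hundreds of
  `kB T` neither overflow nor underflow.  Relative tolerance `1e-10`.
* **Closed form** (`approach_frequency_closed()`): completing the square
  gives an error-function expression with `g = (2 D a3)^{-1/2}`.  It is
  evaluated through the *scaled* complementary error function
  (`erfcx`), with three branches depending on the sign of `a2 g` so that
  no branch subtracts nearly equal numbers; for `beta u_e^2 < 1e-6` the
  dielectrophoretic term is treated perturbatively (second-order
  expansion, error below `1e-18` relative) because the erf form would
  cancel catastrophically there.  `pracma`'s `erfcx` is used in its
  reliable range and replaced by the asymptotic series beyond `x = 25`.
  If a branch still cannot guarantee accuracy the function falls back to
  quadrature with a message.

The two routes agree to better than `1e-8` relative over both a weak-drift
grid (`|a2| ≤ 1e-25` m³/s) and physically strong drift
(`|phi(r_e)|` up to tens); this is asserted in the test suite, and the
`a3 = 0` and `a2 = a3 = 0` limits are checked against their elementary
forms `2 pi C0 a2/(1 - e^{-a2/(D r_e)})` and `2 pi D C0 r_e`.

## The Brownian-dynamics oracle

The stochastic validator integrates the overdamped Langevin dynamics in
full 3D (`x += v_r(r) (x/r) dt + sqrt(2 D dt) N(0,1)` per coordinate) —
working in 3D avoids the spurious Jacobian drift a 1D radial scheme would
need.  Choices:

* **Robin boundary**: on contact with `r_e` the walker is absorbed with
  probability `k sqrt(pi dt / D)`, else specularly reflected — the
  standard partially reflecting discretization, with `O(sqrt(dt))` bias.
  The suite includes a `dt`-halving check (estimates move by less than two
  combined standard errors).
* **Step-size control**: far from both boundaries the time step is
  enlarged so that a 6-sigma diffusive displacement still cannot reach the
  nearest boundary; inside the near-boundary zone the base `dt` applies,
  so contacts are always resolved at the base resolution.  Configuration
  invariants (`drift per base step < 0.1 r_e`, contact absorption
  probability `< 0.1`) are validated before any sampling.
* **Capture-rate estimator**: walkers are injected at `r_out` (default
  `20 r_e`) and followed to capture or escape; excursions beyond
  `2 r_out` are resolved analytically by re-injection with the exact
  return probability computed from the same potential integrals.  The
  identity `f = f_arr(r_out) * P_capture` used here is exact for any
  potential, not only for force-free far fields.
* **Determinism**: R's RNG drives the C++ core, so a seed makes runs
  bit-identical.

## The synthetic trace generator

`synth_trace()` emulates what a two-state analysis of a recording sees: a
renewal process of exponential open dwells (mean `1/f`) and exponential
blocked dwells, two current levels, and additive white Gaussian noise.
It deliberately does **not** emulate baseline drift, flicker noise,
filter rise times, sub-levels within blockades, or dwell-time
distributions with short-dwell excess — so a passing closed loop shows
that the estimator chain (threshold at `b > 0.5`, duration filter, dwell
averaging, `err(f) = err(tau)/tau^2`) is unbiased under the model's own
assumptions, not that it is robust to every artifact of real recordings.
Blocked dwells shorter than the duration filter are folded back into the
surrounding open time, which biases `tau` upward by roughly the dropped
fraction; the closed-loop tests keep that fraction well below the
statistical error, and users analyzing fast-blocking data should do the
same or lower `min_duration`.

The classic event definition on slow recordings uses a 1 s minimum
duration, which is the function default; for kHz-bandwidth data a
millisecond-scale value is the sensible setting, and the parameter is
exposed precisely because the appropriate value is
acquisition-dependent.

## Scenario fixtures and calibrated values

The packaged scenarios encode the worked systems end to end.  Where a
quantity is not derivable from first principles the fixture says so in
its `note` field:

* the electroosmotic conductance of the peptide/αHL scenario is an MD
  estimate whose printed units are garbled in the source; the stored
  magnitude is flagged unverified, and its sign follows this package's
  convention (negative: flow out of the pore at positive voltage, i.e.
  competition with electrophoretic capture of a positive peptide);
* its docking barrier (21 kB T) is calibrated so the computed mean
  capture time reproduces the observed ~1 s; the entrance-limited regime
  classification is then an output, not an input;
* the solid-state-pore protein scenarios store the published
  electroosmotic-conductance estimate (`15e-18` m³/s/V) as an override;
  the package's thin-double-layer model would give ~`23e-18` for the same
  wall charge — the ~1.5× gap is a known limitation of the no-slip
  thin-layer cylinder formula at these geometries;
* protein hydrodynamic radii and dipoles in those fixtures are
  literature-typical estimates (the dipole contribution is negligible
  there, which the computation confirms).

The competition number `b_eo/di` is implemented as the force ratio
`|a2_eo| r_e / a3` with the pore-only ionic conductance; alternative
normalizations (potential-term ratio, conductance with access resistance)
differ by factors of about two, and the chosen convention reproduces the
worked magnitudes (~0.03 and ~0.1 for wall charges of 0.006 and
0.025 C/m²) only approximately.  It should be read as an
order-of-magnitude diagnostic.

## Problem sizes used in validation

The shipped tests run the closed-form/quadrature agreement on a few
hundred parameter combinations, the Brownian-dynamics grid at 10⁴ walkers
per case (binomial standard errors of ~0.5 %, three-standard-error
acceptance), and the trace closed loop at 20 seeds per frequency with
~85 dwells per trace (2-standard-error acceptance per seed and pooled).
These sizes keep the statistical power high enough that a systematic bias
of a few percent would fail the suite, while remaining desk-scale.

## Known limitations

* Quantitative capture frequencies in barrier-dominated systems depend on
  the effective `dG0` and `l0`, which this model cannot predict from
  structure; it predicts *shapes* (voltage dependence, polarity symmetry,
  regime crossovers) and transport-limited magnitudes.
* The radial-field idealization overestimates how well the hemispherical
  formulas hold within a nanometre of the mouth — exactly where docking
  happens; the field-enhancement factor `s` is an acknowledged effective
  patch for this.
* The thin-double-layer electroosmotic conductance assumes
  `r_p >> lambda_D`, no slip and no entrance effects; a warning fires
  when `r_p < 5 lambda_D`, and measured or simulated overrides always win
  over the model value.
* Flexible polymers (entropic, spatially extended entrance barriers) and
  post-capture translocation dynamics are out of scope.
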
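---
title: "Stochastic adaptation in the two-state protein motif: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic adaptation in the two-state protein motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptmotif)
```

## The motif and what it is for

Adaptation is a signaling system's ability to mount a transient response to
a sustained input and then return to (near) its pre-stimulus equilibrium.
The minimal architecture with this property is a protein interconverting
between an unmodified state P and a modified state Pm:

* synthesis of P at rate `ks` (micromolar per time unit),
* basal interconversion P -> Pm (`kf`) and Pm -> P (`kr`) (1/time),
* a signal-coupled modification channel with propensity `ka * A(t)` per P
  molecule, where A(t) is an external piecewise-constant input in
  micromolar and `ka` has units 1/(uM time),
* independent degradation of both forms (`dP`, `dPm`, 1/time).

At a constant signal the deterministic equilibria are
`P* = ks (kr + dPm) / D` and `Pm* = ks (kf + ka A) / D` with
`D = dP kr + dPm (dP + kf + ka A)`. When one degradation rate vanishes, the
*other* species' steady state becomes independent of the input
(`Pm* = ks / dPm` for `dP = 0`): sustained inputs shift the equilibrium of
P but not of Pm, which is perfect adaptation. A small positive `dP` gives
near-perfect adaptation, with equilibria that converge to the perfect ones
as the input grows (`equilibrium_convergence()`).

The default parameterization is `ks = 0.01, ka = 1, kf = 1, kr = 10,
dPm = 1`, with `dP` either 0 or 0.01, in a volume of one femtoliter. At
that volume 1 uM corresponds to `V * N_A * 1e-6 ~ 602` molecules, so the
system holds tens of molecules — exactly the regime where a deterministic
description and the stochastic reality can disagree qualitatively.
Zeroth-order rate constants are multiplied by `V * N_A * 1e-6` when moving
to molecule units, second-order ones divided by it; the signal channel
keeps its macroscopic value because A stays in micromolar.

## Study conditions emulated by the scenario generator

`scenario()` bundles the input protocols and configurations the analyses
run under; these defaults *are* the study conditions, not tuning knobs.

* **Step protocol** (`adaptation_signal(F_i)`): A = S(t) * F_i with S equal
  to 0, 1, 0, 1, 2, 3, 4 on successive 50-unit intervals up to t = 350,
  and F_i drawn from 0.01, 0.1, 1, 10, 100. Initial copy numbers
  (P, Pm) = (60, 6), i.e. 0.1 and 0.01 uM — close to equilibrium.
* **Output grid** (`output_time_grid()`): nine dyadic offsets
  `50 * (2^-14, 2^-12, ..., 2^-2, 1/2, 1)` per interval, resolving the fast
  post-switch transient.
* **Fold profiles** (`fold_profiles()`): A1 steps through 2^0..2^10 uM on
  consecutive 50-unit intervals, A2 = 2 * A1 at identical times. The first
  interval of each profile sits at the profile's background level, and the
  run starts at that level's equilibrium, so every subsequent interval
  begins with a genuine fold-2 step. This is a deliberate design choice: a
  zero-level baseline would make the first step an *infinite* fold change
  (and a different absolute jump for A1 and A2, 0 -> 1 vs 0 -> 2 uM), for
  which fold-change detection makes no prediction — the two onset responses
  differ by ~27% while all fold-2 steps agree within 10%. Weber-style
  fold-change reasoning requires a nonzero background as the reference.
  A relaxation gap between fold steps is configurable (`gap`, default 0).
* **Population size** 50 cells for the single-cell vs population contrast;
  ensembles of 2,000-10,000 for moment comparisons.
* **Seeding**: one master seed per scenario; cell `i` uses `seed + i`, so
  ensembles are reproducible and independent of worker chunking.
* **Mediated variant** (`mediator_kinase`, `mediator_trapping`): the
  kinase/phosphatase extension with `ks = 0.05, kf = 1, kr = 0.1,
  dP = 0.01, dPm = 10, ka1 = 1e3` and the remaining rates 10 (or
  `ka2 = ka3 = 0.1` for the trapping variant). Here the signal *is* a
  species: signal steps set the unbound kinase copy number, leaving
  complexes untouched, and signal molecules can accumulate in bound form.
  Choices the study conditions leave open are documented as such: initial (P, Pm) are the
  kinase-free equilibrium of the linear part, complexes start empty, and
  the phosphatase starts at 0.1 uM; the catalytic scheme assigns `ka2` to
  complex unbinding and `ka3` to catalysis (symmetrically `kd2`/`kd3`),
  consistent with attributing trapping to a large `ka1/ka2` ratio.

## Exact probability-space solution (FSP)

The chemical master equation over states (n, m) is truncated to the
rectangle P in [0, MP], Pm in [0, MPm] (defaults 110 and 30; 3441 states,
enumerated as `j (MP + 1) + i + 1`). The generator follows the convention
`dp/dt = G p` with columns summing to zero for interior states — the
convention consistent with propagating column vectors of probabilities.
Transitions that would leave the rectangle are dropped while their
propensities remain on the diagonal, so the lost mass is exactly the
truncation error certificate of finite state projection, and retained mass
is non-increasing in time.

Within each constant-signal interval the solution is
`p(t + d) = expm(d G) p(t)`. The exponential action is computed by
**uniformization**: `G = lam (P - I)` with `P = I + G/lam` substochastic
for `lam >= max |diag G|`, giving a series of non-negative terms weighted
by Poisson probabilities. The series is truncated when its remaining tail
drops below `tol` (default 1e-10), and the time step is split so
`lam * dt <= 256` per substep, keeping the scaled weights `a^k / k!` inside
double range. A dense exponential is never formed; the implementation is
validated against `Matrix::expm` on small spaces (agreement ~1e-13) and
against an independent dense Euler integration of the master equation.

Numerical conventions worth stating:

* Probabilities are floored at 1e-280 (flushing subnormals costs nothing at
  tolerance 1e-10 and avoids a ~100x subnormal-arithmetic penalty).
* Moments are renormalized by retained mass; raw probability vectors never
  are, so truncation error stays visible.
* `fsp_propagate()` aborts, naming the worst time point, if retained mass
  falls below `mass_threshold` (default 0.9999); pass 0 to obtain the
  achieved mass instead.

On the state-space certificate: for the near-perfect scenario at F_i = 1
the rectangle retains 99.998% of the mass over the whole protocol. For the
*perfect*-adaptation variant the P equilibrium at zero signal is 66.2
molecules and the n = 110 boundary leaks ~1.3e-4 of mass over the
signal-free stretches (plus ~7e-5 at the Pm = 30 boundary during onset
transients), so the globally accounted minimum is 99.980% — slightly below
the 99.99% certificate that each per-interval FSP solve satisfies on its
own. The package reports the global number because it bounds the 1-norm
error against the untruncated solution; enlarge `state_space()` if a
stricter certificate is needed.

The initial distribution is a point mass at (60, 6) by default; a
truncated product-Poisson initializer with the same means is available
(`fsp_initial(type = "poisson")`) because the open, purely first-order
network maps Poisson laws to Poisson laws at all times. The two choices
give indistinguishable set probabilities by the end of the first interval
(difference < 5e-3), as expected from that stability; the headline "~32%
on 5-6 molecules of Pm at t = 100" is computed from the point mass.

## Trajectory-level solvers

* **SSA** (`ssa_run()`): direct-method Gillespie, exact for the jump
  process. Propensities are recomputed at every firing, and the waiting
  time is re-drawn at every signal switch — valid because the exponential
  clock is memoryless, and necessary because the propensities change
  discontinuously there. Chosen over next-reaction variants: with 6-11
  reactions the direct method's simplicity wins. Event records are kept
  compressed as (time, state) pairs with left-hold queries; ensemble runs
  sample on a grid and accumulate moments online.
* **CLE** (`cle_run()`): Euler-Maruyama on the chemical Langevin equation
  in molecule units, one independent Wiener channel per reaction with
  amplitude `sqrt(a_r(x))`. Negative excursions are handled by clamping
  propensity arguments at zero (reflection would distort the stationary
  law near boundaries). Default `dt = 1e-3`: the fastest first-order rate
  is ~10/time, so dt is two orders below the fastest relaxation; a warning
  fires beyond `0.1 / fastest rate`. Because the drift is affine, the path
  mean solves the ODE up to discretization error — the basis of the
  mean-vs-ODE validation.
* **ODE** (`solve_piecewise()`): the 2x2 affine system is solved in closed
  form per interval by eigen-decomposition (equivalently, matrix
  exponential plus variation-of-parameters particular solution), with
  state continuity at switches. No adaptive integrator is needed; deSolve
  serves as an independent oracle in the tests. Peaks for the response
  metrics are located on a >= 2000-point per-interval grid and polished
  with `stats::optimize()` on the exact segment solution, because the
  nine-point output grid can miss maxima.

## Fold-change detection statistics

`interval_peaks()` records, per signal interval, the peak response, its
time, and the boundary values. The statistics of `ratio_statistics()` and
`relative_difference_statistics()` — `|y1_{j+1}/y1_j|`, `|y1_j/y1_{j+1}|`,
`|y1_j/y2_j|` and the corresponding relative differences — operate on raw
peak values (not baseline-subtracted) over the *step* intervals, aligned
by index between profiles. The verdict applies the 10%-amplitude
criterion: FCD is reported when every supplied value is at or below the
threshold. Mixed units (uM vs molecules) are rejected rather than
converted. On the deterministic peaks the cross-profile statistic maxes at
8.5% and the consecutive-step statistic at 7.9%, so the criterion holds
with margin; the same verdict is reproduced on SSA ensemble means (with a
noise allowance reflecting the Monte-Carlo error of a finite ensemble).

## Adaptation metrics and the ergodicity diagnosis

Sensitivity (peak minus pre-stimulus level) and precision (post- vs
pre-stimulus equilibrium gap) are computed on a trailing moving average of
the sampled trajectory (`adaptation_metrics()`). The window is 20% of a
50-unit interval (10 time units), sampled at `window/40`:

* the slowest relaxation time of the stimulated motif is ~6.4 time units
  at the reference signal level, so a 10-unit window integrates the whole
  transient excess instead of picking an instantaneous extreme, which for
  Poisson-level copy numbers is dominated by shot noise;
* a finer choice matters at strong signals, where the onset burst decays
  in ~2 time units and a coarse Riemann sum inside the window clips it;
* equilibria use the same trailing window at interval boundaries, which is
  quasi-stationary because relaxation rates are >= ~0.15/time.

The verdict (`adaptation_verdict()`) labels each stimulation interval
(level increased) against a noise floor, by default two standard
deviations of the species' samples from an unstimulated run of the same
kind and length (`noise_floor()`): for a single cell this approximates
`2 sqrt(mean)` (Poisson fluctuations, ~4.9 molecules for Pm), for a
50-cell mean it shrinks by `sqrt(50)` (~0.7). An interval is *adaptive* if
sensitivity exceeds the floor while the precision gap stays within it. The
overall label is adaptive if **any** stimulation interval is adaptive: the
motif provably loses sensitivity under repeated stimulation (consecutive
steps of the protocol are ever-smaller fold changes), so a trace that
responds and re-adapts on the large onset steps has demonstrated
adaptation even if later steps sink below noise. A majority rule would
misclassify exactly the strong-signal single-cell regime. These thresholds
are analysis conventions, not claims inherited from any measurement; they
are exposed as arguments.

Under these conventions the three regimes separate cleanly: at F_i = 0.01
neither single cells nor the 50-cell mean respond; at F_i = 1 the
population mean is adaptive while the large majority of single cells are
non-responsive — adaptation as a purely collective property; at F_i = 100
both are adaptive. This is the ergodicity rupture: the snapshot law of
many cells and the time-series law of one cell need not coincide under a
time-inhomogeneous input. `compare_sampling_schemes()` makes the
distributional statement directly, histogramming a same-time snapshot of n
independent cells against n equally spaced observations of a single run
and reporting their total-variation distance. Under a constant signal both
converge to the same stationary law (TV ~ 0.01 at n = 1e4, the positive
control); under the stepping protocol they disagree grossly. No formal
hypothesis test is attached: the claim is structural, not inferential.
T* (the observation start) has no privileged default — stationarity is the
caller's responsibility.

## Poisson structure as a cross-check

The open, first-order network maps product-Poisson laws to product-Poisson
laws, so at every interval endpoint the FSP marginal of Pm should sit near
Poisson(first moment). `poisson_distance()` reports the total-variation
distance on the truncated support, counting the Poisson tail beyond the
support as discrepancy; values stay below 0.02 at all endpoints, and the
~32%/~68% split of the 5-6 molecule band at t = 100 is just
`dpois(5, 6.02) + dpois(6, 6.02)`. This is simultaneously a physics
statement (why single-cell variability is as wide as it is: sd
`sqrt(6) ~ 2.45` molecules around a mean of 6) and an implementation
check, since nothing in the solver assumes it.

## Problem sizes and limitations

The shipped tests and the acceptance script use 2,000-10,000 SSA runs or
CLE paths for moment comparisons, 50 cells for the population contrast,
10^4 samples for distributional checks, and the 3441-state rectangle for
FSP — sizes chosen so every statistical assertion has at least 3-sigma
headroom while a full run stays in the minutes range on one core.

What the synthetic conditions do not emulate: extrinsic noise and
cell-to-cell parameter variability, cell growth/division (the ergodicity
statement here holds for cell-cycle-arrested, non-interacting cells, which
is what makes it stark), spatial effects, and delays. The mediated model
is analyzed at trajectory level only — its reachable state space makes a
direct FSP solve impractical, and no claim about its exact law is made.
Passing tests therefore certify the solvers and statistics under the
stated linear-network conditions, not the behavior of any real signaling
pathway.
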
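---
title: "Adaptive path collective variables with stabilized WTM-eABF sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive path collective variables with stabilized WTM-eABF sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pathsampler)
```

## The problem

Computing a free-energy profile for a multistep molecular transition
requires a reaction coordinate that follows the mechanism.  For
complicated transitions no single predefined collective variable (CV)
does; a *path collective variable* (PCV) instead measures progress
along a discretized curve — a string of `M` nodes — through a space of
candidate CVs, and the curve itself is adapted on the fly toward the
minimum free energy path (MFEP).  `pathsampler` implements this
machinery together with three bias engines that drive the sampling
along the progress coordinate — metadynamics (MtD), well-tempered
metadynamics (WTM), and the extended-system adaptive biasing force
hybrid (WTM-eABF) — plus the estimators that turn the sampled data
into a potential of mean force (PMF).

All of it is exercised end to end on an analytic two-dimensional
Müller–Brown (MB) surface, where exact references (stationary points,
a nudged-elastic-band minimum energy path, closed-form 1D profiles)
make every component testable.

## The geometric path CV

For a point $z$ in CV space with closest path node $z_m$ (ties go to
the lower index), define $v_1 = z_m - z$, $v_2 = z - z_{m-1}$,
$v_3 = z_{m+1} - z_m$.  The progress is

$$ s(z) = \frac{1}{M-1}\left[ m +
   \frac{\sqrt{(v_1\!\cdot\!v_3)^2 - |v_3|^2(|v_1|^2 - |v_2|^2)}
         - v_1\!\cdot\!v_3}{2|v_3|^2} - \frac{1}{2} \right], $$

which equals the fractional arc length exactly on straight equidistant
paths and interpolates smoothly between nodes on curved ones.  One
ghost node is linearly extrapolated beyond each end so projections
slightly outside the path span behave sensibly; `s` is clamped to
$[-0.1, 1.1]$.  The distance from the path, $d(z)$, is the
perpendicular distance to the line through the segment joining the two
closest nodes.  Both carry analytic gradients (`path_locate()`).

Because the closest-node assignment switches discretely, $s$ is only
piecewise smooth: it can jump when the path is updated or when the
system shortcuts a strongly curved path segment.  Handling those jumps
is the central stability concern below.

### Path adaptation

Between updates, every sampled point adds tent-shaped weights
$1\!-\!f$ and $f$ to the two nodes bracketing its continuous node
coordinate $\sigma = s\,(M-1)$ together with its displacement from the
path, $z - P(z)$.  At an update each interior node moves by its
weighted mean displacement (endpoints are anchored at the metastable
states), optionally damped by a memory weight of the current path
whose half-life is `tau` update events, then the node string is
smoothed (each interior node pulled `smooth/2` toward the midpoint of
its neighbours) and reparametrized to equidistant nodes.

Numerical choices worth knowing:

* **Reparametrization** iterates equal-arc resampling to its fixpoint,
  so chord lengths equalize to $10^{-10}$ relative and the operation
  is idempotent.  Re-chording a curved polyline shortens it slightly
  (about $10^{-3}$ relative for a coarse quarter circle); nodes stay
  within that distance of the original curve.
* **Smoothing** (default 0.1) is what lets adaptation propagate
  around sharp bends: the perpendicular density only pulls nodes where
  the system currently samples, and without smoothing a bend stalls at
  the first strongly curved segment of the target path.
* **`tau`** defaults to 0 (each update is the plain weighted mean);
  memory trades adaptation speed for noise averaging and did not
  improve the benchmark robustly.

## Bias engines

MtD/WTM deposit Gaussian hills (height $h_0$, width $\sigma_G$, every
$\tau_G$ steps) directly on a grid over $s$; WTM scales new heights by
$\exp[-U_\mathrm{bias}/(k_B\,\Delta T)]$.  In the extended-system
variants a fictitious particle $\lambda$ is coupled to $s$ by a spring
of stiffness $k = k_B T/\sigma^2$ — $\sigma$ is the thermal width of
$\lambda$ about $s$ — and *all* bias forces act on $\lambda$: the
ramped ABF force (the running per-bin mean of the accumulated
free-energy-gradient samples $k(\lambda - s)$, fully applied beyond
`abf_nfull` samples) plus, for WTM-eABF, the gradient of the WTM
potential.  Harmonic walls keep $\lambda$ on the grid; without them
the WTM bias eventually expels $\lambda$ into a bottomless pocket
beyond the grid edge.

**Stabilization.**  When the CV jumps discontinuously the spring is
suddenly stretched and the extended system is violently heated.  The
correction detects a jump as a single-step CV change larger than
$\sigma$ and translates $\lambda$ by the same jump, leaving the spring
extension — and hence the coupling energy — exactly continuous; the
$\lambda$ velocity is untouched and sub-threshold dynamics are never
modified.  The trigger deliberately compares $|s_t - s_{t-1}|$, not
the spring extension: in equilibrium the extension *is* distributed
with width $\sigma$, and during barrier transmission its static value
is $A'(\lambda)/k$, several $\sigma$ — an extension-triggered rule
fires continuously and destroys the force transmission of eABF (we
measured exactly that).

**Distance confinement.**  A one-sided harmonic restraint beyond
$d_0$ keeps the system near the path.  The benchmark presets use a
mild restraint ($k = 100$, $d_0 = 0.2$) for the adaptive
extended-system runs — it suppresses shortcutting through the
concave side of strongly curved path sections — and none for the
MtD/WTM and static-path runs.

## Units and masses

Energies are kJ/mol, times fs, temperatures K,
$k_B = 0.008314463$ kJ/(mol K); coordinates are dimensionless lengths
in the kJ/mol–amu–fs consistent system (1 kJ/mol = $10^{-6}$
amu·len²/fs²).  The benchmark's physical particle mass (200 atomic
units) is read as electron masses ($200\,m_e \approx 0.11$ amu): with
amu-scale masses the intrawell relaxation times on this surface reach
hundreds of ps and a 500 ps run can neither thermalize nor adapt,
while the $m_e$ reading reproduces the benchmark's qualitative
behavior throughout.  The extended particle's inertia stays amu-scale
(25), roughly 1800× the physical particle, so $\lambda$ moves
quasi-adiabatically; a light $\lambda$ rings violently against the
stiff coupling spring.

## Estimators

* `pmf_from_wtm()` — bias inversion,
  $A = -\tfrac{T+\Delta T}{\Delta T} U_\mathrm{bias}$ (plain MtD as
  $\Delta T \to \infty$).
* `pmf_from_forces()` — trapezoidal integration of the per-bin mean
  spring force.  The conditional spring average estimates
  $\mathrm{d}A_\lambda/\mathrm{d}\lambda$ *exactly*, independent of
  any bias acting through $\lambda$ only — but $A_\lambda$ is the
  $\sigma$-convolved profile.  When the profile curvature in CV units
  approaches $k = k_BT/\sigma^2$ the convolution visibly compresses
  wells and barriers; on the MB benchmark ($|A''| \sim k$ at
  $\sigma = 0.01$) this is an $\mathcal{O}(10\ \mathrm{kJ/mol})$
  systematic, while for molecular applications with
  $|A''| \ll k$ it is negligible.
* `mbar_pmf()` / `mbar_solve()` — the trajectory is decomposed post
  hoc into biased states of constant $\lambda = \lambda_i$ (grouped by
  path epoch, with epochs merged while the path moves less than a
  tolerance), the multistate Bennett acceptance ratio equations are
  solved by Newton iteration with objective backtracking, and the
  unbiased per-frame weights are histogrammed along *any* coordinate —
  in particular along the final path, which removes the convolution
  error above.  Free energies are only defined within a connected
  component of the state-overlap graph; disconnected minority
  components are dropped with a warning.
* `barrier_from_pmf()` — plain profile barrier (max between the
  reactant and product minima minus the reactant minimum), labelled as
  such.
* Confidence bands come from block averaging (default five blocks).

The three estimators agree within 1 kJ/mol RMSE on a converged 1D
double-well benchmark (quartic well, 10 kJ/mol barrier, 300 K, 1 ns of
WTM-eABF) where the exact profile is the potential itself.

## The CV-quality criterion

`criterion_profile()` monitors
$D_S(z) = \langle \nabla S \cdot \nabla U \rangle_{S = z}$, the
conditional mean of the physical force projected on the CV gradient.
Every applied bias acts through $s$ (or $\lambda$) only and therefore
cancels in the conditional average; on piecewise-linear path segments
the curvature correction vanishes.  The quantity crosses zero at every
free-energy stationary point along the path and in particular at the
transition state — on converged benchmark runs the crossing lands
within one bin (0.02 in $s$) of the NEB saddle.

## The Müller–Brown benchmark and what it shows

The frozen presets (`preset_config()`, `run_preset()`) follow the
benchmark conditions: MB surface with the canonical constants and
$B = 1$ kJ/mol, one particle at 50 K, friction 0.001 fs⁻¹, 500 ps =
$10^6$ steps of 0.5 fs, a 30-node straight guess path between the
shallow lower-right and the deep upper-left minimum (started at the
shallow end, $s \approx 0$), path updates every 10 ps, hills of
0.01 kJ/mol width 0.05 every 25 steps, $\Delta T = 5000$ K,
$\sigma = 0.01$, ABF ramp full at 50 samples, grid bin 0.01 on
$[-0.1, 1.1]$.  The guess path is orthogonal to the MEP, which hooks
through a third, middle basin.

What the suite demonstrates at these conditions:

* Path adaptation converges to the NEB MEP (mean node deviation
  0.02–0.05) including the sharply hooked saddle approach.
* The stabilization correction is the difference between night and
  day: paired-seed runs show maximum 1 ps rolling temperatures of
  order $2\times10^3$ K with the correction and $10^5$–$10^7$ K
  without (the uncorrected extended system blows up at path updates).
* MtD escapes the first basin before WTM, as the hill-height scaling
  predicts; the measured replica-mean escape times (first crossing of
  $s = 0.8$) are 180–230 ps (MtD) and 200–330 ps (WTM) — the same
  ordering as the literature values for this setup (50 and 100 ps) but
  roughly 2–4× slower.  Escape here is fill-rate-limited, and with the
  printed hill schedule the maximum possible fill rate is
  0.8 kJ/mol/ps against a 36 kJ/mol exit barrier; the shorter
  literature times would require near-perfect hill stacking, so we
  attribute the gap to surface/bookkeeping details that are not in the
  sources available to this package.
* The PMF along the converged path tracks the MEP energy curve in
  shape, but at these conditions two floors keep the RMSE above
  1 kJ/mol within 500 ps: the $\sigma$-convolution compression of the
  mean-force estimator (above), and, for MBAR, a genuine sampling gap
  at the saddle top where the occupancy is suppressed by the residual
  uncompensated bias over $k_BT = 0.42$ kJ/mol.  Both are reported
  honestly by `convergence_time()`.
* Reweighting a static-straight-path run onto the MEP recovers the
  reference wherever the sampling overlaps the MEP and produces
  localized artifacts where it does not (near the hooked saddle and
  the middle-basin valley) — the expected behavior of
  post-hoc reweighting without overlap.

### What the generator does not emulate

The synthetic benchmark is a single particle on an analytic 2D
surface: no solvent, no multiple time scales, no CV-space curvature of
real molecular CVs, and temperatures/barriers chosen so that unbiased
escape is impossible on the simulated timescale.  Passing tests here
validate the machinery (geometry, integrators, bias bookkeeping,
estimators, stabilization) — not the accuracy of any particular
molecular application, where CV quality and sampling depth dominate.

## Problem sizes used by the test suite

Full benchmark runs are $10^6$ steps and take on the order of a second
each with the compiled core; the acceptance-style checks use five
replicas per experiment.  The 1D estimator benchmarks run $2\times10^6$
steps.  MBAR problems are subsampled (every 4th–10th frame) because
consecutive frames are strongly correlated.
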
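---
title: "Elastic self-propelled-particle sheets: model, order measures, and criticality scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic self-propelled-particle sheets: model, order measures, and criticality scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placosheet)
```

## The scientific problem

Placozoans (*Trichoplax adhaerens*) are flat, millimetre-scale marine
animals that crawl on substrates through the collective beating of
thousands of ventral cilia, with no neurons and no body axis to organize
the effort. How well such a decentralized tissue coordinates its
locomotion — and how that coordination degrades as the animal grows — is a
question about collective order in a sheet of locally coupled, individually
propelled units. `placosheet` provides both halves of the toolkit this
question needs: a minimal mechanistic simulation of such a sheet, and the
measurement stack that quantifies collective order, fluctuations and their
spatial correlations in any per-frame velocity field, whether simulated,
synthetic, or imported from optical-flow software.

## The model

The sheet is a two-dimensional collection of $N$ self-propelled particles
on a fixed interaction network. Each particle $i$ has a position
$\mathbf{r}_i$ and a heading angle $\varphi_i$, and obeys overdamped
dynamics:

$$\frac{d\mathbf{r}_i}{dt} = v_0\,\hat{\mathbf{v}}_i(t)
  + \mu \sum_{j \in \mathcal{N}_i} \mathbf{F}_{ij},$$

$$\frac{d\varphi_i}{dt} = \frac{1}{\tau}\,\sin(\theta_i - \varphi_i)
  + \eta_i(t),$$

where $\hat{\mathbf{v}}_i = (\cos\varphi_i, \sin\varphi_i)$,
$\mathbf{F}_{ij} = k\,(|\mathbf{r}_{j}-\mathbf{r}_i| - r_0)\,
\hat{\mathbf{r}}_{ij}$ is a linear attraction–repulsion spring with
coupling $k$ and equilibrium spacing $r_0$, $\theta_i$ is the polar angle
of the net spring force on $i$, and $\eta_i$ is Gaussian white noise with
$\langle \eta_i(t)\eta_i(t')\rangle = 2D\,\delta(t-t')$. Headings relax
toward the direction of the local elastic force with time scale $\tau$;
there is no explicit alignment rule, so any directional consensus is an
emergent property of the force–heading coupling. The neighbor set
$\mathcal{N}_i$ is the first Voronoi shell of the initial configuration
and is never updated (cells in a tissue do not swap neighbors on the time
scales of interest). One particle stands for a disc of tissue roughly
20 µm across — the typical fiber-cell spacing — and the simulation itself
is dimensionless: lengths in units of $r_0$, times in units of $\tau$.

### Numerical scheme and its choices

* **Integrator.** Euler–Maruyama with additive angular noise
  $\sqrt{2D\,dt}\,\xi_i$, $\xi_i \sim \mathcal{N}(0,1)$. Both updates use
  the state at the start of the step: positions move with the current
  headings and forces, then headings relax toward the same force field.
  The default step is $dt = \min(0.01, \tau/10)$, and the constructor
  refuses $dt > \tau/10$; instabilities at stiff $k\,dt$ raise an error
  naming `dt` rather than silently producing garbage.
* **Zero-force regularization.** $\theta_i$ is undefined where the net
  force vanishes. The relaxation term is set to zero whenever
  $|\mathbf{f}_i| \le 10^{-10}$ (in $k r_0$ force units) rather than only
  at exactly zero: at the equilibrium lattice the summed spring forces are
  roundoff-level, and the angle of a $10^{-16}$-magnitude vector is
  numerically meaningless. This choice preserves the exact fixed point in
  which an equilibrium sheet with a common heading translates rigidly
  forever.
* **Topology.** Voronoi adjacency is computed exactly by a
  perpendicular-bisector feasibility test (each other site contributes one
  linear inequality in the bisector coordinate), then edges longer than
  $1.8\,r_0$ are pruned to remove the spurious hull-spanning edges a
  Delaunay triangulation produces along an open boundary. The sheet is a
  free-standing disc: there is no confinement and no periodic boundary.
* **Reproducibility.** The compiled inner loop draws its noise from R's
  RNG in the same order as the exported R-level stepper, so a run is
  bitwise reproducible from its seed and the two code paths can be checked
  against each other (the test suite does).

### Parameter defaults and calibration

$\mu = 1$ and $r_0 = 1$ rescale force and length; $v_0 = 1$ and
$\tau = 1$ set the time unit. The spring coupling $k$ is the control
parameter of every scan (default grid $\{0.5, 1, 2, 3, 3.5, 4, 5, 8\}$,
sizes $N \in \{100, 400, 1600\}$). The angular noise intensity $D$ is the
one genuinely free constant. It was calibrated once, on a coarse scan of
$D \in \{0.15, 0.25, 0.35\}$ at $N = 400$, to the value $D = 0.35$ at
which the finite-size susceptibility peak of the order–disorder transition
sits inside the scanned coupling range (near $k \approx 3\!-\!4$, where
the reference phenomenology places it): at $D = 0.5$ the transition lies
beyond $k = 8$ for $N \ge 400$, and at $D \le 0.25$ the sheet is ordered
almost everywhere on the grid. The value was frozen after that scan; all
reported behavior uses it.

Run lengths for sweeps are a burn-in of 100 time units followed by 80
sampled frames at interval 1.0 ($1.8 \times 10^4$ steps per run). Burn-in
adequacy was checked at the stiffest grid point ($k = 8$, $N = 400$):
tripling the burn-in leaves the mean order unchanged within replicate
noise. These sizes keep a full scan with five replicates within desk-scale
minutes; they are the package's default study conditions, configurable via
`sweep_control()`.

## Order measures

For a per-frame velocity field $\{\mathbf{r}_i, \mathbf{v}_i\}$ with unit
velocities $\hat{\mathbf{v}}_i$ and unit radials $\hat{\mathbf{r}}_{ic}$
from the frame's centre of mass,

$$P = \Big\lVert \tfrac{1}{N}\sum_i \hat{\mathbf{v}}_i \Big\rVert,\qquad
  R = \tfrac{1}{N}\sum_i (\hat{\mathbf{r}}_{ic} \times \hat{\mathbf{v}}_i)_z,\qquad
  \Delta = \tfrac{1}{N}\sum_i \hat{\mathbf{r}}_{ic} \cdot \hat{\mathbf{v}}_i,$$

and the unified order is $O = \sqrt{P^2 + R^2 + \Delta^2}$: 0 for complete
disorder, 1 for a pure affine (solid-body) motion. Conventions worth
stating:

* $P$ is the Euclidean norm of the mean unit vector; $R$ and $\Delta$ are
  kept signed (counterclockwise and expansion positive) and enter $O$
  squared.
* Zero-velocity entries have no direction and are excluded (reducing $N$);
  entries at the exact centre of mass are excluded from $R$ and $\Delta$.
* $O$ can marginally exceed 1: a finite sample of a pure translation
  carries $O(N^{-1/2})$ residues in $R$ and $\Delta$ (and a pure rotation
  in $P$), and strongly asymmetric footprints can push a translation's
  mean radial projection away from zero. The raw value is always
  reported — never clamped — and tests compare against 1 at the
  $N^{-1/2}$-appropriate tolerance.

## Affine decomposition and the noise proxy

The collective component of the motion between frames $y(t)$ and
$y(t+dt)$ is the best similarity transform (translation $\mathbf{T}$,
rotation $R$, isotropic dilatation $\Delta_{\mathrm{aff}}$); the residuals

$$\mathbf{u}_i = \big(y_i(t+dt) - \mathbf{T}
  - \Delta_{\mathrm{aff}} R\, y_i(t)\big)/dt$$

are the velocity fluctuations, and $\epsilon = \sum_i |\mathbf{u}_i|\,dt$
is the residual magnitude. The default solver is the closed-form
similarity Procrustes solution of the least-squares objective (frames are
centred on their means first; the reported $\mathbf{T}$ absorbs the
centring). Because the residual sum of magnitudes — not of squares — is the
quantity of record, an exact L1 mode is available
(`objective = "l1"`, Nelder–Mead refinement started from the closed form);
$\epsilon$ is reported as $\sum_i |\mathbf{u}_i|$ under both objectives,
and the suite verifies $\epsilon_{L1} \le \epsilon_{L2}$. Shear is
deliberately outside the transform family.

The noise proxy is the fluctuation share of the velocity power,
$\eta^* = \langle|\mathbf{u}|^2\rangle / \langle|\mathbf{v}|^2\rangle
\in [0, 1]$: 0 for pure affine motion, 1 when the optimal affine
transform is the identity and no collective component exists. (The ratio
is defined on mean squared magnitudes; the fluctuation vectors are divided
by $dt$ so the ratio is dimensionless.) $\eta^*$ serves as a per-frame
stand-in for the intrinsic noise level, which cannot be manipulated in
living tissue the way $k$ can be dialed in the model; in simulations it is
strongly inversely correlated with $k$.

## Correlation structure

Spatial correlation profiles bin all entry pairs by distance
($C(r)$ on $\mathbf{u}_i \cdot \mathbf{u}_j$, normalized by
$c_0 = \langle|\mathbf{u}|^2\rangle$ so that $C(0) = 1$; directional and
speed variants use the fluctuation unit vectors and the speed fluctuations
$\eta_i = |\mathbf{u}_i| - \overline{|\mathbf{u}|}$). The distance delta
function is realized as half-open bins of width `bin_width` (default
$r_0/2$ in simulation units — the discretization is not prescribed by the
definition, so it is a configurable convention); self-pairs populate the
$r = 0$ bin exclusively, which makes the $C(0) = 1$ normalization exact
rather than approximate. Sparse far-distance bins (single pairs across the
sheet) are reported as computed; only the profile up to its first zero
crossing enters any summary statistic.

From a profile (averaged across frames before summarizing, per-frame
extraction being available too) the package extracts:

* $\lambda_v$ — the first zero crossing, located by linear interpolation
  between the bracketing bins; flagged invalid, not thrown, when the
  profile never crosses.
* the crossing slope — a second-order polynomial least-squares fit to the
  five bins nearest the crossing, differentiated at $\lambda_v$.
* $\chi$ — the integral of a natural cubic spline of the profile,
  resampled at exactly 100 evenly spaced points on $[0, \lambda_v]$ and
  integrated by Simpson's rule (composite 1/3 rule with a 3/8 tail for the
  odd interval count; exact for cubics).
* $\chi_0 = N(\langle O^2\rangle - \langle O\rangle^2)$ — the finite-size
  susceptibility of the order parameter over a stationary series. This
  particular estimator is a convention (the standard one in the
  flocking-transition literature) and is stated as such wherever the
  package reports it.

## Criticality scans

`criticality_sweep()` runs the full pipeline over a $(k, N)$ grid with
replicates (seeds derived from the sweep seed by a counter; cells fail
independently without aborting the sweep) and records per run: mean $O$,
$\chi_0$, mean $\eta^*$, $\lambda_v$, $\chi$, and the per-run steepness
$O'(\eta^*)$ (the OLS slope of instantaneous order on instantaneous noise
proxy). `locate_critical()` takes the coupling that maximizes
replicate-averaged $\chi_0$, refines it by quadratic interpolation through
the grid maximum and its neighbors, and flags edge peaks. The regression
helpers fit the finite-size phenomenology: order against diameter
(`order_size_fit()`), steepness against log size (`steepness_size_fit()`),
and the sublinear correlation-mass law $\chi = \alpha D^\beta + \gamma$
(`chi_scaling_fit()`, nonlinear least squares initialized from a log-log
pre-fit; a constant-$\chi$ input is degenerate — $\alpha D^0$ is
indistinguishable from $\gamma$ — and is returned flagged rather than
fitted).

System "diameter" for a simulated sheet is the equivalent-circle diameter
of its footprint area, $N$ times the hexagonal area per site
($\sqrt{3}r_0^2/2$) — the same definition used for empirical footprints
(`equivalent_diameter()`), which keeps simulated and empirical scaling
fits commensurable.

Under the default conditions the scan reproduces, at desk scale, the
finite-size phenomenology of a continuous order–disorder transition: an
interior susceptibility peak in $k$ whose height grows with $N$; mean
order decreasing with size at the critical coupling but not deep in the
ordered regime; $\lambda_v$ growing with diameter at the critical
coupling; and an order–noise relation that steepens with size near the
peak. The acceptance tests assert exactly these properties and nothing
finer-grained.

## The synthetic field generator

`gen_affine_field()` emulates the per-frame flow fields that optical-flow
software extracts from tissue recordings: points scattered in a disc,
velocities a weighted sum of the three affine modes (uniform translation,
solid-body rotation about the centre of mass, radial expansion) plus
isotropic Gaussian noise carrying a prescribed fraction of the velocity
power. Every mode is normalized to unit RMS over the realized points
before weighting, so the requested `noise_power` is the field's
fluctuation power fraction by construction and the measured $\eta^*$
converges to it as $N$ grows. What the generator deliberately does *not*
emulate: spatially correlated fluctuations, footprint irregularity and
shape change, tracking dropouts, and measurement noise on positions. Tests
that pass on generated fields therefore validate the measurement stack's
algebra and conventions, not its robustness to real-data pathologies; the
filtering helpers (`area_filter()`, `edge_exclusion()` with its
10%-of-diameter default band) exist for exactly those pathologies but are
exercised here on clean geometry.

The empirical tracked-region granularity is left as a parameter (region
spacing/count in the generator) rather than hard-coded, since reasonable
definitions (a fixed region area versus the fiber-cell spacing) differ.

## Known limitations

* The heading-noise intensity enters only through $D$; there is no
  separate speed noise, and $v_0$ is common to all particles.
* No neighbor exchange, cell division, fracture, or hydrodynamic coupling:
  the model is a fixed elastic network of self-propelled units.
* $\chi_0$ depends on the susceptibility estimator convention; peak
  locations are comparable within this package but not directly to
  estimators that use connected correlations.
* Correlation-profile tail bins with very few pairs are noisy; summaries
  only ever use the profile up to its first zero crossing, which is
  supported by dense bins at every size used here.
* The scaled-down scan sizes ($N \le 4900$) are two orders of magnitude
  below a large adult animal in particle count; the scan demonstrates the
  finite-size trends, not converged critical exponents.
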
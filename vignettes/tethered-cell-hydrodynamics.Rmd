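---
title: "Hydrodynamics of stalk-tethered, veil-forming microbes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamics of stalk-tethered, veil-forming microbes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veildyn)
```

# The system

Some microaerophilic microbes — the giant sulfur bacterium *Thiovulum majus*
and the ciliate *Uronemella* are the two modelled here — live in the
diffusive boundary layer above sulfidic sediment, where oxygen arrives only
by molecular diffusion.  Both exert propulsive forces of tens of
piconewtons, tether themselves to surfaces with a mucous stalk, and
collectively weave the accumulated stalk material into a centimetre-scale
mucous sheet (a *veil*) on which the community arranges itself and pumps
water.  This package implements the individual-scale physics behind that
behaviour and a synthetic emulation of the collective-scale measurements:

* the advection-versus-diffusion scalings that set the minimum useful
  propulsive force (`stokes_force()`, `diffusive_force()`, `peclet()`);
* the resistance functions of a prolate cell body (`drag_coefficients()`);
* the flow of a point-forced cell near a no-slip wall (`stokeslet()`,
  `image_system()`, `ambient_at()`, `advect_tracers()`);
* the orientation dynamics and stability of a cell on a rigid stalk
  (`integrate_tether()`, `linear_stability()`, `critical_length()`,
  `phase_portrait()`);
* generators for synthetic stalk-elongation tracks, an oxygen-consuming
  chemotactic chamber and veil scattered-light series, plus the measurement
  stages that recover the generating parameters
  (`generate_stalk_tracks()` / `fit_elongation_rate()`,
  `simulate_chamber()` / `oxygen_map()` / `cell_density_map()` /
  `front_report()`, `generate_veil_series()` / `veil_production_fit()`).

Internally the hydrodynamic modules use a (um, s, pN, Pa s) unit system,
which is closed under the Stokes formulas: `6 * pi * mu * a * U` with `a` in
um and `U` in um/s gives pN directly.  Diffusivities enter in cm^2/s and are
converted at the interface.  The chamber works in (cm, s, % of atmospheric
oxygen saturation).

# Feeding scalings

A sessile cell pulling water toward itself with force $f_0$ drives a flow
$u \sim f_0/(8\pi\mu r)$, hence an advective nutrient flux
$j_a \sim u c$, while diffusion supplies $j_d \sim D c / r$.  Their ratio

$$\mathrm{Pe} = \frac{j_a}{j_d} = \frac{f_0}{8\pi D\mu}$$

is independent of distance, so $f_d = 8\pi D\mu$ acts as a *diffusive
force*: a cell weaker than this cannot outrun diffusion.  With
$D = 10^{-5}\,\mathrm{cm^2\,s^{-1}}$ and $\mu = 10^{-3}$ Pa s,
$f_d \approx 25$ pN; the ~40-50 pN these organisms exert puts them at
$\mathrm{Pe}\approx 2$, whereas a conventional ~1 pN bacterial swimmer sits
at $\mathrm{Pe}\approx 0.04$.

```{r}
diffusive_force()
peclet(40)
scaling_report("uronemella")
```

For *Uronemella* the preset keeps both the characteristic rounded force
(50 pN) and the raw Stokes estimate $6\pi\mu a U \approx 59$ pN computed
from its radius and swim speed; the two differ because the literature value
rounds an order-of-magnitude estimate, and `scaling_report()` reports both
rather than silently preferring one.

# Resistance functions of a prolate cell

Both organisms are modestly prolate (aspect ratios ~1.3 and ~2).  The drag
on a prolate spheroid depends on its orientation; the package uses the
classical closed forms in terms of the eccentricity
$e = \sqrt{1-(b/a)^2}$ and $L = \log\frac{1+e}{1-e}$, normalized by the
**semi-major** axis $a$ so that force $= 6\pi\mu a\,\alpha\,U$ and torque
$= 8\pi\mu a^3\beta\,\omega$:

$$\alpha_\parallel = \frac{\tfrac{8}{3}e^3}{-2e + (1+e^2)L},\qquad
  \alpha_\perp = \frac{\tfrac{16}{3}e^3}{2e + (3e^2-1)L},$$
$$\beta_\parallel = \frac{\tfrac43 e^3(1-e^2)}{2e-(1-e^2)L},\qquad
  \beta_\perp = \frac{\tfrac43 e^3(2-e^2)}{-2e+(1+e^2)L},$$

together with the shape factor $\Gamma = (a^2-b^2)/(a^2+b^2)$ that controls
how the ambient rate of strain rotates the body.  The semi-major-axis
normalization is a deliberate choice: it is the only convention that
reproduces the coefficient values quoted for these organisms (e.g.
$\alpha_\parallel = 0.60$ at aspect 2).  All four coefficients tend to 1 in
the sphere limit; below $e = 10^{-2}$ the denominators are evaluated by
their series ($-2e+(1+e^2)L = \tfrac83 e^3 + \tfrac{16}{15}e^5 + \dots$),
because three leading orders cancel and the closed forms lose
$\sim\epsilon_{\mathrm{mach}}/e^2$ relative accuracy.  At the switch point
the series is accurate to $O(e^6)\sim 10^{-12}$, so the two branches join
smoothly.

```{r}
drag_coefficients(aspect_geometry(1.3))  # T. majus-like
drag_coefficients(aspect_geometry(2))    # Uronemella-like
```

# Flow near the wall

The fluid occupies $z>0$ with a no-slip wall at $z=0$.  A cell with
orientation $\hat d$ applies the force $-f_0\hat d$ to the fluid (oriented
away from the wall, it pumps water *toward* the wall).  The wall's back-flow
is represented by an image system beneath the plane:

* `mode = "leading"` — only the sign-reversed stokeslet at the reflected
  point (the "image cell").  This is the approximation used for the
  orientation dynamics below, and it captures the dominant effect: the
  image flow at the cell points away from the wall, at the scale
  $u_s \sim f_0/(8\pi\mu\ell)$ for a cell at height $\ell$.
* `mode = "blake"` — adds the stokeslet-doublet and source-doublet
  corrections, after which the total velocity vanishes identically on the
  wall (machine precision; the test-suite checks $10^{-10}$ relative).

The far-field consequences are what make stalks worthwhile: a cell at
height $\sim a$ above the wall has its stokeslet nearly cancelled by the
image system and its feeding flow decays as $r^{-3}$, while a cell held at
$\ell \gg a$ keeps the free-space $r^{-1}$ decay in the region
$a \ll r \ll \ell$.  `decay_exponent()` fits the log-log slope and
recovers $-1$ and $-3$ in the two regimes; the wall-height fit needs the
full Blake system, since the $r^{-3}$ behaviour is produced by the
doublet-level cancellation.

`ambient_at()` returns the velocity, angular velocity
$\Omega = \tfrac12\nabla\times u$ and rate of strain
$E=\tfrac12(\nabla u + \nabla u^\top)$ of the image flow only, from
analytic gradients (finite-difference checked); the cell's own unbounded
stokeslet exerts no net force or torque on itself and is excluded.  The
cell is treated as a point: Faxen (finite-size) corrections and near-wall
modifications of the drag tensors are out of scope.

# Orientation dynamics of a tethered cell

The cell sits at the end of a rigid stalk of length $\ell$ anchored at the
origin; $\hat r$ is the stalk direction, $\hat d$ the cell orientation.
Two balances close the dynamics, both in the Stokes regime (no inertia):

**Stalk swing.**  Torque about the anchor vanishes:
$0 = \hat r \times\{f_0\hat d + 6\pi\mu a A(u - \ell\,\partial_t\hat r)\}$
with $A = \alpha_\parallel\hat d\hat d + \alpha_\perp(I-\hat d\hat d)$.
This determines $\partial_t\hat r$ only up to its component along the
stalk; that component of the force balance is carried by stalk tension, so
the implementation introduces a Lagrange multiplier along $\hat r$ chosen
to make $\hat r\cdot\partial_t\hat r = 0$ exactly.  A consequence worth
noting: with quiescent fluid and $\hat d\perp\hat r$ the swing speed is
$f_0/(6\pi\mu a\,\alpha_\parallel\,\ell)$ — the *parallel* coefficient
applies, because the cell then moves along its own symmetry axis.

**Cell reorientation.**  The torque-free condition on the cell gives

$$\partial_t \hat d = -\,\frac{\hat d\times\{3\,\hat d\times A u
  + 4a\,\hat d\times B\Omega + 4a\beta_\perp\Gamma\,(\hat d\times E\hat d)\}}
  {a(3\alpha_\perp + 4\beta_\perp)},$$

which is exactly tangent to $\hat d$.  For a small cell the $\Omega$ and
$E$ terms vanish and the cell simply aligns with the flow; the strain term
(proportional to $\Gamma$, hence absent for a sphere) is what tilts the
cell toward its image and destabilizes the upright posture on short stalks.

Integration is always in the Cartesian unit vectors, never in angles, so
there is no coordinate singularity at the upright state; the polar angles
$\theta$ (of $\hat d$) and $\phi$ (of $\hat r$) are derived outputs.  The
integrator is `deSolve::lsodar` at relative tolerance $10^{-8}$, with the
rates computed from defensively renormalized unit vectors and a root
function that terminates runs in which the cell reaches the wall
($\hat r\cdot\hat e_3 < 0.02$).  Time is kept in physical seconds — the
relevant scales (0.1-1000 s) need no rescaling for a stiff-capable solver.
Unit norms stay within $10^{-8}$ over full trajectories.

## Fixed points, critical length, timescales

For stalks longer than a critical length the only attractor is the upright
state $\theta=\phi=0$.  The closed form from the linearized planar
dynamics is

$$\ell_c = \frac{4\beta_\perp\Gamma}{3\alpha_\perp}\,a,$$

giving $\ell_c/a = 0.26$ (aspect 1.3) and $0.44$ (aspect 2) — both well
below one cell length, so any real stalk stabilizes the cell
(`critical_length()`).  Independently, `critical_length_numeric()` bisects
the leading eigenvalue of the finite-difference Jacobian of the full
reduced dynamics and finds the crossing at $\ell^*/\ell_c = 1.50$ for the
default (leading-image) model.  The package reports both numbers rather
than reconciling them: the closed form descends from a further-reduced
planar equation (`polar_rate()`, which also carries its own printed
prefactor convention $t_f\,\partial_t\theta = \dots$), and the two agree
in sign structure — destabilizing for $\ell\ll a$, stabilizing for
$\ell\gg a$ — but not in magnitude.  The test-suite asserts the sign
agreement and the order-one ratio, keeping the discrepancy visible.

Two timescales organize the motion (`timescales()`): the fast swing time
$\tau_f = 6\pi\mu a\ell/f_0$ on which cell and stalk align
($\approx 0.5$ s for $a=10$ um, $\ell=100$ um, $f_0=40$ pN) and the slow
righting time $\tau_s = \ell/u_s = 8\pi\mu\ell^2/f_0 \approx 6$ s on which
the image flow pushes the pair upright; their ratio is
$\tfrac34(a/\ell)$.  Trajectories correspondingly collapse quickly onto
$\phi\approx\theta$ and then creep to the origin.

`phase_portrait()` samples the reduced $(\theta,\phi)$ field on
$[-\pi,\pi]\times(-\pi/2,\pi/2)$ (beyond $|\phi|=\pi/2$ the cell would be
below the wall; the wall state itself is singular and excluded by a 0.12
rad margin), locates fixed points by damped Newton refinement of grid
candidates, classifies them by Jacobian eigenvalues, and can label each
grid initial condition `attracted` / `escaped` / `undetermined` by
integration with a time cap of $200\tau_s$.  At $\ell=10a$ (aspect 2) the
portrait has the single attractor at the origin and an unstable
(saddle) inverted state, which appears at both $\theta=\pm\pi$ on the
closed display range; the basin is approximately the strip
$|\theta|<\pi/2$.

# The synthetic-data generators

The generators emulate the structure of the bench observations — not their
microscopic detail — so that every measurement stage can be exercised and
its parameter recovery quantified.

**Stalk tracks** (`generate_stalk_tracks()`): anchored cells drift from
their anchor as the stalk elongates at a constant rate (presets: 0.65 um/s
for *T. majus*, 1.5 um/s for *Uronemella*), sampled at 1 Hz for 30 s with
0.3 um Gaussian localization noise per coordinate, ten cells per batch.
These are the conditions of the elongation measurement; the fitting stage
projects each track on its principal displacement axis and averages
per-track OLS slopes.

**Chamber** (`chamber_config()`, `simulate_chamber()`): a 128 x 128 grid
over a 1.5 cm square, oxygen diffusing in from Dirichlet edges held at
100 % atmospheric saturation ($D = 10^{-5}$ cm^2/s; explicit five-point
stepping, stability bound $D\,\mathrm{d}t/\mathrm{d}x^2 \le 0.25$ checked
at construction), 300 chemotactic random walkers that each consume
$10^{-4}$ % atm cm^2/s spread over a 5 x 5-pixel neighbourhood.  Walkers
take Gaussian steps (scale $2\times10^{-3}$ cm/\sqrt{s}, an effective
diffusivity $\sim 2\times10^{-6}$ cm^2/s of the right order for
run-and-tumble microbes) plus a drift
$-\chi\,(c - c^*)\,\nabla c/|\nabla c|$ with
$\chi = 5\times10^{-4}$ cm/s per % atm, capped at 30 um/s — a few percent
of the organisms' swim speed, as expected for the net velocity of a biased
random walk.  Consumption depletes the interior over ~1 h and the walkers
collapse onto the ring where the concentration crosses their preference
$c^*$ (4 % atm for *T. majus*, 7 % for *Uronemella*).

Three modelling points deserve emphasis.  First, consumption is spread
over a neighbourhood and the steering gradient uses a wide (+/-3 px)
stencil because a walker that deposits its full consumption in one pixel
carves a pit under itself and then steers by it.  Second, the drift
strength was set so the band tracks the *outward-moving* preference
contour with a lag small compared to 1 % atm; with much weaker drift the
band reads systematically below $c^*$, and with much weaker motility
secondary clumps self-trap (a dense clump depletes its own oxygen toward
$c^*$ and stabilizes — the physics that seeds the veil's later density
fluctuations, but at 300-walker scale an artifact for front detection).
Third, the rendered scattered-light frames displace each cell by an
independent per-snapshot "swimming jitter" (80 um sd): the cells swim
hundreds of um/s, so any two photos seconds apart show every cell at a
decorrelated position, and frame differencing therefore registers the
whole population rather than only the fastest net drifters.  Each stored
state carries the oxygen field, a Stern-Volmer fluorescence image
$I = I_0/(1+K_{sv}c)$, and a frame pair (20 s apart) for differencing.

What the chamber does **not** model: fluid flow and the hydrodynamic
coupling between cells, attachment/detachment kinetics, veil mechanics,
and three-dimensionality.  Passing recovery tests therefore shows that the
measurement stages are correct and well-conditioned for band-like data —
not that the model captures everything about a real chamber.

**Veil series** (`generate_veil_series()`): each cell produces stalk
material at a constant rate, so scattered intensity follows the running
time-integral of the cell count (the *integrated cell number*, trapezoid
rule) plus optional Gaussian noise.  The fit stage regresses intensity on
integrated cell number and reports $R^2$.  One caution documented here
because it matters for reproduction: at a signal-to-noise ratio of exactly
10 (sd of signal over sd of noise) the population $R^2$ is
$100/101 = 0.9901$, so single-series realizations straddle 0.99; the
package's own check averages over one hundred generation seeds, where the
statistic concentrates at its population value.

# The measurement pipeline

All stages are pure functions.  `calibrate()` solves the two-point
Stern-Volmer calibration; `oxygen_map()` divides by a saturated reference
frame (cancelling any dye-loading gain field) and inverts the quenching
law pointwise — the forward/inverse round trip is exact to $10^{-12}$.
`cell_density_map()` takes the absolute frame difference and smooths with
a separable Gaussian (default sd 1 px; a small kernel because on a steep
oxygen gradient smoothing smears detected density asymmetrically toward
the oxygen-rich side).  `front_report()` thresholds the density at a high
quantile (default 0.99 over all pixels), reports the **median** oxygen
over front pixels (robust to the band's ends and to stragglers), and
returns the cross-front profile of density and oxygen against signed
distance to the nearest front pixel, negative on the oxygen-poor side.
On the default chamber the front stage reads $7.1 \pm 0.7$ % atm (mean and
sd over 30 seeds) for a preference of 7 % — the residual scatter is the
finite-population noise of 300 walkers, with occasional excursions when a
secondary clump persists through the measurement window.

`fit_elongation_rate()` recovers the preset elongation rates to within
the OLS slope-estimator error (sd
$\sigma\sqrt{12/(n(n^2-1))}/\mathrm{d}t \approx 0.019$ um/s per track at
the default generation, hence ~0.006 um/s for the 10-track mean).

# Numerical choices and degenerate inputs

* Series/closed-form switch for the resistance functions at $e=10^{-2}$;
  oblate geometries are rejected, exact spheres use the analytic limit.
* `drag_tensor()` requires a unit orientation within $10^{-9}$; its
  inverse is the tensor of reciprocal scalars (tested identity).
* Explicit-diffusion stability is validated at `chamber_config()`
  construction, not at run time.
* The stalk-swing solve is singular only if a drag coefficient vanishes,
  which valid geometries exclude.
* Fixed-point classification uses central differences with step
  $10^{-5}$ rad; eigenvalues with $|\mathrm{Re}\,\lambda| <
  10^{-10}/\tau_f$ are reported as marginal.
* Basin integration caps at $200\tau_s$ and labels non-settled initial
  conditions `undetermined` rather than guessing.
* Degenerate measurement inputs fail loudly: constant-time tracks, equal
  calibration intensities, nonpositive image intensities, shape
  mismatches, uniform density maps, constant regressors.

Problem sizes throughout the test-suite are desk-scale by design: chamber
runs of 5000 simulated seconds on the 128 x 128 default grid (a few
seconds of compute), tether integrations of tens of $\tau_s$, and
twenty-point decay fits; these sizes were chosen as the smallest at which
each quantity's estimator is comfortably inside its stated tolerance.

# Known limitations

* The tethered-cell model treats the stalk as rigid and inextensible
  within a dynamics run; slow elongation is a separate (synthetic-data)
  process, consistent with treating $\ell$ as fixed in the stability
  analysis.
* The leading-image approximation is the default for the orientation
  dynamics; the Blake system is available as a sensitivity check
  (`mode = "blake"`), and the phase-portrait topology is unchanged.
* The closed-form critical length and the numerical eigenvalue crossing
  differ by a factor 1.5 (see above); both are exposed.
* The chamber walkers are a minimal mechanism — diffusion, point-ish
  sinks, concentration-seeking drift — chosen because the measurement
  stages only need a front at a controllable concentration.  No claim is
  made that its parameters are the organisms' true motility parameters.
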
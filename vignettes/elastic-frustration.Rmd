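---
title: "Elastic frustration and the fate of capsid self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic frustration and the fate of capsid self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

An empty viral capsid assembles from capsomers (pentameric and hexameric
protein oligomers) that gain a binding free energy $\Delta\mu$ per subunit
when they join a shell, pay a line energy $\Lambda$ per unit length of the
open rim, and accumulate elastic energy because a hexagonally ordered sheet
cannot wrap a sphere without stretching. Within classical nucleation theory
extended by continuum elasticity, the formation free energy of a partial
shell of area $S$ is

$$\Delta G = -\frac{S\,\Delta\mu}{a_1} + \Lambda\, l(S) + G_{stretch} + G_{bend},$$

with $a_1$ the area per subunit and $l(S)$ the rim length. Scaling energies
by $4\pi R_0^2 Y$ (with $Y$ the 2-D Young's modulus and $R_0$ the radius
preferred by the capsomer interaction angle) and lengths by $R_0$ leaves
exactly three control parameters:

* the scaled line tension $\lambda = \Lambda/(R_0 Y)$,
* the scaled chemical potential $\tilde{\Delta\mu} = \Delta\mu/(Y a_1)$,
* the Föppl–von Kármán number $\gamma = Y R_0^2/\kappa$, the ratio of
  stretching to bending stiffness.

Every structure the sheet can adopt to relieve frustration — a defectless
spherical cap, a cap with one or several 5-fold disclinations, an open
ribbon, a closed belt girdling the sphere, or a cylinder — has a closed-form
scaled free energy (`dg_cap_bending()`, `dg_shell_n_defects()`,
`dg_ribbon_bending()`, `dg_belt()`, `dg_cylinder()` and their general-
$\gamma$ variants). Comparing their size-minimised values yields a
*universal* phase diagram in $(\lambda, \tilde{\Delta\mu}, \gamma)$,
independent of microscopic interaction details.

Sizes are expressed by the equal-area convention: a patch of area
$S = \pi\rho_0^2$ has scaled size $x = \rho_0/R_0$, and a sphere of scaled
radius $r = R/R_0$ closes at $x = 2r$.

## Disclination energetics

The in-plane elastic terms follow the flat-metric approximation: the cap is
flattened to a disk of equal area (a point at polar angle $\theta$ maps to
disk radius $2R\sin(\theta/2)$), and the stress state solves the Airy
biharmonic problem with free edges, which on a simply connected domain is
equivalent to the clamped-plate problem. Three closed-form ingredients
result, all in units of $4\pi R_0^2 Y$:

* background Gaussian-curvature stretching of the defect-free cap,
  $x^6/(1536\,r^4)$;
* for a 5-fold disclination (deficit angle $s = \pi/3$) at reduced disk
  position $\beta$: a self-energy $(x^2/1152)(1-\beta^2)^2$ and a coupling
  to the background curvature $-(x^4/(768 r^2))(1-\beta^2)^2$ — together
  `gs1`.  The factor $(1-\beta^2)^2$ is the free-rim screening; a defect
  *on* the rim costs nothing;
* a pairwise repulsion `gs2` from the clamped-disk biharmonic Green's
  function, $\tfrac{x^2}{576}\left[d^2\ln(d^2/d^{*2}) - d^2 +
  d^{*2}\right]$ per pair, with $d$ the separation and
  $d^{*2} = 1 - 2u_i\!\cdot\!u_j + |u_i|^2|u_j|^2$ the image separation in
  the unit disk.

For one disclination the defect is held at the cap centre, reproducing the
familiar $(x^2/1152)(1 - \tfrac32 x^2/r^2)$, which turns favourable at
$x/r = \sqrt{2/3}$. (Some renderings of this threshold drop the radical;
the sign of the printed term fixes it unambiguously, and
`defect_onset_x()` returns $\sqrt{2/3}$.)

For $n \ge 2$ disclinations we adopt one fixed symmetric arrangement per
$n$: the layout that minimises the closed-shell defect energy, found once
by quasi-Newton relaxation in the unit disk (for $n = 12$ it converges to
the icosahedral arrangement under the chord map) and then held at fixed
fractional positions as the cap grows. Because both layout functionals are
scale-free, the defect energy reduces to
$E = x^2\,[f_1(c)\,w(t) + G_2(c)]$ with $t = x^2/r^2$ and
$w(t) = 1/1152 - t/768$ — two constants per defect count. We deliberately
do *not* re-relax the layout at every cap size: letting defects slide
freely towards the rim (where screening makes them free) over-stabilises
partial shells and destroys the observed insensitivity of the belt/shell
frontier to the line tension. With fixed layouts the rim terms of the belt
($\lambda r$) and of the closed shell ($(\lambda/2)\,x$ at $x = 2r$) cancel
identically at coexistence, making the frontier exactly
$\lambda$-independent, as expected from the theory.

## Phase-diagram engine

`classify_point()` minimises each candidate's free energy over its size
variables and reports the global minimum:

* $x \in (0, 2r]$ for every finite structure; $r \in [0.2, 5]$ where the
  radius is free. These bounds cover every physically sensible optimum for
  the parameter ranges of real capsids; the upper radius bound matters only
  deep in the cylinder-dominated region, where the cylinder has already
  won.
* The defectless cap's radius comes from the stationarity cubic
  $r^2(r-1) = \gamma x^4/192$ (unique root $\ge 1$, bracketed Brent to
  $10^{-12}$; `optimal_cap_radius()`), clamped to the closure constraint
  $r \ge x/2$.
* The landscape is non-convex (nucleation barrier, then a well), so each
  minimisation is seeded by a dense grid scan (a mixed log/linear grid of
  about 200 sizes, and 36 log-spaced radii where $r$ is free, plus the
  closure line $x = 2r$) and refined by bounded coordinate descent in $x$
  and $r$, with an extra 1-D search *along* the closure line, where closed
  shells form a diagonal valley that plain coordinate descent tracks
  poorly. The two best defect counts are refined.
* A cylinder at its optimal radius $r = 1$ has formation energy
  $(-\tilde{\Delta\mu}/4 + 1/(8\gamma))x^2 + \lambda r$: it grows without
  bound exactly when $\tilde{\Delta\mu} > 1/(2\gamma)$, where it is
  declared the winner with `unbounded = TRUE`. Below the threshold it has
  no assembled well at all.
* The disassembled state wins when every minimum is non-negative
  (thermodynamic convention). Ties are broken by a fixed structure order
  and flagged as coexistence.

`trace_boundary()` locates coexistence by bisection in
$\tilde{\Delta\mu}$, comparing the structures' *assembled wells* — interior
local minima beyond the nucleation barrier, or the closure boundary —
rather than their global infima; the trivial $x \to 0$ branch, whose energy
tends to zero, is the disassembled state and must not stand in for a phase.
The belt/multi-defect-shell frontier at $\gamma = 0$ computes to
$\tilde{\Delta\mu} \approx 0.0020$ and is $\lambda$-independent.

`critical_gamma_no_spheres()` returns the self-consistency estimate
$\gamma_c = 1/(2\,\tilde{\Delta\mu}_{bs})$: the Föppl–von Kármán number at
which the cylinder's unbounded-growth threshold descends to the
belt/shell frontier, closing the window in which a defective sphere can be
globally stable — about 250. Two caveats are documented with the function:
the frontier entering the formula is the bending-dominated one, and in the
full grid classification (where belts and shells also relax their radius at
weak bending) the last multi-defect cells disappear somewhat earlier, near
$\gamma \approx 200$. Either way, grids computed at $\gamma \ge 250$
contain no multi-defect-shell cells.

Default reproduction grids (`default_grid_axes()`) are log-spaced
$60 \times 60$ over $\lambda \in [10^{-5}, 2\times10^{-3}]$,
$\tilde{\Delta\mu} \in [10^{-4}, 10^{-2}]$, covering both the tabulated
capsid estimates and the simulation mappings; the figure axes themselves
are not published numerically, so these ranges are a package choice.

```{r phase-example}
library(capshell)
classify_point(scaled_parameters(lam = 1e-4, dmu = 1e-3, gamma = 0))
trace_boundary("belt", "shell_n_defects", gamma = 0, lam = 1e-4)
```

## Parameter mappings

`potential_to_elastic()` and `potential_to_scaled()` connect the
coarse-grained capsomer potential (exponents $m > n$, preferred angle
$\nu$, angular width $\alpha$, binding energy $\epsilon_0$, diameter
$\sigma$) to the elastic constants and the scaled parameters:

$$Y = \frac{2nm}{\sqrt3}\frac{\epsilon_0}{\sigma^2},\quad
\kappa = \frac{3\sqrt3}{8}\frac{\epsilon_0}{\alpha^2},\quad
R_0 = \frac{\sigma}{2|\cos\nu|},\quad
\Lambda = \frac{2\epsilon_0}{\sqrt3\sigma},$$

hence $\gamma = 4nm\alpha^2/(9\cos^2\nu)$ and $\lambda = 2|\cos\nu|/(nm)$.
Two conventions deserve a note:

* **Area per subunit.** The scaled chemical potential identity
  $\tilde{\Delta\mu} = (2\sqrt3/\pi nm)\,\Delta\mu/\epsilon_0$ together
  with the $Y$ formula forces $a_1 = \pi\sigma^2/4$, the projected disk of
  one capsomer. The package adopts this and unit-tests the round trip.
* **Interaction angle.** Only $|\cos\nu|$ enters the geometry: $\nu$ and
  $\pi - \nu$ describe the same shell with the orientation vector flipped.
  The mapping accepts either convention; the simulator uses acute $\nu$
  with orientations pointing towards the curvature centre.

`capsid_estimate()` produces the experimental estimates: $Y = Eh$ from AFM
nanoindentation moduli, $\sigma(R, T) = R/\sqrt{2(T + \cot(\pi/5)/\sqrt3 -
1)}$ from equal-area packing of $10T + 2$ capsomers,
$\lambda = \Lambda/(YR)$ with $\epsilon_0 = 10\,k_BT$, and
$\gamma = 12(1-\nu_p^2)(R/h)^2$ with Poisson ratio 0.3. $k_BT$ is fixed at
$4.11\times10^{-21}\,$J (about 298 K; the temperature behind the published
table is unstated, and the sensitivity of $\lambda$ is below 2%).

## The Brownian-dynamics simulator

Capsomers are spheres with an orientation unit vector $\Omega$, interacting
through $V = V_{Mie}\,V_a\,V_{tor}$: a Mie term with minimum $-\epsilon_0$
at $r = \sigma$, Gaussian angular factors of preferred angle $\nu$ and
width $\alpha$ on both orientations, and a torsion factor
$\exp(-k_t(1-\cos\xi)^2)$ with $\xi$ the angle between the planes spanned
by the centre line and each orientation. The modulation is applied to the
attractive branch only (WCA split at the minimum): a literal product would
switch off core repulsion at unfavourable angles, while the split keeps
excluded volume orientation-independent and the potential $C^1$ at
$r = \sigma$. A `strict_product` mode applies the product literally for
comparison.

Dynamics are overdamped Euler steps in reduced units ($\sigma = D =
\epsilon_0 = 1$): translations move by $F\,dt/T_{red}$ plus Gaussian noise
of variance $2\,dt$, orientations rotate by the tangent-projected torque
times $D_r dt/T_{red}$ plus rotational noise of variance $2 D_r dt$ and are
renormalised every step. Forces and torques are analytic gradients,
verified against central differences to $10^{-6}$. Defaults follow the
reference protocol: $k_t = 1.5$, $T_{red} = 0.1$ (a 10 $k_BT$ binding
energy), time step $5\times10^{-5}$, cutoff $2.5\sigma$ with energy shift,
and a 19-capsomer spherical-cap seed (`build_seed_cap()`) because the
critical nucleus is always a small cap. The rotational diffusion constant
is not stated by the source model; the stick-sphere ratio $D_r = 3D/\sigma^2$
is the package default.

Deliberately scaled-down sizes are used throughout the test suite: the
production protocol of the underlying model ($N = 200$–$400$ capsomers,
$2\times10^9$ steps) is documented but not exercised; qualitative checks
(seed growth at high capsomer concentration versus seed dissolution at very
low concentration) run with $N \le 80$ and $\le 2\times10^5$ steps over
three seeds. At $T_{red} = 0.1$ a bound capsomer sits in a well tens of
$k_BT$ deep and detachment is unobservable on such runs, so the
dissolution leg is run at $T_{red} = 0.3$, where unbinding is accessible
while the scaled parameters $\lambda$ and $\gamma$ (which do not depend on
$\epsilon_0$) are unchanged. What these desk-scale runs demonstrate is the
direction of the thermodynamic drive on either side of the assembly
boundary, not the full shape selection of long trajectories.

## Cluster and shape analysis

`find_clusters()` performs single-linkage clustering at cutoff $1.4\sigma$
(the midpoint between the first and second hexagonal neighbour shells).
`count_disclinations()` counts interior members with five neighbours;
interior means the neighbours close a full angular fan (gap below 120°)
around the local normal. For a closed triangulated shell the Euler sum
$\sum(6 - \text{coordination}) = 12$ exactly, which the tests verify on
icosadeltahedral fixtures.

`classify_shape()` separates closed shells, caps, ribbons, tubes and cones
using the gyration tensor, a least-squares sphere fit, rim detection, and
the cross-section profile along candidate symmetry axes; curved strips are
told apart from caps by their thinness in an azimuthal-equidistant chart
around the cluster's mean direction. The published work classifies
simulation outcomes visually, so no quantitative thresholds exist to
reproduce; all thresholds here were calibrated on the deterministic
`make_shape_fixture()` point sets and frozen. They are reliable for
clean fixtures and late-stage assemblies but are not guaranteed for small
or highly defective intermediates, which report `amorphous`.

## Known limitations

* The flat-metric, small-curvature approximations of the free energies are
  inherited from the theory; the rim length of a nearly closed shell is in
  particular a flat-disk estimate.
* `gs1`/`gs2` rest on the package's reconstruction of the disclination
  energetics (equal-area flattening, clamped-disk Green's function, fixed
  symmetric layouts). It reproduces the known single-defect results
  exactly and the published frontier and critical Föppl–von Kármán number
  to about 1%, but it is not a transcription of any published multi-defect
  formula.
* Assembly kinetics (nucleation rates, kinetic trapping at high
  concentration) and co-assembly with cargo are out of scope; the
  simulator runs fixed $N$, so the chemical potential drifts as assembly
  depletes free capsomers.
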
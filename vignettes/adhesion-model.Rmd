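---
title: "Catch-bond cell adhesion: model, metrics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catch-bond cell adhesion: model, metrics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adhesim` has two halves that meet at the integrin--fibronectin bond. The
first half is a whole-cell finite-element (FE) model of a contracting cell
disk adhering to a rigid substrate through a mean-field population of
catch--slip bonds; it asks how a change in single-bond kinetics -- such as
the affinity loss caused by mutating the fibronectin synergy site
(R1374/9A) -- reshapes the collective force balance across thousands of
bonds. The second half is the set of trajectory metrics used to
characterise the single-bond mechanics in the first place: fluctuation
(equipartition) stiffness, force--extension departure energy,
hydrogen-bond detection, radius of gyration, inertia-axis angles, and
pairwise-Coulomb punctual stress. Because the raw inputs to such metrics
are multi-hundred-nanosecond molecular-dynamics trajectories of a
~1.5 M-atom system, the package ships seeded synthetic generators that
produce every input with known ground truth; all quantitative claims in
the test suite are made against that ground truth or against closed-form
oracles, never against an MD run.

## The bond model

A bond loaded by force $f \ge 0$ dissociates at

$$K_\mathrm{off}(f) = K_a e^{f/F_a} + K_b e^{-f/F_b},$$

the standard two-pathway catch--slip form: the slip pathway accelerates
with force, the catch pathway is suppressed by it. When $K_b F_a > K_a
F_b$ the lifetime $1/K_\mathrm{off}$ is unimodal with an interior maximum
at

$$f^\ast = \frac{F_a F_b}{F_a + F_b}\,\ln\!\frac{K_b F_a}{K_a F_b},$$

which the test suite uses as a closed-form oracle against brute-force
scans. Each bond is a linear spring, $\mathbf{f}_\mathrm{int} =
k_\mathrm{int}\,\mathbf{u}_\mathrm{int}$ with $k_\mathrm{int} =
0.5$ pN/nm, anchored where its node first touched the substrate. The
bond population at a node is a dimensionless concentration $C \in [0,1]$
relative to the saturation density $\rho_\mathrm{max} = 100\,\mu m^{-2}$,
advanced by explicit Euler,

$$C^{t+\Delta t} = C\,(1 - K_\mathrm{off}\Delta t) +
  K_\mathrm{on}\Delta t\,(1 - C),$$

whose fixed point at constant force is $K_\mathrm{on}/(K_\mathrm{on} +
K_\mathrm{off})$. The update is clamped to $[0,1]$: the explicit scheme
can overshoot when $K_\mathrm{off}\Delta t > 1$, and a concentration is
meaningless outside the unit interval (a warning reports the stability
violation). The nodal traction transmitted to the substrate is
$\mathbf{f}_\mathrm{node} = C\,\rho_\mathrm{max}\,A\,
\mathbf{f}_\mathrm{int}$ with $A$ the node's tributary area.

### Kinetic presets

The `wildtype` and `mutant_R1374_9A` presets live in
`inst/extdata/bond_presets.yaml`. The fitted kinetic constants for
$\alpha_5\beta_1$--fibronectin used in the original study are published
only in its supplementary table, which is not redistributed here, so the
shipped presets are the package's own calibration, chosen once from the
observables that are public:

* **wildtype** ($K_\mathrm{on} = 0.5$, $K_a = 0.02$, $F_a = 10$ pN,
  $K_b = 2$, $F_b = 5$ pN): a catch bond with zero-force occupancy
  $\approx 0.2$, zero-force lifetime $\approx 0.5$ s, and a lifetime
  maximum of $\approx 5.7$ s at $f^\ast \approx 17.7$ pN -- within the
  range reported for this receptor in single-molecule catch-bond assays.
* **mutant_R1374_9A**: association is left untouched -- initial capture
  is RGD-mediated and the synergy site acts after engagement -- while both
  dissociation prefactors are scaled up by 13.47 so that the zero-force
  equilibrium concentration is exactly 11-fold below wild-type, the
  affinity loss measured for synergy-site-mutant fibronectin by surface
  plasmon resonance.

A pure-slip mutant ($K_b = 0$) was considered and rejected: a load-balance
estimate shows that with an 11-fold affinity loss and no catch pathway the
maximum sustainable traction $\max_f C(f)\,f\,\rho_\mathrm{max}A$ falls
far below the 200 Pa contractile line load, so the mutant cell would
detach wholesale -- contradicting the observed behaviour of mutant bonds
holding at elevated per-bond force. The rescaled-catch mutant reproduces
exactly that: fewer bonds, each reinforced under the load it inherits.

Because the true fitted constants are unavailable, simulation outputs that
depend on them quantitatively (the concentration ratio under contraction,
the transient force peaks) reproduce the reported study only in regime and
ordering, not digit-for-digit; the package reports its own computed values
and makes no attempt to tune toward the published ones.

## The cell model

The cell is a 2D disk (default radius 10 µm, thickness 1 µm) of
incompressible neo-Hookean material under plane stress,

$$\sigma^\mathrm{pas} = \mu_c\,\mathbf{b} - p_c \mathbf{I}, \qquad
  p_c = \frac{\mu_c}{(\det \mathbf{F})^2},$$

with shear modulus $\mu_c = 1$ kPa and $\mathbf{b} =
\mathbf{F}\mathbf{F}^\top$ the left Cauchy--Green tensor of the in-plane
deformation gradient; $p_c$ follows from $\sigma_{33} = 0$ and
incompressibility. Contractility is an isotropic active stress
$\sigma^\mathrm{act} = t_\mathrm{myo}\mathbf{I}$ ramped at 100 Pa/s for
2 s and held at 200 Pa (held beyond 30 s if a run is longer). For a free
disk the uniform equilibrium stretch solves
$\mu_c(\lambda^2 - \lambda^{-4}) + t_\mathrm{myo} = 0$; the FE solution
matches that root to machine precision because a homogeneous deformation
is exactly representable on linear triangles -- the benchmark therefore
validates the constitutive law, the assembly and the integrator, not the
mesh resolution.

Internal forces come from single-point quadrature of the total Cauchy
stress on linear triangles; the residual sums to zero over the mesh
(partition of unity), so momentum is conserved exactly in the absence of
external forces. Boundary nodes additionally carry three regularization
forces whose functional forms follow the conventions of boundary-resolved
cell models: curvature smoothing $-k_\kappa \kappa_i \mathbf{n}_i$ (with
$\kappa_i$ the turning angle over the mean adjacent segment length), an
outward actin protrusion noise $a_\mathrm{ac}\,\xi_i\,\mathbf{n}_i$ with
$\xi_i \sim U(0,1)$ per node per step, and a global area penalty
$k_A (A_0 - A)\,w_i \mathbf{n}_i$ distributed by segment length. Body
forces are the adhesion tractions and a linear viscous drag
$-\gamma \mathbf{v}$.

No published values exist for the regularization coefficients. The
defaults ($\gamma = 10$ pN s/µm, $k_\kappa = 10$ pN µm,
$a_\mathrm{ac} = 0.5$ pN, $k_A = 0$) were fixed once so that each term is
small against the contractile load (the total boundary line force at the
plateau is $\sim 1.3 \times 10^4$ pN, against which the noise and
curvature terms contribute of order 1 pN per node): they regularise
without steering the force balance. All are configurable, and the
validation benchmarks switch them off.

## Numerical choices

* **Time integration** is the explicit midpoint rule: half-step velocity
  and position predictors, force re-evaluation at the midpoint, full
  update. The step's accuracy is second order; the harmonic-oscillator
  test holds the trajectory to < 1% RMS of the analytic cosine over ten
  periods at 200 steps/period.
* **Mass scaling.** At the physical density ($\rho_c = 1000$ kg/m³) the
  explicit stability limit of a micrometre-scale mesh is around 2 µs,
  far below the 50 µs step the protocol uses. Because the 30 s contraction
  is quasi-static -- loading times of seconds against elastic relaxation
  times of milliseconds -- the package applies selective mass scaling
  (`density_scale`, default $10^4$), the standard device for quasi-static
  explicit analysis. Scaled inertial forces remain roughly six orders of
  magnitude below the adhesion forces, and the convergence test (halving
  $\Delta t$ changes the concentration trace by < 0.5%) runs at the scaled
  mass.
* **Drag is folded in semi-implicitly**, dividing the velocity update by
  $1 + \Delta t\,\gamma/m$. This is unconditionally stable for the drag
  term, exact in the overdamped limit ($\mathbf{v} \to \mathbf{F}/\gamma$),
  and reduces to the pure midpoint rule when $\gamma = 0$.
* **Mesh.** A fixed-topology polar triangulation (ring $k$ carries $6k$
  nodes; $6 n_r^2$ triangles) keeps radial and tangential spacing nearly
  equal, giving radius-independent quality (all elements above 0.2
  inradius/circumradius, median 0.47). There is no dynamic remeshing;
  instead every force evaluation checks for element inversion and aborts
  with the element id, which at 200 Pa (boundary displacements of tens of
  nanometres against anchored bonds) is never approached. An energy
  blow-up detector (max nodal speed) aborts unstable runs with advice to
  reduce $\Delta t$.
* **Kinetics--mechanics coupling.** Bond concentrations advance once per
  step from the per-bond force magnitude at the current extension;
  anchors are fixed at each node's initial position (rigid substrate,
  mean-field bonds -- the concentration field, not any individual bond,
  is the state variable, so re-anchoring on rebinding has no meaning at
  this level of description).
* **Units.** Bond mechanics are carried in pN and nm, the cell model in
  µm, s and Pa; the conversions live in one place (`R/units.R`), using
  the identity 1 Pa µm² = 1 pN and nodal masses in pN s²/µm.

## Trajectory metrics

**Fluctuation stiffness.** For a reaction-coordinate length $L(t)$ in a
harmonic well, equipartition gives $k = k_B T / \mathrm{var}(L)$
(population variance; $k_B T = 4.28$ pN nm at 310 K). `block_stiffness`
applies the estimator to contiguous blocks (default mirroring the common
five 10 ns blocks of 1000 samples) and reports mean and dispersion. On
synthetic i.i.d. Gaussian series the estimator recovers a planted
constant within 5% at $n = 5000$, with relative error shrinking as
$n^{-1/2}$; an optional AR(1) mode mimics the autocorrelation of real MD
samples, which widens block-to-block scatter without biasing the mean.

**Departure energy.** The work absorbed before the first major force
peak on a pulling curve -- the proxy for the energetic barrier holding
the synergy site against the integrin head -- is computed by locating
the peak, fitting a continuous piecewise-linear function (20 knots,
uniform in extension) to the nonmonotonic force--extension data up to
it, and integrating the fit with the trapezoid rule from zero extension.
Peak location uses topographic prominence (default 10% of the global
maximum) rather than raw height, so noise bumps riding a rising ramp are
ignored; curves without a detectable peak raise an error that points to
the manual override.

**Hydrogen bonds.** The geometric criterion: donor--acceptor distance
$\le 0.35$ nm *and* deviation of the donor--hydrogen--acceptor angle from
linearity $\le 30^\circ$. The angle convention is a documented choice:
detection tools differ on whether the cutoff applies to the included
D--H--A angle or its deviation from 180°; the deviation convention is
adopted here. The planted generator builds decoys that violate exactly
one criterion so a detector failure localises immediately.

**Inertia-axis angles.** The principal (long) axis is the eigenvector of
the inertia tensor with the smallest moment; near-degenerate spectra
(no clear gap between the two smallest moments) are rejected rather than
returning an arbitrary axis. Eigenvectors carry no sign, so by default
the folded angle $\arccos|\hat u_A \cdot \hat u_B| \in [0^\circ,
90^\circ]$ is reported; supplying reference orientations (e.g. the first
frame's axes) fixes the signs and unfolds the angle to $[0^\circ,
180^\circ]$, which is required to resolve obtuse inter-domain angles such
as the ~151° fibronectin FN9--10 hinge.

**Punctual stress.** Per residue, the sum of absolute pairwise Coulomb
force magnitudes $k_e |q_i q_j| / r^2$ against atoms of other residues
within a 1.2 nm cutoff (configurable), in the force-like MD unit
kJ mol⁻¹ nm⁻¹. This is a deliberate simplification of time-resolved
force-distribution analysis: Lennard-Jones contributions are excluded,
so absolute values are not comparable to full-FDA outputs, while
contrasts between conditions (charged vs neutralised residues) are.

**Condition comparison.** Kolmogorov--Smirnov normality per sample
(against a normal with the sample's moments) followed by the paired
Wilcoxon signed-rank test at $\alpha = 0.05$. Note the exact two-sided
signed-rank test cannot reach $p < 0.0625$ with only five pairs, so
comparisons of five-block stiffness estimates need more blocks to resolve
significance.

## What the synthetic generators do and do not show

The generators emulate the *statistical structure* the metrics consume:
harmonic fluctuations with a known stiffness, piecewise-linear
force--extension curves with known area, rod-like domains at known
angles, hydrogen-bond geometries with margin, and disk meshes of known
area. Passing tests therefore demonstrate that every estimator is
correct on data satisfying its own assumptions, with known answers. They
do not demonstrate robustness to what real trajectories add: anharmonic
wells and slow conformational drift under the stiffness estimator,
force-field-specific noise correlations, bifurcating pulling pathways,
or protein-shaped (rather than rod-shaped) inertia tensors. Those
effects are why the original analyses average over blocks, replicate
runs, and compare conditions nonparametrically -- practices the package
mirrors but cannot itself validate against MD.

## Problem sizes and runtimes

The shipped study configuration -- 10 µm disk, 384 elements (217 nodes),
$\Delta t = 50$ µs, 30 s of simulated time, three replicates per
condition -- was chosen so a full two-condition comparison completes in
about two minutes on one CPU core with the compiled stepping core, which
makes the whole pipeline (and its acceptance checks) routinely
re-runnable. Convergence checks (dt-halving, mesh-level validation
against the analytic stretch) are part of the test suite.

## Known limitations

* The kinetic presets are calibrated stand-ins (see above); quantitative
  outputs that depend on the fitted supplementary constants will differ
  from the original study's, and do.
* 2D plane stress on a rigid substrate: no substrate compliance, no 3D
  cell geometry, no focal-adhesion clustering or cytoskeletal coupling;
  bonds are mean-field, so single-bond stochasticity (and force-history
  dependence) is out of scope.
* Fixed mesh topology: very large contractions that would require
  remeshing abort on the quality monitor instead.
* Punctual stress is Coulomb-only; hydrogen-bond detection is purely
  geometric (no occupancy averaging over frames).
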
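---
title: "Models behind cpaload: membrane transport and coupled diffusion-elasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models behind cpaload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cpaload` simulates how an oocyte responds to loading and unloading of a
membrane-permeating cryoprotective agent (CPA), at two levels of
description: a lumped two-parameter membrane transport model, and a
spatially resolved phenomenological finite-element model. This vignette
records the models, their assumptions, the tunable parameters, the
numerical choices, and the design decisions taken where the design was
genuinely open.

## The two-parameter transport model

The cell is a perfect osmometer with an osmotically inactive solids
fraction. Water and CPA cross the membrane independently:

$$\frac{dV_w}{dt} = -L_p A R T (M^e - M^i), \qquad
  \frac{dV_s}{dt} = P_s A (M_s^e - M_s^i)\,\bar V_s,$$

where $V_w$, $V_s$ are the intracellular water and CPA volumes (µm³),
$A$ the membrane area, $L_p$ the hydraulic permeability
(µm min⁻¹ atm⁻¹), $P_s$ the CPA permeability (µm min⁻¹), $\bar V_s$ the
CPA partial molar volume, and $R = 8.205745\times10^{13}$
µm³ atm mol⁻¹ K⁻¹. Solutions are treated as ideal and dilute, so the
intracellular osmolalities follow from the state alone:
$M_n^i = M_{n0}^i (1-V_{bf}) V_0 / V_w$ (Boyle–van't Hoff dilution of the
initial cytosolic content) and $M_s^i = V_s / (\bar V_s V_w)$. The total
cell volume is $V_c = V_w + V_s + V_b$ with $V_b = V_{bf} V_0$ the
osmotically inactive volume, and results are reported as the normalized
volume $V_n = V_c / V_0$.

Because $L_p A R T M \gg P_s A \bar V_s M$, water initially leaves much
faster than CPA enters: loading is biphasic (shrink, then recover), and
unloading into an isotonic bath is the mirror image (swell, then
recover). The closed-form equilibrium
$V_w^{eq} = M_{n0}^i (1-V_{bf}) V_0 / M_n^e$,
$V_s^{eq} = M_s^e \bar V_s V_w^{eq}$ is exposed as
`equilibriumState()` and doubles as an oracle for the integrator.

Temperature enters through the Arrhenius law
$L_p(T) = L_{pg}\exp(-(E_{Lp}/R_{cal})(1/T - 1/T_0))$ (likewise $P_s$),
with $R_{cal} = 1.987204$ cal mol⁻¹ K⁻¹ and $T_0 = 273.15$ K.

### Parameters

The packaged defaults describe equine oocytes in ethylene glycol (EG)
media:

| quantity | symbol | default | units |
|---|---|---|---|
| membrane area | `A` | 34,763.12 | µm² |
| isotonic volume | `V0` | 609,469.49 | µm³ |
| solids fraction | `Vbf` | 0.3123 | – |
| CPA partial molar volume | `Vs_bar` | 5.5919×10¹³ | µm³ mol⁻¹ |
| hydraulic permeability (22 °C) | `Lp` | 0.6284 | µm min⁻¹ atm⁻¹ |
| CPA permeability (22 °C) | `Ps` | 20.3660 | µm min⁻¹ |
| activation energies | `E_Lp`, `E_Ps` | 11,190 / 15,810 | cal mol⁻¹ |
| 0 °C reference permeabilities | `Lpg`, `Psg` | 0.1522 / 3.7660 | µm min⁻¹ (atm⁻¹) |
| baths (EG + 0.300 mol/L saline) | `Ms_e` | 1.500, 0.700, 0.450 | mol L⁻¹ |

Two deliberate bookkeeping decisions. First, baths are always specified
by their explicit osmolality pair `(Mn_e, Ms_e)`, never by a nominal
molarity label; the three standard EG media correspond to the pairs
above. Second, the two permeability parameterizations — the fitted
`(Lp, Ps)` at the measurement temperature and the literature
`(Lpg, Psg, E)` Arrhenius set — are *not* mutually consistent
(back-computing `Lpg` from `Lp` at 22 °C gives ≈ 0.135, not 0.1522), and
we do not reconcile them: `Lp`/`Ps` are used as-is at the measurement
temperature, and the Arrhenius set is used only when temperature scaling
is explicitly requested (`arrheniusPermeability()`, `permeabilityAt()`,
or `use_arrhenius: true` in a config). "Room temperature" defaults to
295.15 K (22 °C); temperature sweeps conventionally use 278.15, 283.15
and 293.15 K.

### Numerics

* Integrator: `deSolve::lsodar` (adaptive, variable order/step) at
  `rtol = atol = 1e-9`. The suite checks it against an independent
  fixed-step classical RK4 reference at $dt = 10^{-3}$ min to within
  $10^{-5}$ in $V_n$.
* Osmotic collapse guard: a root function terminates the integration if
  $V_w < 10^{-3} V_0$ and reports an "osmotic collapse" error rather
  than silently producing unphysical states.
* Extremum timing: the volume minimum (or maximum) is sharpened by a
  quadratic fit through the three samples bracketing the discrete
  extremum (`vnMinimum()`), reported in seconds; the default output grid
  is 0.1 s.

## Permeability fitting and the synthetic-trace generator

`fitTwoParameter()` estimates $(L_p, P_s)$ by least squares on the
normalized volume only — the quantity a video-microscopy experiment
observes — using Levenberg–Marquardt with finite-difference Jacobians
over $(\log L_p, \log P_s)$, so positivity holds by construction; the
cost-decrease tolerance is $10^{-10}$.

`generateSyntheticTrace()` emulates the micromanipulator experiment: the
noiseless loading curve sampled at the video frame interval (default
1 s) plus i.i.d. Gaussian noise on $V_n$ (default sd 0.01, a plausible
segmentation error for a ~100 µm cell; the measurement error model is
otherwise unconstrained). It is deterministic given a seed and restores
the caller's RNG state. What the generator does *not* emulate: flow
artefacts during solution addition, non-spherical deformation, focus
drift, or autocorrelated segmentation errors — parameter-recovery
results on synthetic traces therefore bound what real data can deliver
from below in difficulty, and recovery within a few percent at 1% noise
should be read as a best case.

## The coupled diffusion–elasticity FEM

The spatial model is deliberately phenomenological: water transport is
not modelled explicitly (that would require a poro-elastic framework);
instead the local volume change is tied directly to the local CPA
concentration. On a sphere of radius $(3V_0/4\pi)^{1/3} \approx 52.6$ µm
held by a micro-capillary:

* **Diffusion.** $\dot C = \nabla\cdot(D \nabla C)$ with isotropic
  effective diffusivity $D$; Dirichlet $C = C_{ref}$ on the exposed
  surface (0 for unloading; a reduced factor on a cap for non-symmetric
  runs), natural zero flux under the capillary.
* **Elasticity.** Quasi-static isotropic linear elasticity
  ($E = 14.52$ kPa, $\nu = 0.49$; inertia neglected — the process is
  slow), $u = 0$ on the capillary patch (default half-angle 20°, the
  capillary diameter being otherwise unconstrained), driven by the
  isotropic eigenstrain (analogous to thermal expansion)
  $$\varepsilon^{di} = \beta(C)\,(C - C_{ref}^{strain}), \qquad
    \beta(C) = \beta_0 e^{-\bar C / c_0}, \quad
    \bar C = \frac{C}{C_{ref} - C},$$
  with $\beta_0 = -0.20$ and $c_0 = 0.8$. $\beta$ is continuously
  extended by 0 at $C \ge C_{ref}$ (the limit as $\bar C \to \infty$),
  which also defuses the singularity of $\bar C$ at Dirichlet nodes.

**Eigenstrain reference.** Taken literally, a bath-referenced strain
$\beta(C)(C - C_{ref})$ imposes a large uniform eigenstrain at $t = 0$
and a monotone volume response. We reference the strain to the *initial
intracellular* concentration instead (0 for loading, $C_{ref}$ for
unloading): the body then starts undeformed and loading reproduces the
biphasic shrink-recover response, since $\beta(C)\,C$ vanishes at both
$C = 0$ and $C = C_{ref}$ with a single interior minimum near
$C \approx C_{ref}/3$ (volumetric strain ≈ −0.16, i.e. ≈ 15% shrinkage
at the default coefficients). The literal bath-referenced form remains
available via `strain_reference = "bath"`.

**Coupling.** One-way staggered: diffusion step → eigenstrain →
elasticity solve. Two-way terms (stress-driven solute migration, the
nonlinear conductivity corrections) are omitted — no coefficients are
available to parameterize them — so concentration is never influenced by
stress.

**Effective diffusivity.** The literature diffusivity for this system is
printed with ambiguous units. We therefore treat $D$ as the one genuinely
free parameter of the spatial model and calibrate it once against the
two-parameter transport model, exactly as the eigenstrain coefficients
$\beta_0, c_0$ were calibrated against scaled experimental volume
curves: $D = 2.83\times10^{-6}$ mm² s⁻¹ places the FEM volume minimum at
≈ 30 s for 1.5 mol/L EG (matching the transport model), keeps
centre-to-membrane gradients alive over the full 4 min window, and makes
the FEM volume-averaged concentration rise more slowly than the
membrane-limited intracellular osmolality — as expected when
intracellular diffusion (through cytoplasm and organelle barriers) adds
resistance in series. Physically this is an effective, strongly hindered
cytoplasmic diffusivity (2.83×10⁻¹² m² s⁻¹). Any other value, including
literal readings of the literature number under either time base, can be
set via `materialModel(D =, D_time_base =)`.

### Discretization and numerics

* Mesh: layered icosphere (subdivided icosahedron scaled to concentric
  shells plus a centre node); prisms between shells are split into three
  tetrahedra with a smallest-global-index diagonal rule so neighbouring
  prisms agree on shared faces. Default: subdivision 3, 8 layers — 5,137
  nodes, 28,160 linear tets, polyhedral volume within 0.9% of the
  sphere. This is also the problem size used by the acceptance script;
  the test suite mostly uses a coarser 811-node mesh.
* Time stepping: backward Euler for diffusion (unconditionally stable),
  default $dt = 0.5$ s over 240 s. Both system matrices are constant, so
  they are Cholesky-factorized once and reused every step.
* Maximum-principle guard: consistent-mass FEM transport can overshoot
  marginally at a sharp front; each diffusion step is clamped to the
  physical range $[0, C_{ref}]$. The clamp is inactive in smooth
  (all-Neumann) settings, where discrete mass is conserved to solver
  precision.
* Elements: 4-node constant-strain tetrahedra with one-point quadrature
  (exact for these elements); the eigenstrain is evaluated at element
  centroids. At $\nu = 0.49$ such elements are volumetrically stiff and
  their *pointwise* pressure field is noisy; volume-integrated outputs
  (deformed volume, averaged pressure, averaged concentration) are the
  quantities to trust.
* Hydrostatic pressure: reported as the volume-weighted element average
  of $-\mathrm{tr}(\sigma)/3$ (positive = compression). For an almost
  traction-free body the signed volume average nearly cancels (the mean
  stress of a self-equilibrated eigenstrain is zero); what survives is
  the capillary-patch reaction. In this model its magnitude therefore
  peaks *after* the volume minimum (≈ 41 s vs ≈ 31 s at the defaults),
  not before it — magnitude-style averages of $|p|$ peak within the
  first few seconds instead. Both facts are structural (the ratio of
  the two times is invariant under rescaling $D$), which is worth
  knowing before comparing against pressure summaries whose precise
  definition is unknown.
* Probes: named locations at radii 1.0 / 0.9 / 0.1 of the sphere radius
  on the ray opposite the capillary; barycentric interpolation in the
  containing tetrahedron (the on-membrane probe is nudged 10⁻⁹ inside
  the polyhedral surface).

## Known limitations

* The eigenstrain law caps the FEM shrinkage: $|3\beta(C)C| \le 0.16$,
  so the FEM volume minimum (≈ 0.93) is much shallower than the
  two-parameter minimum (≈ 0.73) at 1.5 mol/L EG. The two models agree
  on timing and shape of the response, not on its depth, at the default
  coefficients.
* FEM unloading swells monotonically towards $3|\beta_0|C_{ref}$ rather
  than returning to the isotonic volume: $\beta(C\to 0)\to\beta_0$ does
  not vanish, so the loading-calibrated law has no memory of the loaded
  reference state. The transport model, not the FEM, is the tool for
  quantitative unloading protocols.
* One-way coupling: stress never feeds back into transport.
* The capillary is a kinematic constraint only; suction and contact
  mechanics of the holding pipette are out of scope, as are thermal
  fields and ice formation.

## Problem sizes and runtimes

The defaults were chosen so a full loading study is interactive: the
transport simulations and fits run in well under a second each; a
240 s FEM run takes ≈ 60 s on the default 5,137-node mesh (one core)
and ≈ 6 s on the 811-node test mesh. The test suite and the acceptance
script together complete in a few minutes.
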
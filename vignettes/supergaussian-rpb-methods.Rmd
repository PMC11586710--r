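---
title: "Regularized super-Gaussian Poisson-Boltzmann electrostatics: model and methods"
author: "suGaussRPB package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized super-Gaussian Poisson-Boltzmann electrostatics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suGaussRPB)
```

## The problem

The polar solvation free energy $\Delta G^{\mathrm{solv;polar}}$ is the
electrostatic work of moving a solute from vacuum ($\epsilon = 1$) into
water ($\epsilon = 80$). In implicit-solvent Poisson-Boltzmann (PB)
modelling this is obtained from two solutions of the PB equation — one
per phase — differenced at the atomic charge sites. Two modelling
decisions dominate the result: how the dielectric varies in space, and
how the singular point charges are handled numerically.

Classical two-dielectric solvers draw a sharp molecular surface and
assign one dielectric inside and one outside. This package instead
implements a *smooth*, atom-packing-dependent dielectric built from
super-Gaussian atom densities, combined with a *regularized* form of
the linearized PB equation in which the singular Coulomb part of the
potential is removed analytically before anything touches a grid. The
payoff of the regularization is grid-scale robustness: with no
singular source on the lattice, the computed energy converges smoothly
and monotonically as the grid is refined.

## The dielectric model

Each atom $j$ (center $\mathbf{r}_j$, radius $R_j$) carries a
super-Gaussian density

$$ g_j(\mathbf{r}) = \exp\!\left[-\left(\frac{|\mathbf{r}-\mathbf{r}_j|^2}
   {\sigma^2 R_j^2}\right)^{m}\right], $$

which is 1 at the center, $e^{-1}$ at distance $\sigma R_j$, and decays
super-exponentially. $m = 1$ is a plain Gaussian; larger $m$ flattens
the top and sharpens the fall-off, approaching a hard sphere as
$m \to \infty$. The total solute density is the probabilistic union

$$ g(\mathbf{r}) = 1 - \prod_j \left(1 - g_j(\mathbf{r})\right), $$

so overlapping atoms saturate rather than add. Two functions of $g$
define the dielectric:

* the packing-dependent solute component
  $\epsilon_g = \epsilon_{\mathrm{ref}} +
  (\epsilon_{\mathrm{gap}} - \epsilon_{\mathrm{ref}}) \prod_j (1-g_j)$,
  which is $\epsilon_{\mathrm{ref}}$ in densely packed regions and
  rises toward $\epsilon_{\mathrm{gap}}$ in loosely packed ones;
* a surface function
  $S(g) = \left[1 + (1/g - 1)^{\eta}\right]^{-1}$, a sigmoid equal to
  $1$ inside the solute, $0.5$ at $g = 0.5$ for every $\eta$, and $0$
  in bulk solvent.

The smooth spatial dielectric is the convex blend
$\epsilon = S\,\epsilon_g + (1-S)\,\epsilon_{\mathrm{out}}$ with the
phase dielectric $\epsilon_{\mathrm{out}}$ (80 in water, 1 in vacuum).
In the vacuum phase, regions where $\epsilon_g > 1$ produce an interior
dielectric "hump" above 1 — a real feature of the model, visible in
`dielectricValue()` scans.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `sigma` | 1.0 | density width in units of the atom radius |
| `m` | 2 | super-Gaussian exponent |
| `epsRef` | 1 | dielectric at atom centers |
| `epsGap` | 22 | limiting solute dielectric, loose packing |
| `epsOut` | 80 | solvent dielectric |
| `eta` | 4/m | surface steepness |
| `saltMolar` | 0 | ionic strength, mol/L |
| `scale` | 2.5 | grid nodes per Å (h = 0.4 Å) |
| `paddingA` | 15 | minimum atom-to-boundary distance, Å |

These defaults are the optimal set for reproducing ensemble-averaged
protein polar solvation from a single structure; they are asserted in
the test suite so accidental drift is caught. `pbParams()` exposes all
of them.

## Regularization

The potential is decomposed as $\phi = G + \phi_{\mathrm{RF}}$, where
$G(\mathbf{r}) = C\sum_j q_j / (\epsilon_{\mathrm{ref}}
|\mathbf{r}-\mathbf{r}_j|)$ is the analytic Coulomb (Green's function)
potential of the charges in the uniform reference dielectric, and
$\phi_{\mathrm{RF}}$ is the reaction field. Substituting into the
linearized PB equation moves the singular source off the grid entirely:

$$ -\nabla\cdot(\epsilon\nabla\phi_{\mathrm{RF}})
   + (1-S)\,\kappa^2\,\phi_{\mathrm{RF}}
   = \nabla\epsilon\cdot\nabla G - (1-S)\,\kappa^2 G, $$

with $\phi_{\mathrm{RF}} = \phi_b - G$ on the boundary. Both right-hand
terms are *finite everywhere*: near an atom center
$\nabla\epsilon \to 0$ and $1-S \to 0$ faster than $\nabla G$ and $G$
diverge (for $m \ge 2$), and far away $\nabla\epsilon \to 0$ while $G$
decays. Grid nodes that coincide with an atom center to within
$10^{-9}$ Å are assigned the analytic limit, zero. The vacuum phase
drops the salt terms.

One printed-form subtlety: the equations defining $G$ use the
reference dielectric $\epsilon_{\mathrm{ref}}$, and the package keeps
that convention consistently in $G$, $\nabla G$ and the boundary
subtraction (for the default $\epsilon_{\mathrm{ref}} = 1$ this choice
is invisible). The direction vector in $\nabla G$ and the sign
bookkeeping of the gradient chain
($\nabla g_j \to \nabla g \to \nabla S, \nabla\epsilon_g \to
\nabla\epsilon$) are fixed by requiring agreement with
central-finite-difference oracles, which the test suite enforces at
$10^{-6}$ relative tolerance; signs are not taken on faith from any
printed formula.

The energy is

$$ E = \tfrac{1}{2} k_B T \sum_j q_j\left[
   \phi_{\mathrm{RF}}(\mathbf{r}_j; \mathrm{water}) -
   \phi_{\mathrm{RF}}(\mathbf{r}_j; \mathrm{vacuum})\right], $$

with the potentials interpolated trilinearly at the charge sites. The
Coulomb parts cancel exactly in the difference, by construction. Both
phases are always solved on one grid geometry (asserted), since
per-atom differencing on mismatched lattices would reintroduce
interpolation bias.

## Numerical scheme

**Grid.** A node-centered uniform lattice with spacing $h =
1/\mathrm{scale}$ surrounds the solute's bounding box expanded by
`paddingA` on every side and snapped outward to whole cells. Padding
is measured from atom centers. The guarantee matters because the
Dirichlet boundary values come from far-field approximations: the
screened Coulomb sum over charges ("coulombic"), or the cheaper
two-center dipole form ("dipolar", available only when both charge
signs are present). At zero salt the screening factor is 1.

**Discretization.** The flux-form 7-point stencil uses the dielectric
evaluated *analytically at the stencil midpoints* — the model is
closed-form, so no averaging of node values is needed. The assembled
operator is symmetric for any dielectric field (verified by explicit
assembly in the tests). Salt enters as the per-node screening
$(1-S)\kappa^2$ with
$\kappa^2 = 2 N_A e^2 I / (1000\,k_B T)$ per Å², carried separately
from $\epsilon_{\mathrm{out}}$ so that the far-field screening length
is $\sqrt{\epsilon_{\mathrm{out}}/\kappa^2}$ (about 8 Å at 145 mM,
300 K).

**Solver.** Lexicographic successive over-relaxation (SOR) with
$\omega = 1.9$, implemented in compiled code. Convergence is measured
by the diagonally scaled residual — the Gauss-Seidel displacement, in
kT/e — with default tolerance $10^{-6}$; a residual growing over 50
consecutive sweeps stops the solve with `converged = FALSE` rather
than an error. Sweeps are deterministic, so repeated solves are
bitwise identical. A sparse direct LU factorization (`directSolve()`,
guarded to $\le 25000$ nodes) provides an SOR-independent reference;
the suite requires agreement to $10^{-8}$ in max-norm.

**Direct (Gaussian PB) route.** For cross-validation the package also
solves the unregularized equation, with each charge spread onto its 8
enclosing nodes by trilinear (cloud-in-cell) weights. This route
carries a large grid self-energy that cancels only approximately
between phases, which is exactly the scale sensitivity the
regularization removes.

**Numerical guards.** The density is clamped at $g_{\mathrm{floor}} =
10^{-14}$ before the surface sigmoid (singular at $g = 0$); $S$ is
exactly 0/1 on the clamped plateaus and the surface gradient is zero
there. Per-atom densities are truncated beyond the radius where the
exponent argument reaches 36 ($g_j < 10^{-15}$); the cutoff can be
disabled (`cutoff = FALSE`), and all oracle comparisons in the tests
disable it. In the gradient accumulator the factor
$\prod_{k\ne j}(1-g_k)$ is obtained as $P/(1-g_j)$; where $1-g_j <
10^{-12}$ (within ~$10^{-3}\sigma R_j$ of a center) the whole term is
set to zero, its analytic limit.

## Validation anchors

* **Born ion.** The single closed-form anchor. In the sharp-dielectric
  configuration ($\epsilon_{\mathrm{gap}} = \epsilon_{\mathrm{ref}} =
  1$), the model's 50%-density radius is $R_{\mathrm{eff}} = \sigma R
  (\ln 2)^{1/2m}$ and the analytic reference is $\Delta G =
  -(C/2)\,q^2(1/\epsilon_{\mathrm{in}} -
  1/\epsilon_{\mathrm{out}})/R_{\mathrm{eff}}$. The m-sweep ($m = 2,
  4, 8$) holds $\eta$ fixed at 2 — its optimum value at the default
  $m = 2$ — because the point of the sweep is that sharpening the
  *density* sharpens the dielectric step; with the $\eta = 4/m$
  coupling the surface function would simultaneously soften, and the
  sweep would not isolate the limit. At $m = 8$, scale 4, the solver
  lands within 10% of the analytic value, and the discrepancy
  decreases monotonically in $m$ (62% → 25% → 7% at the problem sizes
  used here). The 3-D solver was additionally checked against an
  exact 1-D radial quadrature of the same smooth profile, agreeing to
  under 1% at scale 4.
* **Linear response.** Doubling a Born charge must scale the energy by
  exactly 4 under the linearized equation; the suite requires 4.000
  within 0.5%.
* **Cross-method agreement.** At scale 4 the regularized and direct
  routes agree within 2% for the Born ion. For the two-atom fixture
  (radii 1.5/1.7 Å at (-1.5, 0, 0)/(1.7, 0, 0), charges ±0.5 e) the
  two routes converge to each other under refinement (5.2% at scale
  4, 2.2% at 6, 1.2% at 8) but sit outside the 2% band at scale 4
  itself: with ±0.5 e charges the phase energies nearly cancel, so
  |ΔG| ≈ 21 kcal/mol is small and the ordinary O(h²) truncation error
  of the regularized route is amplified in relative terms. The
  corresponding assertion is kept at 2% and is expected to fail for
  that fixture; the test documents real behavior rather than a
  loosened band.
* **Scale convergence.** The normalized energy
  $100\,\Delta G(s)/\Delta G(4)$ over $s \in \{1.5, \dots, 4\}$
  approaches 100 with monotonically shrinking deviation for the
  regularized route (e.g. 116.5 → 92.7 → 98.7 → 99.0 → 99.6 → 100 for
  the default-parameter Born ion).

## The synthetic fixtures

`makeBornIon()` and `makeTwoAtomSystem()` are the two canonical
geometries. `makeSyntheticPeptide()` generates a deterministic
peptide-like chain — backbone-spaced beads with jitter, radii in
[1.2, 1.9] Å, alternating partial charges with a chosen net charge —
sized to exercise multi-atom overlap, charge-summary and boundary
paths. These fixtures emulate the *geometry and charge scale* of real
solutes but not their chemistry: no force field, protonation or
conformational realism is involved. Passing tests therefore
demonstrates correctness of the model and solver, not accuracy of any
particular protein energy; reproducing ensemble-averaged protein
solvation additionally requires real structures with force-field
charges and radii supplied as PQR.

## Problem sizes and tunables in the shipped tests

Unit tests run on coarse lattices (scale 1–2, padding 5–8 Å); the
validation anchors use scale 4 with 8–10 Å padding for the Born-type
checks, and the convergence scan uses the full 15 Å padding protocol
at scales 1.5–4.0 (grids up to 137³). These sizes were chosen once,
as the smallest boxes for which the boundary approximation error is
negligible next to each test's tolerance — for a Born ion the
screened-Coulomb boundary value is exact outside the interface, so
padding mainly buffers the two-atom and peptide fixtures.

## Known limitations

* Only the linearized PB operator is solved; the full sinh
  nonlinearity is out of scope (weak-potential assumption).
* No nonpolar (SASA) term: `dGPolar()` is the polar component alone.
* Single uniform grid: no focusing, multigrid or adaptive meshing.
* The direct route's charge assignment is plain cloud-in-cell;
  fancier spreading would reduce, not remove, its self-energy.
* The m = 1 (plain Gaussian) parameterization works but is untuned;
  defaults target the super-Gaussian model.
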
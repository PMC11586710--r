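# suGaussRPB

Polar solvation free energies of biomolecules from a regularized
Poisson-Boltzmann (PB) equation with a smooth, atom-packing-dependent
super-Gaussian dielectric. For structural-bioinformatics and
molecular-modelling users who need the electrostatic (polar) component
of solvation from a PQR structure without drawing a molecular surface.

## The model

Each atom carries a super-Gaussian density
`g_j(r) = exp(-[|r-r_j|^2/(sigma^2 R_j^2)]^m)`; the solute density is
the union `g = 1 - prod(1 - g_j)`. A sigmoid surface function
`S = 1/(1 + (1/g - 1)^eta)` blends the packing-dependent solute
dielectric `eps_g = eps_ref + (eps_gap - eps_ref) prod(1 - g_j)` into
the phase dielectric: `eps = S eps_g + (1-S) eps_out`. The potential is
split as `phi = G + phi_RF`, where `G` is the analytic Coulomb
potential of the charges in the reference dielectric; the reaction
field solves

```
-div(eps grad phi_RF) + (1-S) kappa^2 phi_RF = grad(eps).grad(G) - (1-S) kappa^2 G
```

with `phi_RF = phi_b - G` on the boundary — a right-hand side that is
finite everywhere, so no singular charge ever touches the grid. The
polar solvation free energy is
`dG = (kT/2) sum_j q_j [phi_RF(r_j; water) - phi_RF(r_j; vacuum)]`,
both phases solved on one grid by a compiled SOR iteration. A direct
(unregularized) Gaussian-PB route with cloud-in-cell charge assignment
is included for cross-validation.

## Worked example

```r
library(suGaussRPB)

ion <- makeBornIon(q = 1, R = 2)     # a Born ion: the closed-form anchor
res <- polarSolvation(ion, defaultParams())
show(res)
#> SolvationResult [rpb]
#>   E(water)  =    -198.0066 kcal/mol
#>   E(vacuum) =    -116.3818 kcal/mol
#>   dG_polar  =     -81.6247 kcal/mol
#>   water: 355 sweeps, residual 9.99e-07, converged
#>   vacuum: 302 sweeps, residual 9.79e-07, converged
```

`dG_polar` is the polar solvation free energy in kcal/mol: the
electrostatic work of moving the ion from vacuum into water (negative:
water stabilizes the charge). The two phase energies are the
reaction-field terms entering the difference; with the default
`eps_gap = 22` the vacuum phase has its own (large, nonzero) reaction
field because the solute interior is polarizable, and only the
water-vacuum difference is physical.

Grid-scale robustness — the point of the regularization — via the
convergence scan:

```r
scan <- convergenceScan(ion, defaultParams(), "rpb")
show(scan)
#> ConvergenceScan (normalized to scale 4.0)
#>   scale  1.5: dG =     -96.3065 kcal/mol  ( 116.52%)
#>   scale  2.0: dG =     -76.6127 kcal/mol  (  92.69%)
#>   scale  2.5: dG =     -81.6247 kcal/mol  (  98.75%)
#>   scale  3.0: dG =     -81.8621 kcal/mol  (  99.04%)
#>   scale  3.5: dG =     -82.2989 kcal/mol  (  99.57%)
#>   scale  4.0: dG =     -82.6550 kcal/mol  ( 100.00%)
```

The deviation from the fine-grid value shrinks monotonically with
scale; at the default 2.5 grids/A the energy is within ~1.3% of the
scale-4 reference.

Real structures enter as PQR (positions, per-atom charge and radius):

```r
solute <- readPQR("protein.pqr")
res <- polarSolvation(solute, pbParams(scale = 2.5, paddingA = 15))
```

A command-line wrapper with the same options lives at
`inst/scripts/solvate.R`:

```sh
Rscript inst/scripts/solvate.R protein.pqr --scale 2.5 --method rpb
Rscript inst/scripts/solvate.R protein.pqr --scan-scales 1.5:4:0.5
```

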
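---
title: "Charge-based BEM with residual-driven adaptive refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based BEM with residual-driven adaptive refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The forward problem

Transcranial electrical stimulation (TES), electroconvulsive therapy and
EEG source analysis all need the quasi-static electric field produced in
the head by scalp electrodes. In the quasi-static regime the field is
governed by `div(sigma grad u) = 0` with piecewise-constant tissue
conductivities, so all structure lives on the tissue interfaces. The
boundary element method represents those interfaces exactly as triangulated
surfaces, with no volume mesh.

`chargebem` uses the *charge-based* formulation: the unknown is the induced
surface charge density `rho(x)` on every conductivity interface, not the
potential. At an interface point `x` with outward normal `n(x)` and
conductivity contrast

    kappa(x) = (sigma_in - sigma_out) / (sigma_in + sigma_out),

the charge satisfies a second-kind Fredholm integral equation: half the
local sheet density balances the contrast times the normal component of the
total field — the Coulomb field of all other charge plus the impressed
(electrode) field `E_i`. Discretized with piecewise-constant densities on
triangles and centroid collocation, the equation for triangle `T` reads

    c_T = 2 kappa_T n_T . ( sum_{K != T} |K| c_K (x_T - x_K) / (4 pi |x_T - x_K|^3) + E_i(x_T) ),

where `c = rho / eps0` is the scaled charge the package stores throughout
(units V/m; `eps0` cancels everywhere and physical charge is recoverable on
output). The kernel is the Coulomb kernel with the cubed distance in the
denominator. Away from the surfaces, the potential is the single-layer
potential `u(x) = sum_K |K| c_K / (4 pi |x - x_K|)` and the field its
gradient, so electrode currents, surface fields and deep-target fields all
come from the same charge vector.

### Electrodes

*Voltage electrodes* impose `u(x_T) = V_e` on each electrode triangle — a
first-kind (Dirichlet) constraint that replaces the second-kind row there.
First-kind rows are ill-conditioned and generate genuine charge
singularities along the electrode rim, which is precisely where adaptive
refinement is needed. *Current (sponge) electrodes* are idealized as a
uniform impressed source layer of density `gamma = I_e / (A_e sigma_skin)`
over the patch; every row stays second-kind and the injected currents must
sum to zero. Because the source layer is co-located with the induced
charge, the interface current balance
`sigma_out E_out.n - sigma_in E_in.n = J_s` picks up the layer's own jump
and the patch rows become `c = 2 kappa PV + kappa gamma`; with that local
source term the recovered electrode current matches the injected current
(a self-consistency check the test-suite enforces at the 2% level), and
the layer's jump also enters the one-sided fields used for flux
integration.

The sectored block preconditioner addresses the first-kind rows: the
discrete single-layer operator restricted to the electrode triangles is
built as a dense matrix per angular sector (tangent-plane rays through the
patch center split it into `d` near-even sectors), factorized once, and
applied as a left preconditioner on the electrode rows only. Sector count
defaults to `ceiling(Ne / 3000)` so each dense block stays cheap to
factorize; the omitted cross-sector coupling only weakens the
preconditioner, never the solution. Collocation breaks the exact symmetry
of the continuous kernel when neighboring areas differ, so each block is
symmetrized (`(M + M')/2`) before factorization.

### Near field

The centroid (point) approximation of the kernel is inaccurate when source
and observation triangles are close. For pairs closer than `near_factor`
times the larger of the two triangles' longest edges (default 4, set 0 to
disable) the package replaces the point term with the analytic potential
and gradient integrals of a constant density over a flat triangle,
evaluated by the standard edge-wise closed form. The same analytic
integral provides the self-term of the Dirichlet rows and the
preconditioner diagonal. These corrections are assembled once per mesh
state as a sparse set of pair deltas, so the per-iteration cost stays one
dense Coulomb sum plus one sparse scatter.

### Solver

The coupled system is solved matrix-free with restarted GMRES (modified
Gram–Schmidt, Givens rotations; defaults `tol = 1e-9` on the true relative
residual, restart 40, 300 iterations). Two interchangeable matvec
backends exist: a direct `O(N^2)` reference sum and a Barnes–Hut treecode
with Cartesian Taylor expansions (default opening angle 0.25, order 8),
which agrees with the direct sum to better than `1e-6` relative L2 — the
backend-equivalence contract the test-suite enforces. On a single core the
treecode only pays beyond roughly 50k triangles, which is where the
`"auto"` backend switches over.

## Adaptive mesh refinement

The exact charge residual is unknowable, so passes are compared with each
other. After solving pass `l`, the previous solution is injected onto the
current mesh through the refinement lineage (children inherit the parent
value, conserving the integral exactly), and the *surrogate residual*

    xi_T = |T|^p (rho_l,T - rho_{l-1},T)

is formed, with `p = 3/2` by default (any `p >= 0` is admissible; 3/2 is
the area scaling found to work well in practice, and it may be model
dependent). The per-triangle refinement score combines a nonnegative local
term with a distance-weighted nonlocal cross term:

    eta_T = |T|^{3/2} xi_T^2
            + 1/2 sum_{K != T} (|T||K| / dist(T, K)) xi_T xi_K,

with `dist` the centroid distance and the sum truncated at a 3 mm cutoff
for linear cost. `eta` can be negative through the cross term; it is
ranked as printed (signed), since negative values indicate error
cancellation and should not attract refinement. Each pass flags the
`ceiling(0.05 N)` largest-`eta` triangles (ties broken by triangle index,
ceiling so small meshes never stall) and splits each into four by edge
midpoints. The resulting hanging vertices are left in place: the
piecewise-constant charge basis needs no inter-element continuity. New
midpoints stay on the original flat geometry, so refinement conserves area
exactly; an optional snap hook exists for analytic surfaces and is off by
default. After refinement, exact duplicate triangles are removed and edges
shared by three or more triangles are reported (`fix_nonmanifold`), which
matters for segmentation-derived meshes with shared or overlapping
surfaces.

The first pass is a uniform refinement (relative model size exactly 4), the
bootstrap used for every reported run; the alternative `surrogate0` mode
instead seeds the surrogate with the contrast-scaled impressed field
`2 kappa n . E_i` and refines selectively from the start.

### Convergence metrics

Three quantities are tracked per pass, compared across passes with the
relative residual `R = 100 ||f_l - f_{l-1}|| / ||f_l||` (percent):
per-electrode currents (summed normal current flux over the patch, inner
side, positive into the head); the normal field on the innermost
("white-matter") surface, projected onto the fixed pass-0 reference mesh by
k-nearest-neighbor centroid averaging (`k = 3`; the projection is exact for
constants, so uniform rescalings do not inflate the metric); and the field
magnitude at a fixed grid of deep target points chosen at pass 0 and never
regenerated. The loop stops at a pass budget, a triangle budget, or when
both tracked residuals fall below a threshold.

## The synthetic benchmark

`sphere_model_spec()` generates the fully specified benchmark head: five
concentric icosphere interfaces at 92, 86, 80, 78 and 75 mm (scalp, skull,
CSF, gray and white matter boundaries), two antipodal circular electrodes
on the outer sphere (default radius 20 mm, axis ±z, ±1 V), and two deep
target structures: the top and bottom hemispheres of a 50 mm ball at the
origin, filled with a half-integer-offset Cartesian grid (default spacing
2.5 mm) so the two point sets are exact mirror images and every point is
strictly interior to the innermost surface. Conductivities default to a
conventional 5-layer set (S/m): scalp 0.333, skull 0.0066, CSF 1.654, gray
0.275, white 0.126, air outside. The symmetry, conservation and
convergence properties exercised by the test-suite do not hinge on these
values, and all of them are configurable.

What this benchmark emulates: nested closed interfaces with strong
conductivity jumps (skull ~50:1), electrode rim singularities, deep
targets shielded by multiple layers, and an exactly known mirror symmetry
that turns into sharp checks (anode and cathode currents equal and
opposite; global charge neutrality). What it does not emulate: anatomical
geometry (thin, highly curved, possibly non-manifold tissue sheets),
segmentation noise, or electrode placement on irregular scalp — so passing
here demonstrates correctness of the numerics and the refinement
machinery, not anatomical fidelity.

## Problem sizes and numerical choices

The test-suite and the acceptance script run desk-scale versions of the
benchmark, chosen so the whole suite completes on one core: analytic
oracles use a single icosphere at subdivision 4–5 (5,120–20,480
triangles); the adaptive benchmark starts from subdivision-2 spheres
(1,600 triangles), refines uniformly to 6,400 and then adaptively under a
25,000-triangle budget with a 5 mm deep grid, stopping when both tracked
residuals drop below 1% — reached after roughly eight adaptive passes with
the tracked residuals decreasing over the final passes. The solver runs
the benchmark at `tol = 1e-5` and `near_factor = 2`, both far below the
percent-scale quantities being tracked; oracle solves use `tol = 1e-9`
and `near_factor = 4`. Occasional single-pass upticks in the residual
sequence occur (accumulated small errors in the preconditioner and
near-field assembly); the stopping rule and the acceptance checks
therefore compare across the final passes rather than requiring strict
monotonicity pass by pass.

Other numerical choices: geometry is mm on disk and meters internally;
outward orientation is established per closed surface by the signed-volume
sign, and inconsistently oriented input is rejected rather than silently
repaired; coincident centroids anywhere in a kernel sum are an error, not
a warning; the point-in-surface test is parity ray casting with a fixed
direction pool and deterministic retries on marginal hits, while the
test-suite checks it against an independent solid-angle (winding-number)
oracle.

## Limitations

No full fast-multipole backend: the treecode has no cell-cell
translations, so very large models (tens of millions of triangles) are out
of practical reach on one core. Current electrodes use the standard
uniform sponge idealization with no contact-impedance layer. Meshes must
arrive consistently oriented per surface. The Galerkin theory behind the
refinement criterion (energy-norm bounds relating the Galerkin residual to
the charge residual) motivates the estimator but its constants are never
estimated, and no guaranteed-rate marking strategy is claimed.

## A worked example

```{r example}
library(chargebem)

spec <- sphere_model_spec(subdivision = 3, grid_spacing = 5)
model <- build_sphere_model(spec)
deep <- make_deep_structure_points(spec)$points
electrodes <- list(
  list(name = "anode", center = c(0, 0, 92), radius = 20,
       kind = "voltage", value = 1),
  list(name = "cathode", center = c(0, 0, -92), radius = 20,
       kind = "voltage", value = -1))

run <- run_amr(model, electrodes,
               config = amr_config(max_passes = 6, r_threshold = 1),
               opts = solver_options(tol = 1e-5, near_factor = 2),
               deep_points = deep, progress = TRUE)
convergence_report(run)
plot(run)
```
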
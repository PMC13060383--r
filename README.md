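# chargebem

Quasi-static bioelectric forward modeling — transcranial electrical
stimulation (TES), ECT and EEG — with the charge-based boundary element
method and residual-driven adaptive mesh refinement.

Who it is for: people who need the electric field produced in a layered
conductor (a head) by scalp electrodes, resolved well enough that electrode
currents and deep-target fields are discretization-converged, without a
volume mesh.

## The method

Tissue interfaces are triangulated surfaces; the unknown is the induced
surface charge density on them, stored scaled as `c = rho/eps0` (V/m). On
an interface with conductivity contrast
`kappa = (sigma_in - sigma_out)/(sigma_in + sigma_out)` the charge solves
the second-kind integral equation (centroid-collocated on triangles)

```
c_T = 2 kappa_T n_T . ( sum_{K != T} |K| c_K (x_T - x_K)/(4 pi |x_T - x_K|^3) + E_i(x_T) )
```

with `E_i` the impressed electrode field. Voltage electrodes add
first-kind Dirichlet rows `u(x_T) = V_e` (single-layer potential equal to
the set voltage) handled by a sectored block single-layer preconditioner;
current (sponge) electrodes enter as an impressed surface source layer.
The system is solved matrix-free by restarted GMRES over a direct `O(N^2)`
Coulomb backend or an equivalent treecode, with analytic flat-triangle
near-field integrals.

Refinement is driven by the area-scaled surrogate residual
`xi_T = |T|^p (rho_l - rho_{l-1})` (default `p = 3/2`) and the
local + nonlocal criterion

```
eta_T = |T|^{3/2} xi_T^2 + 1/2 sum_{K != T} (|T||K|/dist(T,K)) xi_T xi_K
```

(nonlocal term truncated at 3 mm). Each pass refines the top 5% of
triangles by `eta` (1-to-4 edge-midpoint split), cleans duplicated
features, re-solves, and tracks the pass-to-pass relative residual
`R = 100 ||f_l - f_{l-1}||/||f_l||` of electrode currents, the projected
normal field on the innermost surface, and deep-target field magnitudes.

A fully synthetic benchmark generator ships with the package: five
concentric sphere interfaces (92/86/80/78/75 mm), two antipodal circular
scalp electrodes, and deep "hippocampus" target grids (the top and bottom
hemispheres of a 50 mm ball). See the vignette
(`vignettes/charge-bem-amr.Rmd`) for the model, parameters and numerical
choices.

## Worked example

Adaptive refinement on the 5-layer sphere with 20 mm, ±1 V electrodes,
starting from subdivision-2 icospheres (1,600 triangles):

```r
library(chargebem)
spec  <- sphere_model_spec(subdivision = 2, grid_spacing = 5)
model <- build_sphere_model(spec)
deep  <- make_deep_structure_points(spec)$points
electrodes <- list(
  list(name = "anode",   center = c(0, 0,  92), radius = 20, kind = "voltage", value =  1),
  list(name = "cathode", center = c(0, 0, -92), radius = 20, kind = "voltage", value = -1))
run <- run_amr(model, electrodes,
               config = amr_config(max_passes = 9, r_threshold = 1),
               opts   = solver_options(tol = 1e-5, restart = 60, near_factor = 2),
               deep_points = deep, progress = TRUE)
convergence_report(run)
```

which prints (abridged):

```
 pass n_triangles  R_wm_pct R_deep_pct mean_E_deep_Vm relative_model_size current_mA_anode
    0        1600        NA         NA          5.865               1.000            6.118
    1        6400    13.1       11.1            5.278               4.000            6.293
    2        7360    10.1        6.30           4.973               4.600            6.516
    4        9736     3.12       1.99           4.770               5.290            7.270
    7       14809     2.25       1.04           4.469               8.048            7.292
    8       17032     0.750      0.224          4.425               9.256            7.275
```

Reading it: the first pass is the uniform 4x refinement; later passes
refine 5% of triangles each, concentrated at the electrode rims. The
tracked residuals of the white-matter-surface normal field (`R_wm_pct`)
and of the deep-target field magnitude (`R_deep_pct`) fall below 1% by
pass 8, while the electrode current stabilizes near 7.3 mA and the mean
deep field near 4.4 V/m — i.e. the quantities clinicians care about have
converged with respect to the discretization.

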
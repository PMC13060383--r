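#' Surrogate charge residual
#'
#' The true charge residual (difference between the unknown exact charge
#' and the discrete solution) is not computable, so the refinement
#' machinery uses an area-scaled difference of consecutive adaptive-pass
#' solutions as its surrogate:
#' `xi_T = |T|^p (rho_l,T - rho_{l-1},T)`, with the previous solution
#' interpolated onto the current mesh. The signed value is kept. `p = 3/2`
#' is the default area scaling (any `p >= 0` is admissible; 3/2 was found
#' to work well in practice, though this may be model dependent). Areas are
#' in mm^2.
#'
#' @param rho_l current-pass per-triangle scaled charge.
#' @param rho_prev previous-pass solution interpolated onto the current
#'   mesh (see [interpolate_solution()]).
#' @param areas per-triangle areas (mm^2).
#' @param p area-scaling exponent (>= 0).
#' @return per-triangle signed surrogate xi.
#' @export
surrogate <- function(rho_l, rho_prev, areas, p = 1.5) {
  if (length(rho_l) != length(rho_prev) || length(rho_l) != length(areas))
    stop("rho_l, rho_prev and areas must have equal length")
  if (any(areas <= 0)) stop("areas must be positive")
  if (p < 0) stop("p must be >= 0")
  areas^p * (rho_l - rho_prev)
}

#' Local + nonlocal refinement criterion
#'
#' Per-triangle refinement score combining a nonnegative local term with a
#' distance-weighted nonlocal cross term:
#' `eta_T = |T|^{3/2} xi_T^2
#'          + 1/2 sum_{K != T, dist(T,K) < cutoff} (|T||K|/dist(T,K)) xi_T xi_K`,
#' where `dist` is the centroid-to-centroid distance. The cross term is
#' restricted to triangles within the cutoff radius (default 3 mm) to keep
#' the cost linear; with `cutoff -> 0` the criterion reduces exactly to the
#' local term. The score can be negative through the cross term (error
#' cancellation), and is ranked as-is.
#'
#' @param xi per-triangle surrogate (see [surrogate()]).
#' @param mesh a [surface_mesh()] (areas mm^2, centroids mm).
#' @param cutoff nonlocal interaction radius (mm).
#' @return per-triangle eta.
#' @export
refinement_criterion <- function(xi, mesh, cutoff = 3) {
  m <- nrow(mesh$triangles)
  if (length(xi) != m) stop("xi length must equal the triangle count")
  if (cutoff <= 0) stop("cutoff must be positive")
  A <- mesh$area
  eta <- A^1.5 * xi^2
  pairs <- cb_near_pairs(mesh$centroid, rep(cutoff, m),
                         mesh$centroid, rep(cutoff, m), 1.0)
  keep <- pairs[, 1] != pairs[, 2]
  if (any(keep)) {
    i <- pairs[keep, 1] + 1L
    j <- pairs[keep, 2] + 1L
    d <- sqrt(rowSums((mesh$centroid[i, , drop = FALSE] -
                       mesh$centroid[j, , drop = FALSE])^2))
    if (any(d < 1e-12))
      stop("coincident centroids within the nonlocal cutoff")
    w <- 0.5 * A[i] * A[j] / d * xi[i] * xi[j]
    add <- numeric(m)
    agg <- rowsum(w, i)
    add[as.integer(rownames(agg))] <- agg
    eta <- eta + add
  }
  eta
}

#' Select the refinement target set
#'
#' Flags the `ceiling(fraction * N)` triangles with the largest criterion
#' values (default fraction 5% of all triangles). Ties are broken by
#' triangle index (lowest first), and the ceiling convention means
#' refinement never stalls on small meshes.
#'
#' @param eta per-triangle criterion values.
#' @param fraction fraction of triangles to refine, in (0, 1].
#' @return logical flag vector.
#' @export
select_refinement_set <- function(eta, fraction = 0.05) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n <- length(eta)
  nsel <- ceiling(fraction * n)
  flags <- logical(n)
  flags[order(-eta, seq_len(n))[seq_len(nsel)]] <- TRUE
  flags
}

#' AMR settings
#'
#' @param p surrogate area-scaling exponent.
#' @param fraction refinement fraction per pass.
#' @param nonlocal_cutoff nonlocal criterion radius (mm).
#' @param max_passes number of adaptive passes after the initial solve.
#' @param max_triangles triangle budget; a pass that would exceed it is not
#'   taken.
#' @param first_pass `"uniform"` (uniform barycentric refinement on pass 1)
#'   or `"surrogate0"` (use the contrast-scaled impressed field as a
#'   zeroth-pass charge estimate and refine selectively from the start).
#' @param r_threshold stop when both tracked relative residuals (percent)
#'   fall below this value.
#' @param k_project k-nearest-neighbor count for reference-mesh projection.
#' @return list of settings.
#' @export
amr_config <- function(p = 1.5, fraction = 0.05, nonlocal_cutoff = 3,
                       max_passes = 5, max_triangles = Inf,
                       first_pass = c("uniform", "surrogate0"),
                       r_threshold = 0.1, k_project = 3) {
  stopifnot(fraction > 0, fraction <= 1, p >= 0, nonlocal_cutoff > 0)
  list(p = p, fraction = fraction, nonlocal_cutoff = nonlocal_cutoff,
       max_passes = max_passes, max_triangles = max_triangles,
       first_pass = match.arg(first_pass), r_threshold = r_threshold,
       k_project = k_project)
}

#' Run the adaptive mesh refinement loop
#'
#' Pass 0 solves on the input mesh. Pass 1 refines uniformly (relative
#' model size exactly 4) and re-solves -- or, in `surrogate0` mode, flags
#' from a surrogate built against the contrast-scaled impressed field.
#' Every later pass interpolates the previous solution, computes the
#' surrogate and the refinement criterion, flags the top fraction, refines,
#' cleans duplicated features, re-solves, and records convergence metrics:
#' per-electrode currents, the relative residual of the projected normal
#' field on the reference (pass-0 innermost) surface, and the relative
#' residual of the deep-target field magnitudes. The loop stops at
#' `max_passes`, at the triangle budget, or when both tracked residuals
#' fall below the threshold.
#'
#' @param model a `bem_model` (see [bem_model()]).
#' @param electrodes electrode description list (as for [electrode_set()];
#'   patches are re-selected on each refined mesh).
#' @param config [amr_config()].
#' @param opts [solver_options()].
#' @param deep_points fixed n x 3 matrix of deep-target points (mm);
#'   required for the deep-field metric.
#' @param wm_surface label of the surface tracked by the reference-mesh
#'   metric (default: the innermost surface).
#' @param progress print per-pass summaries.
#' @return object of class `bem_amr_run`: `states` (per-pass list with
#'   `mesh`, `solution`, `xi`, `eta`, `flags`), `records` (data frame of
#'   convergence metrics), `reference_mesh`, `deep_points`, `config`.
#' @export
run_amr <- function(model, electrodes, config = amr_config(),
                    opts = solver_options(), deep_points = NULL,
                    wm_surface = NULL, progress = FALSE) {
  layers <- model$layers
  mesh <- model$mesh
  if (is.null(wm_surface)) wm_surface <- inner_surface_id(mesh)
  reference_mesh <- extract_surface(mesh, wm_surface)
  n0 <- nrow(mesh$triangles)
  states <- list()
  records <- list()
  f_wm_prev <- NULL
  e_deep_prev <- NULL
  sol_prev <- NULL

  for (l in 0:config$max_passes) {
    if (l > 0) {
      prev <- states[[l]]
      flags <- prev$flags
      ntri <- nrow(prev$mesh$triangles)
      if (ntri + 3 * sum(flags) > config$max_triangles) {
        if (progress) message("triangle budget reached; stopping")
        break
      }
      mesh <- barycentric_refine(prev$mesh, flags)
      fx <- fix_nonmanifold(mesh)
      mesh <- fx$mesh
    }
    cond <- triangle_conductivity(bem_model(mesh, layers))
    eset <- if (length(electrodes)) electrode_set(mesh, electrodes) else NULL
    sol <- solve_charges(mesh, cond, eset, opts = opts)

    # surrogate and criterion (pass >= 1, or surrogate0 mode at pass 0)
    xi <- eta <- rep(NA_real_, nrow(mesh$triangles))
    if (l >= 1) {
      rho_prev <- interpolate_solution(sol_prev$c, mesh$lineage)
      xi <- surrogate(sol$c, rho_prev, mesh$area, config$p)
      eta <- refinement_criterion(xi, mesh, config$nonlocal_cutoff)
      flags_next <- select_refinement_set(eta, config$fraction)
    } else if (config$first_pass == "surrogate0") {
      rho0 <- approx_rho0(mesh, cond, sol$drive, opts)
      xi <- surrogate(sol$c, rho0, mesh$area, config$p)
      eta <- refinement_criterion(xi, mesh, config$nonlocal_cutoff)
      flags_next <- select_refinement_set(eta, config$fraction)
    } else {
      flags_next <- rep(TRUE, nrow(mesh$triangles))   # uniform first pass
    }

    # convergence metrics
    nE_wm <- normal_field_on_surface(sol$c, mesh, surface = wm_surface,
                                     side = "inner", drive = sol$drive,
                                     near_factor = opts$near_factor,
                                     backend = opts$backend, tc = opts$tc)
    wm_mesh <- extract_surface(mesh, wm_surface)
    f_wm <- project_to_reference(nE_wm, wm_mesh, reference_mesh,
                                 k = config$k_project)
    e_deep <- if (!is.null(deep_points)) {
      sqrt(rowSums(efield_at_points(sol$c, mesh, deep_points,
                                    drive = sol$drive,
                                    near_factor = opts$near_factor,
                                    backend = opts$backend,
                                    tc = opts$tc)^2))
    } else NULL
    I_e <- if (!is.null(eset))
      electrode_current(sol, mesh, eset, cond, drive = sol$drive,
                        near_factor = opts$near_factor,
                        backend = opts$backend, tc = opts$tc) else numeric(0)
    r_wm <- if (!is.null(f_wm_prev)) safe_relative_residual(f_wm, f_wm_prev) else NA_real_
    r_deep <- if (!is.null(e_deep) && !is.null(e_deep_prev))
      safe_relative_residual(e_deep, e_deep_prev) else NA_real_

    rec <- data.frame(
      pass = l,
      n_triangles = nrow(mesh$triangles),
      n_electrode_triangles = if (!is.null(eset))
        length(electrode_triangles(eset)) else 0L,
      gmres_iterations = sol$iterations,
      R_wm_pct = r_wm,
      R_deep_pct = r_deep,
      mean_E_deep_Vm = if (!is.null(e_deep)) mean(e_deep) else NA_real_,
      relative_model_size = nrow(mesh$triangles) / n0)
    # per-target-set residuals when the deep points carry set labels
    lab <- attr(deep_points, "label")
    if (!is.null(lab) && !is.null(e_deep)) {
      for (lv in unique(lab)) {
        rec[[sprintf("R_deep_%s_pct", lv)]] <-
          if (!is.null(e_deep_prev))
            safe_relative_residual(e_deep[lab == lv],
                                   e_deep_prev[lab == lv]) else NA_real_
      }
    }
    for (en in seq_along(I_e))
      rec[[sprintf("current_mA_%s", names(I_e)[en])]] <- I_e[en] * 1e3
    records[[l + 1L]] <- rec
    states[[l + 1L]] <- list(pass = l, mesh = mesh, solution = sol, xi = xi,
                             eta = eta, flags = flags_next, f_wm = f_wm,
                             e_deep = e_deep, currents = I_e)
    if (progress)
      message(sprintf(
        "pass %d: N=%d Ne=%d iters=%d R_wm=%s R_deep=%s",
        l, rec$n_triangles, rec$n_electrode_triangles, sol$iterations,
        format(r_wm, digits = 3), format(r_deep, digits = 3)))
    f_wm_prev <- f_wm
    e_deep_prev <- e_deep
    sol_prev <- sol
    if (!is.na(r_wm) && !is.na(r_deep) &&
        r_wm < config$r_threshold && r_deep < config$r_threshold) {
      if (progress) message("residual threshold reached; stopping")
      break
    }
  }
  structure(list(states = states,
                 records = do.call(rbind_fill, records),
                 reference_mesh = reference_mesh,
                 deep_points = deep_points, config = config),
            class = "bem_amr_run")
}

# identically-zero quantities across both passes (null models) record 0
safe_relative_residual <- function(f_l, f_lm1) {
  if (sqrt(sum(f_l^2)) == 0 && sqrt(sum(f_lm1^2)) == 0) return(0)
  relative_residual(f_l, f_lm1)
}

inner_surface_id <- function(mesh) {
  ids <- unique(mesh$surface_id)
  r <- vapply(ids, function(s)
    mean(sqrt(rowSums(mesh$centroid[mesh$surface_id == s, , drop = FALSE]^2))),
    numeric(1))
  ids[which.min(r)]
}

# zeroth-pass charge estimate: the local response to the impressed field,
# c0 = 2 kappa n . E_inc (the dominant component near sources)
approx_rho0 <- function(mesh, cond, drive, opts) {
  if (is.null(drive)) return(numeric(nrow(mesh$triangles)))
  E <- drive_field_at(drive, mesh, mesh$centroid,
                      exclude_self = seq_len(nrow(mesh$triangles)),
                      backend = opts$backend, tc = opts$tc)
  2 * cond$kappa * rowSums(mesh$normal * E)
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  }))
}
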
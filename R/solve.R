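#' Second-kind fixed-point residual of the charge equation
#'
#' The defect `c_T - 2 kappa_T n_T . (E_nonlocal(c) + E_inc)_T` of a
#' candidate scaled-charge vector in the centroid-collocated charge
#' equation; its zero is the discrete charge solution. With `kappa == 0`
#' the zero vector is the solution for any drive. `near_factor = 0`
#' (default) is the pure centroid collocation form; a positive value adds
#' the analytic near-field corrections the solver can also use.
#'
#' @param c_scaled candidate per-triangle scaled charge (V/m).
#' @param mesh a [surface_mesh()].
#' @param conductivity a [conductivity_model()].
#' @param drive optional [drive_field()].
#' @param near_factor,backend,tc see [single_layer_potential()].
#' @return per-triangle residual vector.
#' @export
assemble_second_kind_residual <- function(c_scaled, mesh, conductivity,
                                          drive = NULL, near_factor = 0,
                                          backend = "direct",
                                          tc = treecode_options()) {
  m <- nrow(mesh$triangles)
  stopifnot(length(c_scaled) == m,
            length(conductivity$kappa) == m)
  si <- mesh_si(mesh)
  E <- backend_eval(si$cent, si$area * c_scaled, si$cent, seq_len(m) - 1L,
                    backend, want_pot = FALSE, want_field = TRUE, tc = tc)$field
  if (near_factor > 0) {
    nc <- near_corrections(mesh, si, si$cent, si$ledge, near_factor,
                           tgt_src_index = seq_len(m) - 1L)
    E <- E + apply_field_correction(nc, c_scaled, m)
  }
  if (!is.null(drive))
    E <- E + drive_field_at(drive, mesh, mesh$centroid,
                            exclude_self = seq_len(m), backend = backend,
                            tc = tc)
  c_scaled - 2 * conductivity$kappa * rowSums(mesh$normal * E)
}

#' Solver options
#'
#' @param tol GMRES relative residual tolerance.
#' @param max_iter maximum GMRES iterations.
#' @param restart GMRES restart length.
#' @param backend `"direct"`, `"treecode"` or `"auto"` (treecode beyond
#'   20k triangles).
#' @param near_factor near-field analytic-integration radius as a multiple
#'   of the local triangle edge length (0 = pure centroid collocation).
#' @param preconditioner `"sector"` (block single-layer on voltage
#'   electrodes) or `"none"`.
#' @param sectors fixed sector count per electrode (default: automatic).
#' @param tc [treecode_options()].
#' @return list of solver settings.
#' @export
solver_options <- function(tol = 1e-9, max_iter = 300, restart = 40,
                           backend = "auto", near_factor = 4,
                           preconditioner = "sector", sectors = NULL,
                           tc = treecode_options()) {
  list(tol = tol, max_iter = max_iter, restart = restart, backend = backend,
       near_factor = near_factor,
       preconditioner = match.arg(preconditioner, c("sector", "none")),
       sectors = sectors, tc = tc)
}

#' Solve the charge-based BEM system
#'
#' Assembles and solves the coupled system for the scaled surface charge
#' density `c = rho/eps0`: second-kind rows
#' `c_T - 2 kappa_T n_T . (E_nonlocal + E_inc) = 0` on ordinary triangles,
#' and first-kind Dirichlet rows `u(x_T) = V_e` (single-layer potential
#' equals the set electrode voltage) on voltage-electrode triangles. The
#' system is solved matrix-free by restarted GMRES; voltage-electrode rows
#' can be left-preconditioned by the sectored block single-layer
#' preconditioner. Current (sponge) electrodes enter through the impressed
#' field only and keep every row second-kind.
#'
#' @param mesh a [surface_mesh()].
#' @param conductivity a [conductivity_model()] (or a `bem_model`, whose
#'   mesh must be `mesh`).
#' @param electrodes optional [electrode_set()].
#' @param drive optional [drive_field()]; built automatically for current
#'   electrodes.
#' @param opts [solver_options()].
#' @param verbose print per-cycle residuals.
#' @return object of class `charge_solution`: `c` (scaled charge, V/m),
#'   `iterations`, `relres`, `history`, `converged`, `drive`, `precond`.
#' @export
solve_charges <- function(mesh, conductivity, electrodes = NULL,
                          drive = NULL, opts = solver_options(),
                          verbose = FALSE) {
  if (inherits(conductivity, "bem_model")) {
    mesh <- conductivity$mesh
    conductivity <- triangle_conductivity(conductivity)
  }
  m <- nrow(mesh$triangles)
  si <- mesh_si(mesh)
  kappa <- conductivity$kappa
  if (!is.null(electrodes) && electrodes$kind == "current" && is.null(drive))
    drive <- current_drive(mesh, electrodes, conductivity = conductivity)

  el_idx <- integer(0)
  el_v <- numeric(0)
  if (!is.null(electrodes) && electrodes$kind == "voltage") {
    el_idx <- electrode_triangles(electrodes)
    el_v <- unlist(lapply(electrodes$electrodes,
                          function(e) rep(e$value, length(e$patch))))
  }
  is_el <- logical(m)
  is_el[el_idx] <- TRUE

  # near-field corrections, built once per mesh state; target normals are
  # folded into per-pair scalars so each GMRES iteration does one scatter
  nc <- near_corrections(mesh, si, si$cent, si$ledge, opts$near_factor,
                         tgt_src_index = seq_len(m) - 1L)
  fk <- !nc$self
  fi <- nc$pairs[fk, 1]; fj <- nc$pairs[fk, 2]
  fv <- if (any(fk)) rowSums(nc$dfield[fk, , drop = FALSE] *
                             mesh$normal[fi + 1L, , drop = FALSE]) else numeric(0)
  # potential corrections restricted to electrode target rows (self terms
  # are always included for Dirichlet rows, even with near_factor = 0)
  pot_i <- pot_j <- integer(0); pot_v <- numeric(0)
  if (length(el_idx)) {
    keep <- is_el[nc$pairs[, 1] + 1L]
    pot_i <- nc$pairs[keep, 1]; pot_j <- nc$pairs[keep, 2]
    pot_v <- nc$dpot[keep]
    have_self <- nc$self[keep]
    miss <- el_idx[!(el_idx %in% (pot_i[have_self] + 1L))]
    if (length(miss)) {
      sp <- vapply(miss, function(t) {
        tri <- si$verts[mesh$triangles[t, ], , drop = FALSE]
        cb_tri_integral(tri, si$cent[t, ])$I / (4 * pi)
      }, numeric(1))
      pot_i <- c(pot_i, miss - 1L)
      pot_j <- c(pot_j, miss - 1L)
      pot_v <- c(pot_v, sp)
    }
  }

  einc_n <- numeric(m)
  gamma_src <- numeric(m)
  if (!is.null(drive)) {
    Einc <- drive_field_at(drive, mesh, mesh$centroid,
                           exclude_self = seq_len(m),
                           backend = opts$backend, tc = opts$tc)
    # analytic near corrections for the impressed layer, reusing the pairs
    if (!is.null(drive$gamma) && any(drive$gamma != 0)) {
      Einc <- Einc + apply_field_correction(nc, drive$gamma, m)
      # an injecting co-located source layer modifies the interface current
      # balance: sigma+ E+.n - sigma- E-.n = J_s with the layer's own jump
      # included gives c = 2 kappa PV + kappa gamma on the patch triangles
      gamma_src <- kappa * drive$gamma
    }
    einc_n <- rowSums(mesh$normal * Einc)
  }

  Afun <- function(x) {
    w <- si$area * x
    Ef <- backend_eval(si$cent, w, si$cent, seq_len(m) - 1L, opts$backend,
                       want_pot = FALSE, want_field = TRUE, tc = opts$tc)$field
    g <- rowSums(mesh$normal * Ef) + cb_pair_apply(fi, fj, fv, x, m)
    out <- x - 2 * kappa * g
    if (length(el_idx)) {
      up <- backend_eval(si$cent, w, si$cent[el_idx, , drop = FALSE],
                         el_idx - 1L,
                         if (length(el_idx) <= 2000L) "direct" else opts$backend,
                         want_pot = TRUE, want_field = FALSE, tc = opts$tc)$potential
      upc <- cb_pair_apply(pot_i, pot_j, pot_v, x, m)
      out[el_idx] <- up + upc[el_idx]
    }
    out
  }
  b <- 2 * kappa * einc_n + gamma_src
  if (length(el_idx)) b[el_idx] <- el_v

  Mfun <- identity
  precond <- NULL
  if (opts$preconditioner == "sector" && length(el_idx)) {
    precond <- build_preconditioner(mesh, electrodes,
                                    near_factor = max(opts$near_factor, 4))
    Mfun <- function(r) apply_preconditioner(precond, r)
  }
  sol <- gmres_solve(Afun, b, Mfun, tol = opts$tol, restart = opts$restart,
                     max_iter = opts$max_iter)
  if (verbose)
    message(sprintf("GMRES: %d iterations, relres %.2e%s", sol$iterations,
                    sol$relres, if (sol$converged) "" else " (NOT converged)"))
  if (!sol$converged)
    warning(sprintf("GMRES did not reach tol %.1e in %d iterations (relres %.2e)",
                    opts$tol, sol$iterations, sol$relres))
  structure(list(c = sol$x, iterations = sol$iterations, relres = sol$relres,
                 history = sol$history, converged = sol$converged,
                 drive = drive, n_triangles = m),
            class = "charge_solution")
}

#' @export
print.charge_solution <- function(x, ...) {
  cat(sprintf(
    "charge_solution: %d triangles, %d GMRES iterations, relres %.2e\n",
    x$n_triangles, x$iterations, x$relres))
  invisible(x)
}
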
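# Field and potential evaluation from a scaled surface charge density.
#
# All user-facing geometry is in mm; evaluation converts to meters. The
# charge unknown c = rho/eps0 is in V/m, so potentials come out in volts
# and fields in V/m with no eps0 anywhere.

MM <- 1e-3

mesh_si <- function(mesh) {
  list(cent = mesh$centroid * MM,
       area = mesh$area * MM^2,
       ledge = mesh$longest_edge * MM,
       verts = mesh$vertices * MM,
       tris0 = mesh$triangles - 1L,
       normal = mesh$normal)
}

#' Treecode settings
#'
#' Accuracy/cost knobs of the accelerated (Barnes-Hut Taylor treecode)
#' backend. With the defaults (opening angle 0.25, expansion order 8) the
#' treecode agrees with the direct sum to better than 1e-6 relative L2 on
#' typical surface meshes.
#'
#' @param theta multipole acceptance angle (cell radius / distance).
#' @param order Cartesian Taylor expansion order.
#' @param leaf_size maximum points per octree leaf.
#' @return list of settings.
#' @export
treecode_options <- function(theta = 0.25, order = 8, leaf_size = 32) {
  stopifnot(theta > 0, theta < 1, order >= 1, leaf_size >= 1)
  list(theta = theta, order = as.integer(order),
       leaf_size = as.integer(leaf_size))
}

# dispatch between the O(NM) direct reference backend and the treecode
backend_eval <- function(src, w, tgt, excl, backend = "direct",
                         want_pot = TRUE, want_field = TRUE,
                         tc = treecode_options()) {
  backend <- match.arg(backend, c("direct", "treecode", "auto"))
  if (backend == "auto")
    backend <- if (nrow(src) >= 50000L) "treecode" else "direct"
  if (backend == "direct")
    cb_direct_eval(src, w, tgt, excl, want_pot, want_field)
  else
    cb_treecode_eval(src, w, tgt, excl, tc$theta, tc$order, tc$leaf_size,
                     want_pot, want_field)
}

# Near-field correction set for targets `tgt` (SI units): pairs closer than
# factor * max(edge scale of target, edge scale of source) get the analytic
# constant-density flat-triangle integral in place of the centroid term.
# tgt_src_index (0-based, -1 for none) marks which source triangle a target
# point *is*, so self terms are handled (analytic potential; field skipped,
# the one-sided jump being applied by the caller).
near_corrections <- function(mesh, si, tgt, tgt_ledge, factor,
                             tgt_src_index = NULL) {
  if (factor <= 0 || nrow(tgt) == 0L)
    return(list(pairs = matrix(0L, 0, 2), dpot = numeric(0),
                dfield = matrix(0, 0, 3), self = logical(0)))
  pairs <- cb_near_pairs(tgt, tgt_ledge, si$cent, si$ledge, factor)
  if (is.null(tgt_src_index)) tgt_src_index <- integer(0)
  vals <- cb_near_values(si$verts, si$tris0, si$cent, si$area, tgt, pairs,
                         as.integer(tgt_src_index))
  self <- if (length(tgt_src_index) == nrow(tgt))
    tgt_src_index[pairs[, 1] + 1L] == pairs[, 2] else rep(FALSE, nrow(pairs))
  list(pairs = pairs, dpot = vals$dpot, dfield = vals$dfield, self = self)
}

apply_pot_correction <- function(nc, cvec, n_tgt) {
  if (!length(nc$dpot)) return(numeric(n_tgt))
  cb_pair_apply(nc$pairs[, 1], nc$pairs[, 2], nc$dpot, cvec, n_tgt)
}

apply_field_correction <- function(nc, cvec, n_tgt) {
  out <- matrix(0, n_tgt, 3)
  keep <- !nc$self
  if (!any(keep)) return(out)
  i <- nc$pairs[keep, 1]; j <- nc$pairs[keep, 2]
  for (k in 1:3)
    out[, k] <- cb_pair_apply(i, j, nc$dfield[keep, k], cvec, n_tgt)
  out
}

#' Nonlocal Coulomb field of the surface charge at triangle centroids
#'
#' The centroid-collocation sum at the heart of the second-kind charge
#' equation: for each triangle T, the field at its centroid from every
#' other triangle K treated as a point source of strength `|K| c_K`,
#' `E_T = sum_{K != T} |K| c_K (x_T - x_K) / (4 pi |x_T - x_K|^3)`.
#' The direct backend is the O(N^2) reference; the treecode backend must
#' agree with it to better than 1e-6 relative L2.
#'
#' @param c_scaled per-triangle scaled charge density rho/eps0 (V/m).
#' @param mesh a [surface_mesh()].
#' @param backend `"direct"`, `"treecode"` or `"auto"`.
#' @param tc [treecode_options()].
#' @return m x 3 matrix of fields (V/m).
#' @export
charge_matvec <- function(c_scaled, mesh, backend = "direct",
                          tc = treecode_options()) {
  si <- mesh_si(mesh)
  m <- nrow(mesh$triangles)
  stopifnot(length(c_scaled) == m)
  backend_eval(si$cent, si$area * c_scaled, si$cent, seq_len(m) - 1L,
               backend, want_pot = FALSE, want_field = TRUE, tc = tc)$field
}

#' Single-layer potential of the surface charge
#'
#' `u(x) = sum_K w_K(x) c_K` where `w_K` is the centroid approximation
#' `|K| / (4 pi |x - x_K|)` for distant triangles and the analytic
#' constant-density flat-triangle integral for triangles within the
#' near-field radius (`near_factor` times the larger of the triangle edge
#' scales). Evaluation exactly on a source centroid requires near-field
#' handling (the default) and uses the analytic self integral.
#'
#' @param c_scaled per-triangle scaled charge density (V/m).
#' @param mesh a [surface_mesh()].
#' @param points n x 3 evaluation points (mm); default: all triangle
#'   centroids (with analytic self terms).
#' @param near_factor near-field radius as a multiple of the local edge
#'   length (0 disables near-field handling).
#' @param backend,tc see [charge_matvec()].
#' @return potential in volts at each point.
#' @export
single_layer_potential <- function(c_scaled, mesh, points = NULL,
                                   near_factor = 4, backend = "direct",
                                   tc = treecode_options()) {
  si <- mesh_si(mesh)
  m <- nrow(mesh$triangles)
  stopifnot(length(c_scaled) == m)
  if (is.null(points)) {
    tgt <- si$cent
    tgt_ledge <- si$ledge
    src_idx <- seq_len(m) - 1L
  } else {
    tgt <- as.matrix(points) * MM
    tgt_ledge <- rep(0, nrow(tgt))
    src_idx <- rep(-1L, nrow(tgt))
  }
  base <- backend_eval(si$cent, si$area * c_scaled, tgt, src_idx, backend,
                       want_pot = TRUE, want_field = FALSE, tc = tc)$potential
  nc <- near_corrections(mesh, si, tgt, tgt_ledge, near_factor, src_idx)
  base + apply_pot_correction(nc, c_scaled, nrow(tgt))
}

#' Electric field at interior points
#'
#' Induced field of the surface charges (with near-field analytic gradients
#' for points close to a source triangle) plus the impressed drive field
#' when one is supplied. Points must not coincide with a source centroid.
#'
#' @param c_scaled per-triangle scaled charge density (V/m).
#' @param mesh a [surface_mesh()].
#' @param points n x 3 evaluation points (mm).
#' @param drive optional [drive_field()] contributing its impressed field.
#' @param near_factor,backend,tc see [single_layer_potential()].
#' @return n x 3 matrix of fields (V/m).
#' @export
efield_at_points <- function(c_scaled, mesh, points, drive = NULL,
                             near_factor = 4, backend = "direct",
                             tc = treecode_options()) {
  si <- mesh_si(mesh)
  tgt <- as.matrix(points) * MM
  base <- backend_eval(si$cent, si$area * c_scaled, tgt,
                       rep(-1L, nrow(tgt)), backend,
                       want_pot = FALSE, want_field = TRUE, tc = tc)$field
  nc <- near_corrections(mesh, si, tgt, rep(0, nrow(tgt)), near_factor)
  E <- base + apply_field_correction(nc, c_scaled, nrow(tgt))
  if (!is.null(drive)) E <- E + drive_field_at(drive, mesh, points,
                                               backend = backend, tc = tc)
  E
}

#' One-sided normal electric field on a surface
#'
#' Evaluates `n . E` on the chosen side of a charged interface using the
#' single-layer jump relation: the principal-value (nonlocal) field plus
#' the impressed field, minus half the local sheet density on the inner
#' side and plus half on the outer side. Outer minus inner equals the
#' scaled charge density exactly, by construction.
#'
#' @param c_scaled per-triangle scaled charge density (V/m).
#' @param mesh a [surface_mesh()].
#' @param surface surface label to evaluate on (default: all triangles).
#' @param side `"inner"` or `"outer"`.
#' @param drive optional [drive_field()]; its impressed layer density (for
#'   sponge electrodes) takes part in the jump term.
#' @param subset optional integer vector of triangle indices to evaluate on
#'   (overrides `surface`).
#' @param near_factor,backend,tc see [single_layer_potential()].
#' @return numeric vector of `n . E` (V/m) on the selected triangles.
#' @export
normal_field_on_surface <- function(c_scaled, mesh, surface = NULL,
                                    side = c("inner", "outer"), drive = NULL,
                                    subset = NULL,
                                    near_factor = 4, backend = "direct",
                                    tc = treecode_options()) {
  side <- match.arg(side)
  si <- mesh_si(mesh)
  m <- nrow(mesh$triangles)
  sel <- if (!is.null(subset)) as.integer(subset)
         else if (is.null(surface)) seq_len(m)
         else which(mesh$surface_id == surface)
  tgt <- si$cent[sel, , drop = FALSE]
  base <- backend_eval(si$cent, si$area * c_scaled, tgt, sel - 1L, backend,
                       want_pot = FALSE, want_field = TRUE, tc = tc)$field
  nc <- near_corrections(mesh, si, tgt, si$ledge[sel], near_factor,
                         tgt_src_index = sel - 1L)
  E <- base + apply_field_correction(nc, c_scaled, length(sel))
  gamma <- rep(0, m)
  if (!is.null(drive)) {
    E <- E + drive_field_at(drive, mesh, mesh$centroid[sel, , drop = FALSE],
                            exclude_self = sel, backend = backend, tc = tc)
    if (!is.null(drive$gamma)) gamma <- drive$gamma
  }
  pv <- rowSums(mesh$normal[sel, , drop = FALSE] * E)
  jump <- (c_scaled[sel] + gamma[sel]) / 2
  if (side == "inner") pv - jump else pv + jump
}
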
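#' Icosphere
#'
#' Recursive edge-midpoint subdivision of a regular icosahedron with vertex
#' re-projection onto the sphere. Subdivision level L gives `20 * 4^L`
#' triangles.
#'
#' @param subdivision nonnegative integer subdivision depth.
#' @param radius sphere radius (mm).
#' @param center length-3 center (mm).
#' @param surface_id label for the triangles.
#' @return a closed, outward-oriented [surface_mesh()].
#' @export
icosphere <- function(subdivision = 3, radius = 1, center = c(0, 0, 0),
                      surface_id = "S1") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v, f, surface_id, fix_orientation = FALSE)
  snap_unit <- function(x) x / sqrt(rowSums(x^2))
  for (l in seq_len(subdivision)) {
    mesh <- barycentric_refine(mesh, rep(TRUE, nrow(mesh$triangles)),
                               snap = snap_unit)
  }
  mesh$vertices <- sweep(mesh$vertices * radius, 2, center, `+`)
  mesh <- recompute_geometry(mesh)
  repair_orientation(mesh)
}

#' Specification of the 5-layer sphere benchmark
#'
#' A fully synthetic benchmark head: five concentric spherical tissue
#' interfaces (defaults 92, 86, 80, 78, 75 mm -- scalp, skull, CSF, gray and
#' white matter boundaries), two circular electrodes placed antipodally on
#' the +z/-z poles of the outer sphere, and a pair of deep target
#' structures: the top and bottom hemispheres (relative to the electrode
#' axis) of a ball of radius 50 mm at the origin, filled with a regular
#' Cartesian point grid.
#'
#' Default conductivities are a conventional 5-layer set (S/m): scalp 0.333,
#' skull 0.0066, CSF 1.654, gray matter 0.275, white matter 0.126, with air
#' (0) outside. Convergence, symmetry and conservation behavior of the
#' solver does not hinge on this choice, and all values are configurable.
#'
#' @param radii five strictly decreasing layer radii (mm).
#' @param electrode_radius electrode radius (mm), smaller than the outermost
#'   layer radius.
#' @param electrode_axis unit axis for the antipodal electrode pair.
#' @param deep_structure_radius radius of the deep target ball (mm), smaller
#'   than the innermost layer radius.
#' @param grid_spacing deep-target grid spacing (mm).
#' @param subdivision icosphere subdivision level per surface.
#' @param conductivities length-5 vector of per-layer conductivities,
#'   outermost first (S/m).
#' @return object of class `sphere_model_spec`.
#' @export
sphere_model_spec <- function(radii = c(92, 86, 80, 78, 75),
                              electrode_radius = 20,
                              electrode_axis = c(0, 0, 1),
                              deep_structure_radius = 50,
                              grid_spacing = 2.5,
                              subdivision = 4,
                              conductivities = c(scalp = 0.333,
                                                 skull = 0.0066,
                                                 csf = 1.654,
                                                 gray = 0.275,
                                                 white = 0.126)) {
  if (length(radii) != 5 || any(diff(radii) >= 0))
    stop("radii must be 5 strictly decreasing values")
  if (electrode_radius >= radii[1])
    stop("electrode_radius must be smaller than the outermost radius")
  if (deep_structure_radius >= radii[5])
    stop("deep_structure_radius must be smaller than the innermost radius")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (length(conductivities) != 5) stop("need 5 layer conductivities")
  structure(list(radii = radii, electrode_radius = electrode_radius,
                 electrode_axis = electrode_axis / sqrt(sum(electrode_axis^2)),
                 deep_structure_radius = deep_structure_radius,
                 grid_spacing = grid_spacing, subdivision = subdivision,
                 conductivities = conductivities),
            class = "sphere_model_spec")
}

#' Build the 5-layer sphere model
#'
#' Generates the five closed icosphere surfaces S1 (outermost) .. S5
#' (innermost) with the layer conductivity table: surface Si separates
#' layer i (inside) from layer i-1 (outside), with air outside S1.
#' Warns when the triangle edge length exceeds the smallest inter-layer gap,
#' since accurate interface resolution wants edges shorter than the distance
#' between neighboring tissue boundaries.
#'
#' @param spec a [sphere_model_spec()].
#' @return a `bem_model` (see [bem_model()]).
#' @export
build_sphere_model <- function(spec) {
  stopifnot(inherits(spec, "sphere_model_spec"))
  vert <- NULL; tris <- NULL; sid <- character(0)
  for (i in seq_along(spec$radii)) {
    s <- icosphere(spec$subdivision, spec$radii[i],
                   surface_id = sprintf("S%d", i))
    off <- if (is.null(vert)) 0L else nrow(vert)
    vert <- rbind(vert, s$vertices)
    tris <- rbind(tris, s$triangles + off)
    sid <- c(sid, s$surface_id)
  }
  mesh <- surface_mesh(vert, tris, sid)
  gap <- min(abs(diff(spec$radii)))
  maxedge <- max(mesh$longest_edge)
  if (maxedge > gap)
    warning(sprintf(paste0("triangle edges up to %.1f mm exceed the minimum ",
                           "inter-layer gap of %.1f mm; increase the ",
                           "subdivision level for accurate interface ",
                           "resolution"), maxedge, gap))
  sig <- unname(spec$conductivities)
  layers <- data.frame(surface = sprintf("S%d", 1:5),
                       sigma_in = sig,
                       sigma_out = c(0, sig[1:4]))
  bem_model(mesh, layers)
}

#' Deep-target point grids
#'
#' Regular Cartesian grid (half-integer offsets, so the grid is symmetric
#' about all coordinate planes and never sits exactly on the equator)
#' restricted to the interior of the deep-structure ball, split into the
#' top and bottom hemispheres along the electrode axis.
#'
#' @param spec a [sphere_model_spec()].
#' @param mesh optional model mesh; when given, every point is verified to
#'   lie inside the innermost surface and an error is raised otherwise.
#' @return list with matrices `top` and `bottom` (n x 3, mm) and the
#'   combined matrix `points` with a `label` attribute.
#' @export
make_deep_structure_points <- function(spec, mesh = NULL) {
  h <- spec$grid_spacing
  r <- spec$deep_structure_radius
  n <- ceiling(r / h)
  g <- (seq(-n, n - 1) + 0.5) * h
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) < r^2, , drop = FALSE]
  ax <- spec$electrode_axis
  s <- as.vector(pts %*% ax)
  top <- pts[s > 0, , drop = FALSE]
  bottom <- pts[s < 0, , drop = FALSE]
  if (!is.null(mesh)) {
    inner <- sprintf("S%d", length(spec$radii))
    ok <- points_inside_surface(pts, mesh, surface = inner)
    if (!all(ok))
      stop(sprintf("%d deep-target points fall outside %s", sum(!ok), inner))
  }
  all_pts <- rbind(top, bottom)
  attr(all_pts, "label") <- rep(c("top", "bottom"),
                                c(nrow(top), nrow(bottom)))
  list(top = top, bottom = bottom, points = all_pts)
}

#' Select an electrode patch on a surface
#'
#' All triangles of the given surface whose centroid lies within the
#' Euclidean ball of the given radius about the electrode center.
#'
#' @param mesh a [surface_mesh()].
#' @param center length-3 electrode center (mm), on or near the surface.
#' @param radius patch radius (mm).
#' @param surface surface label to restrict to (default: the outermost
#'   surface, chosen as the one with the largest mean centroid norm).
#' @return integer vector of triangle indices (into `mesh`); an error if the
#'   patch is empty, a warning if it is not edge-or-vertex connected.
#' @export
select_electrode_patch <- function(mesh, center, radius, surface = NULL) {
  if (is.null(surface)) surface <- outer_surface_id(mesh)
  sel <- which(mesh$surface_id == surface)
  d <- sqrt(rowSums((mesh$centroid[sel, , drop = FALSE] -
                     matrix(center, length(sel), 3, byrow = TRUE))^2))
  patch <- sel[d <= radius]
  if (!length(patch))
    stop(sprintf(paste0("no triangle centroid within %.1f mm of the ",
                        "electrode center; use a coarser radius or a finer ",
                        "mesh"), radius))
  if (!patch_is_connected(mesh, patch))
    warning("electrode patch is not connected")
  patch
}

outer_surface_id <- function(mesh) {
  ids <- unique(mesh$surface_id)
  r <- vapply(ids, function(s)
    mean(sqrt(rowSums(mesh$centroid[mesh$surface_id == s, , drop = FALSE]^2))),
    numeric(1))
  ids[which.max(r)]
}

patch_is_connected <- function(mesh, patch) {
  f <- mesh$triangles[patch, , drop = FALSE]
  n <- length(patch)
  if (n <= 1) return(TRUE)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  # union triangles sharing any vertex
  byv <- split(rep(seq_len(n), 3), as.vector(f))
  for (grp in byv) {
    if (length(grp) > 1) {
      r0 <- find(grp[1])
      for (j in grp[-1]) comp[find(j)] <- r0
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}
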
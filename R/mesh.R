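#' Labeled triangular surface mesh
#'
#' Container for a multi-surface triangulation with per-triangle tissue
#' labels, used by every stage of the charge-based BEM pipeline. Coordinates
#' are in millimeters. Per-triangle areas (mm^2), centroids and outward unit
#' normals are computed at construction; `lineage` maps each triangle to its
#' parent in the previous mesh generation (the identity for an unrefined
#' mesh) and is what solution interpolation across adaptive passes uses.
#'
#' Triangles must be consistently oriented within each surface. For closed
#' surfaces the global orientation is repaired so normals point outward
#' (positive signed volume).
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param surface_id per-triangle surface label (character or integer);
#'   recycled if length 1.
#' @param lineage optional integer vector mapping each triangle to its parent
#'   triangle index in the previous generation; defaults to the identity.
#' @param fix_orientation flip closed surfaces whose signed volume is
#'   negative so that normals point outward (default `TRUE`).
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `surface_id`, `lineage`, `area`, `centroid`,
#'   `normal`, `longest_edge`.
#' @export
surface_mesh <- function(vertices, triangles, surface_id = "S1",
                         lineage = NULL, fix_orientation = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  m <- nrow(triangles)
  if (length(surface_id) == 1L) surface_id <- rep(surface_id, m)
  if (length(surface_id) != m) stop("surface_id must have one entry per triangle")
  if (m > 0L && (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle vertex indices out of range")
  if (m > 0L && any(triangles[, 1] == triangles[, 2] |
                    triangles[, 2] == triangles[, 3] |
                    triangles[, 1] == triangles[, 3]))
    stop("a triangle repeats a vertex")
  if (is.null(lineage)) lineage <- seq_len(m)
  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         surface_id = as.vector(surface_id), lineage = as.integer(lineage)),
    class = "surface_mesh")
  mesh <- recompute_geometry(mesh)
  if (fix_orientation && m > 0L) mesh <- repair_orientation(mesh)
  mesh
}

recompute_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(cr^2))
  mesh$area <- nn / 2
  mesh$centroid <- (p1 + p2 + p3) / 3
  mesh$normal <- cr / ifelse(nn > 0, nn, 1)
  mesh$longest_edge <- pmax(sqrt(rowSums(e1^2)), sqrt(rowSums(e2^2)),
                            sqrt(rowSums((p3 - p2)^2)))
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, %d surface(s)\n",
              nrow(x$vertices), nrow(x$triangles),
              length(unique(x$surface_id))))
  for (s in unique(x$surface_id)) {
    sel <- x$surface_id == s
    cat(sprintf("  %s: %d triangles, area %.1f mm^2%s\n", s, sum(sel),
                sum(x$area[sel]),
                if (surface_is_closed(x, s)) " (closed)" else ""))
  }
  invisible(x)
}

# per-surface signed volume (mm^3); positive for outward-oriented closed
# surfaces enclosing the origin side consistently
signed_volume <- function(mesh, surface = NULL) {
  sel <- if (is.null(surface)) rep(TRUE, nrow(mesh$triangles))
         else mesh$surface_id == surface
  f <- mesh$triangles[sel, , drop = FALSE]
  v <- mesh$vertices
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

repair_orientation <- function(mesh) {
  for (s in unique(mesh$surface_id)) {
    if (!surface_is_closed(mesh, s)) next
    if (signed_volume(mesh, s) < 0) {
      sel <- mesh$surface_id == s
      mesh$triangles[sel, c(2, 3)] <- mesh$triangles[sel, c(3, 2)]
    }
  }
  recompute_geometry(mesh)
}

# unordered edge table: one row per triangle edge, columns (lo, hi, triangle)
edge_table <- function(mesh, sel = NULL) {
  f <- if (is.null(sel)) mesh$triangles else mesh$triangles[sel, , drop = FALSE]
  tri <- if (is.null(sel)) seq_len(nrow(mesh$triangles)) else which(sel)
  a <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  cbind(lo = pmin(a[, 1], a[, 2]), hi = pmax(a[, 1], a[, 2]),
        triangle = rep(tri, 3))
}

edge_use_counts <- function(mesh, sel = NULL) {
  et <- edge_table(mesh, sel)
  key <- paste(et[, 1], et[, 2])
  cnt <- table(key)
  list(edges = et, key = key, counts = cnt)
}

#' Test whether a surface is closed
#'
#' A surface is closed (watertight) when every unordered edge is shared by
#' exactly two of its triangles.
#'
#' @param mesh a [surface_mesh()].
#' @param surface surface label; `NULL` tests all triangles together.
#' @return logical scalar.
#' @export
surface_is_closed <- function(mesh, surface = NULL) {
  sel <- if (is.null(surface)) NULL else mesh$surface_id == surface
  ec <- edge_use_counts(mesh, sel)
  all(ec$counts == 2L)
}

#' Validate surface-mesh invariants
#'
#' Checks positive areas, unit normals, index ranges and (optionally)
#' duplicate triangles. Called by higher-level operations; exported because
#' tests and user pipelines use it as a guard.
#'
#' @param mesh a [surface_mesh()].
#' @param require_clean error when duplicate triangles are present.
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_mesh <- function(mesh, require_clean = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (any(mesh$area <= 0)) stop("mesh contains zero-area triangles")
  if (any(abs(sqrt(rowSums(mesh$normal^2)) - 1) > 1e-12))
    stop("mesh normals are not unit length")
  if (require_clean) {
    key <- apply(mesh$triangles, 1L, function(t) paste(sort(t), collapse = "-"))
    if (anyDuplicated(key)) stop("mesh contains duplicate triangles")
  }
  invisible(TRUE)
}

#' Extract one surface as a standalone mesh
#'
#' @param mesh a [surface_mesh()].
#' @param surface surface label to extract.
#' @return a [surface_mesh()] containing only that surface (vertices are
#'   re-indexed; lineage is reset to the identity).
#' @export
extract_surface <- function(mesh, surface) {
  sel <- mesh$surface_id == surface
  if (!any(sel)) stop(sprintf("no surface '%s' in mesh", surface))
  f <- mesh$triangles[sel, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               surface_id = mesh$surface_id[sel],
               fix_orientation = FALSE)
}
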
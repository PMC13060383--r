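#' Point-in-closed-surface test
#'
#' Classifies points as strictly interior to a closed triangulated surface
#' by parity ray casting: a ray from each point is intersected with every
#' triangle and an odd crossing count means inside. Marginal intersections
#' (grazing an edge or vertex, near-parallel rays) automatically retry with
#' a different ray direction from a fixed pool, so the result is
#' deterministic.
#'
#' @param points numeric n x 3 matrix of query points (mm).
#' @param mesh a closed [surface_mesh()]; if it carries several surfaces the
#'   union is tested, which is only meaningful for a single closed surface.
#' @param surface optional surface label to test against.
#' @return logical vector, `TRUE` for strictly interior points.
#' @export
points_inside_surface <- function(points, mesh, surface = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (!is.null(surface)) mesh <- extract_surface(mesh, surface)
  ec <- edge_use_counts(mesh)
  bad <- names(ec$counts)[ec$counts != 2L]
  if (length(bad))
    stop(sprintf("surface is not closed; offending edges (vertex pairs): %s%s",
                 paste(utils::head(bad, 10), collapse = "; "),
                 if (length(bad) > 10) " ..." else ""))
  cb_points_inside(points, mesh$vertices, mesh$triangles - 1L)
}
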
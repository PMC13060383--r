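#' Project a per-triangle field onto a reference mesh
#'
#' For each reference-mesh triangle centroid, takes the unweighted mean of
#' the field values at the k nearest centroids of the refined mesh. This is
#' how fields computed on adaptively refined meshes are compared across
#' passes on a fixed reference surface.
#'
#' @param field numeric vector, one value per refined-mesh triangle.
#' @param refined_mesh the [surface_mesh()] carrying `field`.
#' @param reference_mesh the fixed [surface_mesh()] to project onto.
#' @param k number of nearest neighbors to average (default 3).
#' @return numeric vector, one value per reference-mesh triangle.
#' @export
project_to_reference <- function(field, refined_mesh, reference_mesh, k = 3) {
  if (k < 1) stop("k must be >= 1")
  m <- nrow(refined_mesh$triangles)
  if (length(field) != m)
    stop("field length must match the refined mesh triangle count")
  if (m == 0L || nrow(reference_mesh$triangles) == 0L)
    stop("both meshes must be nonempty")
  if (k > m)
    stop(sprintf("k = %d exceeds the refined triangle count (%d)", k, m))
  idx <- cb_knn(reference_mesh$centroid, refined_mesh$centroid, as.integer(k))
  rowMeans(matrix(field[idx], nrow = nrow(idx)))
}
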
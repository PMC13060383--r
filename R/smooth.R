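#' Taubin smoothing
#'
#' Alternating lambda/mu uniform-Laplacian smoothing (a lambda shrink step
#' followed by a mu inflation step per iteration), applied to vertex
#' positions only; connectivity is untouched. Vertex adjacency is derived
#' from the triangle edges, so vertices are only averaged with neighbors on
#' their own surface and disjoint surfaces never influence each other --
#' this is the non-manifold-safe graph form of the filter.
#'
#' Stability requires `0 < lambda < -mu` (the classical pass-band
#' condition), e.g. the common pair (0.5, -0.53).
#'
#' @param mesh a [surface_mesh()].
#' @param lambda positive smoothing factor.
#' @param mu negative inflation factor with `abs(mu) > lambda`.
#' @param iterations number of lambda/mu iteration pairs (0 returns the mesh
#'   unchanged).
#' @return the smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10) {
  if (!(lambda > 0 && mu < 0 && abs(mu) > lambda))
    stop("Taubin stability requires lambda > 0 > mu and abs(mu) > lambda")
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0) return(mesh)
  nv <- nrow(mesh$vertices)
  et <- edge_table(mesh)
  # symmetric unique neighbor lists
  pair <- unique(cbind(c(et[, 1], et[, 2]), c(et[, 2], et[, 1])))
  ord <- order(pair[, 1])
  pair <- pair[ord, , drop = FALSE]
  deg <- tabulate(pair[, 1], nbins = nv)
  v <- mesh$vertices
  lap_step <- function(v, w) {
    s <- rowsum(v[pair[, 2], , drop = FALSE], pair[, 1], reorder = TRUE)
    idx <- as.integer(rownames(s))
    mean_nb <- v
    mean_nb[idx, ] <- s / deg[idx]
    v + w * (mean_nb - v)
  }
  for (it in seq_len(iterations)) {
    v <- lap_step(v, lambda)
    v <- lap_step(v, mu)
  }
  mesh$vertices <- v
  recompute_geometry(mesh)
}
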
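#' Sectored block single-layer preconditioner
#'
#' The Dirichlet (voltage-electrode) rows of the coupled system form a
#' first-kind integral equation, which is ill-conditioned and produces
#' charge singularities along the electrode rim. This preconditioner is the
#' discrete single-layer operator restricted to the electrode triangles,
#' built block-wise per angular sector (see [sector_electrode()]) so each
#' dense block stays small: entry (i, j) is the potential at centroid i due
#' to unit scaled charge on triangle j, with analytic near-field entries
#' within the near radius and the analytic self-integral on the diagonal.
#' Blocks are symmetrized (collocation breaks the exact symmetry of the
#' continuous kernel when areas differ) and LU-factorized once via a QR
#' decomposition for repeated application. Cross-sector coupling is
#' deliberately omitted; the preconditioner need not be exact.
#'
#' @param mesh a [surface_mesh()].
#' @param eset an [electrode_set()].
#' @param near_factor near-field radius rule (see
#'   [single_layer_potential()]).
#' @return object of class `block_preconditioner` with per-sector factor
#'   objects and the electrode-row index map.
#' @export
build_preconditioner <- function(mesh, eset, near_factor = 4) {
  si <- mesh_si(mesh)
  blocks <- list()
  for (e in eset$electrodes) {
    for (s in sort(unique(e$sector))) {
      ids <- e$patch[e$sector == s]
      M <- single_layer_block(mesh, si, ids, near_factor)
      M <- (M + t(M)) / 2
      qrM <- tryCatch(qr(M, LAPACK = TRUE),
                      error = function(e) stop("singular preconditioner block"))
      if (any(abs(diag(qr.R(qrM))) < 1e-300))
        stop("singular preconditioner block (duplicate centroids?)")
      blocks[[length(blocks) + 1L]] <- list(rows = ids, qr = qrM, M = M)
    }
  }
  structure(list(blocks = blocks), class = "block_preconditioner")
}

# dense single-layer potential matrix on a triangle subset (SI units in,
# volts per unit scaled charge out)
single_layer_block <- function(mesh, si, ids, near_factor) {
  n <- length(ids)
  P <- si$cent[ids, , drop = FALSE]
  D <- sqrt(pmax(outer(rowSums(P^2), rep(1, n)) +
                 outer(rep(1, n), rowSums(P^2)) - 2 * tcrossprod(P), 0))
  if (any(D[upper.tri(D)] < 1e-15))
    stop("duplicate centroids in preconditioner sector")
  M <- matrix(si$area[ids], n, n, byrow = TRUE) / (4 * pi * pmax(D, 1e-300))
  # analytic entries: self always; near pairs per the near rule
  pairs <- cb_near_pairs(P, si$ledge[ids], P, si$ledge[ids],
                         max(near_factor, 1e-9))
  take <- unique(rbind(pairs, cbind(seq_len(n) - 1L, seq_len(n) - 1L)))
  for (q in seq_len(nrow(take))) {
    i <- take[q, 1] + 1L
    j <- take[q, 2] + 1L
    tri <- si$verts[mesh$triangles[ids[j], ], , drop = FALSE]
    M[i, j] <- cb_tri_integral(tri, P[i, ])$I / (4 * pi)
  }
  M
}

#' Apply a block preconditioner to a residual
#'
#' Electrode rows are replaced by the block solves; all other rows pass
#' through unchanged (identity preconditioning of the well-conditioned
#' second-kind rows).
#'
#' @param precond a `block_preconditioner`.
#' @param r residual vector over all mesh triangles.
#' @return preconditioned vector.
#' @export
apply_preconditioner <- function(precond, r) {
  z <- r
  for (b in precond$blocks)
    z[b$rows] <- qr.coef(b$qr, r[b$rows])
  z
}
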
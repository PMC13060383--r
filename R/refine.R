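#' Selective barycentric (1-to-4) refinement
#'
#' Splits every flagged triangle into four children by inserting the three
#' edge midpoints; the three corner children and the central child exactly
#' tile the parent, so flat-triangle area is conserved and a uniform pass
#' (all triangles flagged) quadruples the triangle count. Unflagged
#' triangles are carried over unchanged. Midpoint vertices shared between
#' two flagged neighbors are created once. Selective refinement leaves
#' hanging vertices on the unrefined side of an edge; this is acceptable for
#' a piecewise-constant charge basis, which needs no inter-element
#' continuity.
#'
#' New midpoints stay on the original piecewise-flat geometry by default; an
#' optional `snap` function can post-process newly created vertices (e.g. to
#' re-project them onto an analytic sphere).
#'
#' @param mesh a [surface_mesh()].
#' @param flags logical vector, one entry per triangle (`TRUE` = refine).
#' @param snap optional `function(xyz)` applied to the matrix of newly
#'   created vertices; must return a matrix of the same shape.
#' @return a [surface_mesh()] whose `lineage` maps each child triangle to
#'   its parent index in `mesh`.
#' @export
barycentric_refine <- function(mesh, flags, snap = NULL) {
  m <- nrow(mesh$triangles)
  flags <- as.logical(flags)
  if (length(flags) != m) stop("flags length must equal the triangle count")
  if (any(mesh$area[flags] <= 0))
    stop(sprintf("cannot refine degenerate (zero-area) triangle(s): %s",
                 paste(which(flags & mesh$area <= 0), collapse = ", ")))
  if (!any(flags)) {
    out <- mesh
    out$lineage <- seq_len(m)
    return(out)
  }
  f <- mesh$triangles
  v <- mesh$vertices
  ftri <- which(flags)
  # unique midpoint per unordered edge of the flagged set
  ed <- rbind(cbind(f[ftri, 1], f[ftri, 2]),
              cbind(f[ftri, 2], f[ftri, 3]),
              cbind(f[ftri, 3], f[ftri, 1]))
  elo <- pmin(ed[, 1], ed[, 2])
  ehi <- pmax(ed[, 1], ed[, 2])
  key <- paste(elo, ehi)
  uk <- !duplicated(key)
  mid_index <- match(key, key[uk])           # edge -> unique midpoint slot
  newv <- (v[elo[uk], , drop = FALSE] + v[ehi[uk], , drop = FALSE]) / 2
  if (!is.null(snap)) newv <- snap(newv)
  nv0 <- nrow(v)
  vid <- nv0 + mid_index                      # vertex ids of all midpoints
  nf <- length(ftri)
  mab <- vid[seq_len(nf)]
  mbc <- vid[nf + seq_len(nf)]
  mca <- vid[2 * nf + seq_len(nf)]
  a <- f[ftri, 1]; b <- f[ftri, 2]; cc <- f[ftri, 3]
  children <- rbind(cbind(a, mab, mca), cbind(mab, b, mbc),
                    cbind(mca, mbc, cc), cbind(mab, mbc, mca))
  child_parent <- rep(ftri, 4)
  keep <- which(!flags)
  new_f <- rbind(f[keep, , drop = FALSE], children)
  new_lineage <- c(keep, child_parent)
  new_sid <- c(mesh$surface_id[keep], rep(mesh$surface_id[ftri], 4))
  surface_mesh(rbind(v, newv), new_f, surface_id = new_sid,
               lineage = as.integer(new_lineage), fix_orientation = FALSE)
}

#' Interpolate a per-triangle solution onto a refined mesh
#'
#' Piecewise-constant injection along the refinement lineage: every child
#' triangle receives its parent's value, so the area-weighted integral of
#' the field is conserved exactly for flat refinements.
#'
#' @param values numeric vector on the parent mesh (one value per parent
#'   triangle).
#' @param lineage integer vector mapping each child triangle to its parent
#'   index (usually `child_mesh$lineage`).
#' @return numeric vector on the child mesh.
#' @export
interpolate_solution <- function(values, lineage) {
  lineage <- as.integer(lineage)
  if (any(is.na(lineage)) || any(lineage < 1L) || any(lineage > length(values)))
    stop("lineage contains entries with no parent value")
  values[lineage]
}
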
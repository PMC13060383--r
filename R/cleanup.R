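#' Remove duplicated mesh features
#'
#' Refinement of overlapping or shared surfaces can produce duplicate
#' triangles and edges shared by three or more triangles. This pass
#' (1) removes exact duplicate triangles -- triangles whose three vertex
#' positions coincide under a 1e-9 mm position hash, whether or not they
#' share vertex indices -- keeping the first copy, and (2) reports any
#' remaining edges incident to three or more triangles. Triangles on such
#' edges are only removed when they are exact geometric duplicates; other
#' multi-shared edges are reported but left in place, since the
#' piecewise-constant charge basis tolerates them.
#'
#' @param mesh a [surface_mesh()].
#' @param tol position hash tolerance in mm.
#' @return list with elements `mesh` (the cleaned [surface_mesh()]) and
#'   `report` (list: `duplicates_removed`, `multi_edges` -- a k x 2 matrix of
#'   vertex index pairs for edges still shared by 3+ triangles, and
#'   `triangles_removed` -- indices removed from the input mesh).
#' @export
fix_nonmanifold <- function(mesh, tol = 1e-9) {
  m <- nrow(mesh$triangles)
  if (m == 0L)
    return(list(mesh = mesh, report = list(duplicates_removed = 0L,
                                           multi_edges = matrix(0L, 0, 2),
                                           triangles_removed = integer(0))))
  # geometric key: sorted vertex-position hashes
  vkey <- apply(round(mesh$vertices / tol), 1L, paste, collapse = ",")
  tkey <- apply(matrix(vkey[mesh$triangles], ncol = 3), 1L,
                function(k) paste(sort(k), collapse = "|"))
  dup <- duplicated(tkey)
  keep <- which(!dup)
  removed <- which(dup)
  out <- surface_mesh(mesh$vertices,
                      mesh$triangles[keep, , drop = FALSE],
                      surface_id = mesh$surface_id[keep],
                      lineage = mesh$lineage[keep],
                      fix_orientation = FALSE)
  ec <- edge_use_counts(out)
  bad <- names(ec$counts)[ec$counts >= 3L]
  multi <- if (length(bad)) {
    do.call(rbind, lapply(strsplit(bad, " "), as.integer))
  } else matrix(0L, 0, 2)
  list(mesh = out,
       report = list(duplicates_removed = length(removed),
                     multi_edges = multi,
                     triangles_removed = removed))
}

#' Write a cleanup report as JSON
#'
#' @param report the `report` element returned by [fix_nonmanifold()].
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_cleanup_report <- function(report, path) {
  jsonlite::write_json(
    list(duplicates_removed = report$duplicates_removed,
         n_multi_edges = nrow(report$multi_edges),
         multi_edges = report$multi_edges,
         triangles_removed = report$triangles_removed),
    path, auto_unbox = TRUE)
  invisible(path)
}
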
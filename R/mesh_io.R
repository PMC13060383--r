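#' Read a triangular surface mesh file
#'
#' Supports ASCII OFF, ASCII PLY and ASCII STL. STL files are triangle
#' soups; their vertices are merged under a 1e-9 mm position hash on read.
#'
#' @param path file path; format inferred from the extension
#'   (`.off`, `.ply`, `.stl`).
#' @param surface_id label assigned to every triangle.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, surface_id = "S1") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = read_off(path, surface_id),
         ply = read_ply(path, surface_id),
         stl = read_stl(path, surface_id),
         stop(sprintf("unsupported mesh format '%s'", ext)))
}

#' Write a triangular surface mesh file
#'
#' @param mesh a [surface_mesh()] (a single surface; use
#'   [write_model_manifest()] for multi-surface models).
#' @param path output path; format from the extension (`.off`, `.ply`,
#'   `.stl`, all ASCII).
#' @return `path` invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = write_off(mesh, path),
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", ext)))
  invisible(path)
}

read_off <- function(path, surface_id) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!grepl("OFF", ln[1])) stop("not an OFF file")
  hd <- scan(text = ln[2], quiet = TRUE)
  nv <- hd[1]; nf <- hd[2]
  v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fr <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  if (any(fr[, 1] != 3)) stop("only triangular OFF faces are supported")
  surface_mesh(v, fr[, 2:4] + 1L, surface_id)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
}

read_ply <- function(path, surface_id) {
  ln <- readLines(path)
  end_hdr <- which(ln == "end_header")[1]
  if (is.na(end_hdr)) stop("not an ASCII PLY file")
  hdr <- ln[seq_len(end_hdr)]
  if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", hdr, value = TRUE)[1]))
  v <- matrix(scan(text = ln[end_hdr + seq_len(nv)], quiet = TRUE),
              nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fr <- matrix(scan(text = ln[end_hdr + nv + seq_len(nf)], quiet = TRUE),
               nrow = nf, byrow = TRUE)
  if (any(fr[, 1] != 3)) stop("only triangular PLY faces are supported")
  surface_mesh(v, fr[, 2:4] + 1L, surface_id)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
}

read_stl <- function(path, surface_id, tol = 1e-9) {
  ln <- readLines(path)
  if (!grepl("^\\s*solid", ln[1]))
    stop("only ASCII STL is supported (file does not start with 'solid')")
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  xyz <- matrix(scan(text = gsub("^\\s*vertex", "", vl), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  if (nrow(xyz) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- apply(round(xyz / tol), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  v <- xyz[uk, , drop = FALSE]
  f <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_mesh(v, f, surface_id)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid chargebem", con)
  v <- mesh$vertices
  f <- mesh$triangles
  n <- mesh$normal
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid chargebem", con)
}

#' Write a multi-surface model (one mesh file per surface plus a manifest)
#'
#' The JSON manifest records, per surface: name, mesh file, inner and outer
#' conductivity (S/m) and whether the surface is closed.
#'
#' @param model a `bem_model` (see [bem_model()]).
#' @param dir output directory (created if missing).
#' @param format mesh file format (`"off"`, `"ply"` or `"stl"`).
#' @return the manifest path invisibly.
#' @export
write_model_manifest <- function(model, dir, format = "off") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surfaces <- lapply(seq_len(nrow(model$layers)), function(i) {
    s <- model$layers$surface[i]
    sub <- extract_surface(model$mesh, s)
    f <- file.path(dir, sprintf("%s.%s", s, format))
    write_mesh(sub, f)
    list(name = s, file = basename(f),
         sigma_in = model$layers$sigma_in[i],
         sigma_out = model$layers$sigma_out[i],
         closed = surface_is_closed(sub))
  })
  manifest <- file.path(dir, "model.json")
  jsonlite::write_json(list(surfaces = surfaces), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a multi-surface model manifest
#'
#' @param manifest path to a `model.json` written by
#'   [write_model_manifest()].
#' @return a `bem_model`.
#' @export
read_model_manifest <- function(manifest) {
  spec <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  meshes <- list()
  layers <- data.frame(surface = character(0), sigma_in = numeric(0),
                       sigma_out = numeric(0))
  vert <- NULL; tris <- NULL; sid <- character(0)
  for (s in spec$surfaces) {
    msh <- read_mesh(file.path(dir, s$file), surface_id = s$name)
    off <- if (is.null(vert)) 0L else nrow(vert)
    vert <- rbind(vert, msh$vertices)
    tris <- rbind(tris, msh$triangles + off)
    sid <- c(sid, msh$surface_id)
    layers <- rbind(layers, data.frame(surface = s$name,
                                       sigma_in = s$sigma_in,
                                       sigma_out = s$sigma_out))
  }
  bem_model(surface_mesh(vert, tris, sid), layers)
}
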
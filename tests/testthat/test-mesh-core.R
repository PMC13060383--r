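test_that("uniform barycentric refinement quadruples the count and conserves area", {
  mesh <- icosphere(2, radius = 10)
  n0 <- nrow(mesh$triangles)
  ref <- barycentric_refine(mesh, rep(TRUE, n0))
  expect_identical(nrow(ref$triangles), 4L * n0)
  # flat refinement (no snapping) conserves total area exactly
  expect_equal(sum(ref$area), sum(mesh$area), tolerance = 1e-12)
  expect_identical(sort(unique(ref$lineage)), seq_len(n0))
})

test_that("refining one flat unit right triangle gives 4 children of area 1/8", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1), fix_orientation = FALSE)
  ref <- barycentric_refine(tri, TRUE)
  expect_identical(nrow(ref$triangles), 4L)
  expect_equal(sum(ref$area), 0.5, tolerance = 1e-14)
  expect_equal(ref$area, rep(0.125, 4), tolerance = 1e-14)
  expect_identical(ref$lineage, rep(1L, 4))
})

test_that("empty flag set returns an identical mesh with identity lineage", {
  mesh <- icosphere(1, radius = 5)
  ref <- barycentric_refine(mesh, rep(FALSE, nrow(mesh$triangles)))
  expect_identical(ref$triangles, mesh$triangles)
  expect_identical(ref$lineage, seq_len(nrow(mesh$triangles)))
})

test_that("degenerate flagged triangles are rejected", {
  bad <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      matrix(c(1, 2, 3), 1), fix_orientation = FALSE)
  expect_error(barycentric_refine(bad, TRUE), "degenerate")
})

test_that("selective refinement shares midpoints between flagged neighbors", {
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                       rbind(c(1, 2, 3), c(2, 4, 3)), fix_orientation = FALSE)
  ref <- barycentric_refine(mesh, c(TRUE, TRUE))
  # 4 original + midpoints: 3 + 3 - 1 shared = 5 new vertices
  expect_identical(nrow(ref$vertices), 9L)
  expect_identical(nrow(ref$triangles), 8L)
})

test_that("mesh invariants hold on construction", {
  mesh <- icosphere(3, radius = 80)
  expect_true(validate_mesh(mesh, require_clean = TRUE))
  expect_true(all(abs(sqrt(rowSums(mesh$normal^2)) - 1) <= 1e-12))
  expect_true(all(mesh$area > 0))
  # outward orientation: positive signed volume, normals point away
  expect_gt(chargebem:::signed_volume(mesh), 0)
  expect_true(all(rowSums(mesh$normal * mesh$centroid) > 0))
  expect_error(surface_mesh(diag(3), matrix(c(1, 1, 2), 1)), "repeats")
  expect_error(surface_mesh(diag(3), matrix(c(1, 2, 4), 1)), "out of range")
})

test_that("fix_nonmanifold removes duplicates and reports multi-shared edges", {
  mesh <- icosphere(2, radius = 1)
  clean <- fix_nonmanifold(mesh)
  expect_identical(nrow(clean$mesh$triangles), nrow(mesh$triangles))
  expect_identical(clean$report$duplicates_removed, 0L)

  dup <- surface_mesh(mesh$vertices,
                      rbind(mesh$triangles, mesh$triangles[7, ]),
                      surface_id = c(mesh$surface_id, mesh$surface_id[7]),
                      fix_orientation = FALSE)
  fixed <- fix_nonmanifold(dup)
  expect_identical(fixed$report$duplicates_removed, 1L)
  expect_identical(nrow(fixed$mesh$triangles), nrow(mesh$triangles))

  # 3-triangle fan: the shared edge must match a brute-force incidence count
  fan <- three_fan_mesh()
  rep3 <- fix_nonmanifold(fan)
  et <- rbind(fan$triangles[, 1:2], fan$triangles[, 2:3], fan$triangles[, c(3, 1)])
  key <- paste(pmin(et[, 1], et[, 2]), pmax(et[, 1], et[, 2]))
  brute <- names(table(key))[table(key) >= 3]
  got <- paste(rep3$report$multi_edges[, 1], rep3$report$multi_edges[, 2])
  expect_identical(sort(got), sort(brute))
  expect_identical(nrow(rep3$mesh$triangles), 3L)   # no exact duplicates
})

test_that("Taubin smoothing is identity at 0 iterations, gentle on spheres, local", {
  mesh <- icosphere(3, radius = 50)
  expect_identical(taubin_smooth(mesh, iterations = 0)$vertices, mesh$vertices)
  sm <- taubin_smooth(mesh, 0.5, -0.53, 10)
  r0 <- mean(sqrt(rowSums(mesh$vertices^2)))
  r1 <- mean(sqrt(rowSums(sm$vertices^2)))
  expect_lt(abs(r1 - r0) / r0, 0.01)
  expect_identical(sm$triangles, mesh$triangles)

  # two disjoint spheres: each component smooths exactly as it would alone,
  # so neither influences the other
  a <- icosphere(2, 10, center = c(0, 0, 0), surface_id = "A")
  b <- icosphere(2, 10, center = c(100, 0, 0), surface_id = "B")
  both <- surface_mesh(rbind(a$vertices, b$vertices),
                       rbind(a$triangles, b$triangles + nrow(a$vertices)),
                       c(a$surface_id, b$surface_id), fix_orientation = FALSE)
  smb <- taubin_smooth(both, 0.5, -0.53, 5)
  sma <- taubin_smooth(a, 0.5, -0.53, 5)
  smb_alone <- taubin_smooth(b, 0.5, -0.53, 5)
  na <- nrow(a$vertices)
  expect_equal(smb$vertices[seq_len(na), ], sma$vertices, tolerance = 1e-12)
  expect_equal(smb$vertices[-seq_len(na), ], smb_alone$vertices,
               tolerance = 1e-12)
  expect_error(taubin_smooth(mesh, 0.5, -0.4, 1), "stability")
})

test_that("solution interpolation injects parent values and conserves the integral", {
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                       rbind(c(1, 2, 3), c(2, 4, 3)), fix_orientation = FALSE)
  vals <- c(1, 3)
  ref <- barycentric_refine(mesh, c(TRUE, FALSE))
  child <- interpolate_solution(vals, ref$lineage)
  expect_identical(sort(unique(child)), c(1, 3))
  expect_equal(sum(child * ref$area), sum(vals * mesh$area), tolerance = 1e-10)
  expect_identical(sum(child == 1), 4L)
  expect_identical(sum(child == 3), 1L)

  # single refined triangle: all 4 children get the parent value
  one <- barycentric_refine(extract_surface(mesh, "S1"), c(TRUE, TRUE))
  expect_identical(interpolate_solution(c(2, 2), one$lineage), rep(2, 8))
  expect_error(interpolate_solution(c(1), c(1L, 2L)), "parent")
})

test_that("projection onto a reference mesh matches the brute-force kNN oracle", {
  set.seed(42)
  mesh <- icosphere(1, radius = 7)          # 80 triangles
  field <- rnorm(nrow(mesh$triangles))
  # identity: same mesh, k = 1
  expect_identical(project_to_reference(field, mesh, mesh, k = 1), field)
  # constants survive any k
  expect_equal(project_to_reference(rep(3.3, 80), mesh, mesh, k = 7),
               rep(3.3, 80), tolerance = 1e-15)
  # random tie-free fixture vs full-sort oracle (20-triangle soups)
  rmesh <- function(n) surface_mesh(matrix(runif(9 * n), 3 * n, 3),
                                    matrix(seq_len(3 * n), n, byrow = TRUE),
                                    fix_orientation = FALSE)
  fine <- rmesh(20); ref <- rmesh(7)
  fld <- rnorm(20)
  idx <- knn_brute(ref$centroid, fine$centroid, 3)
  oracle <- rowMeans(matrix(fld[idx], nrow(ref$centroid)))
  expect_equal(project_to_reference(fld, fine, ref, k = 3), oracle,
               tolerance = 1e-12)
  expect_error(project_to_reference(fld, fine, ref, k = 21), "exceeds")
})

test_that("point-in-surface agrees with the solid-angle oracle", {
  mesh <- icosphere(2, radius = 1)
  expect_true(points_inside_surface(matrix(0, 1, 3), mesh))
  expect_false(points_inside_surface(matrix(c(2, 0, 0), 1, 3), mesh))
  set.seed(7)
  pts <- matrix(runif(300, -1.5, 1.5), 100, 3)
  expect_identical(as.vector(points_inside_surface(pts, mesh)),
                   as.vector(inside_by_solid_angle(pts, mesh)))
  # open surface is refused with the offending edges named
  open <- surface_mesh(mesh$vertices, mesh$triangles[-1, , drop = FALSE],
                       fix_orientation = FALSE)
  expect_error(points_inside_surface(matrix(0, 1, 3), open), "not closed")
})

test_that("mesh files round-trip through OFF, PLY and STL", {
  mesh <- icosphere(1, radius = 3.5)
  for (ext in c("off", "ply", "stl")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mesh(mesh, f)
    back <- read_mesh(f)
    expect_identical(nrow(back$triangles), nrow(mesh$triangles))
    expect_equal(sum(back$area), sum(mesh$area), tolerance = 1e-6)
    expect_equal(sort(back$vertices[, 1]), sort(mesh$vertices[, 1]),
                 tolerance = 1e-6)
    unlink(f)
  }
})
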
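test_that("surrogate is the area-scaled solution difference", {
  expect_identical(surrogate(c(1, 2), c(1, 2), c(4, 9)), c(0, 0))
  # |T| = 4, p = 3/2, drho = 0.5 -> 4^1.5 * 0.5 = 4
  expect_equal(surrogate(1.5, 1.0, 4, p = 1.5), 4)
  # p = 0 reduces to the raw difference
  expect_equal(surrogate(c(2, 5), c(1, 1), c(7, 11), p = 0), c(1, 4))
  expect_error(surrogate(1, c(1, 2), c(1, 1)), "equal length")
  expect_error(surrogate(1, 1, -1), "positive")
})

test_that("refinement criterion reproduces hand-computed micro-examples", {
  # isolated triangle: local term only, |T| = 1, xi = 1 -> eta = 1
  iso <- surface_mesh(rbind(c(0, 0, 0), c(sqrt(2), 0, 0), c(0, sqrt(2), 0)),
                      matrix(1:3, 1), fix_orientation = FALSE)
  expect_equal(refinement_criterion(1, iso, cutoff = 3), 1, tolerance = 1e-12)

  # two unit-area triangles with centroids 2 mm apart, xi = (1, -1):
  # eta_T = 1 + 0.5 * (1*1/2) * (1 * -1) = 0.75
  s <- sqrt(2)
  two <- surface_mesh(rbind(c(0, 0, 0), c(s, 0, 0), c(0, s, 0),
                            c(0, 0, 2), c(s, 0, 2), c(0, s, 2)),
                      rbind(1:3, 4:6), fix_orientation = FALSE)
  expect_equal(two$area, c(1, 1), tolerance = 1e-12)
  eta <- refinement_criterion(c(1, -1), two, cutoff = 3)
  expect_equal(eta, c(0.75, 0.75), tolerance = 1e-12)
  # cutoff below the pair distance reduces to the local term
  expect_equal(refinement_criterion(c(1, -1), two, cutoff = 1), c(1, 1),
               tolerance = 1e-12)
  # zero surrogate, zero criterion
  expect_identical(refinement_criterion(c(0, 0), two, cutoff = 3), c(0, 0))
})

test_that("criterion is quadratically scale-equivariant and local term nonnegative", {
  set.seed(3)
  mesh <- icosphere(2, radius = 4)
  xi <- rnorm(nrow(mesh$triangles))
  e1 <- refinement_criterion(xi, mesh, cutoff = 3)
  e2 <- refinement_criterion(2.5 * xi, mesh, cutoff = 3)
  expect_equal(e2, 2.5^2 * e1, tolerance = 1e-12)
  local_only <- refinement_criterion(xi, mesh, cutoff = 1e-9)
  expect_true(all(local_only >= 0))
  expect_equal(local_only, mesh$area^1.5 * xi^2, tolerance = 1e-12)
})

test_that("selection flags the ceiling of the fraction with index tie-breaks", {
  eta <- c(5, 1, 4, 2, 3, rep(0, 95))
  fl <- select_refinement_set(eta, 0.05)
  expect_identical(sum(fl), 5L)
  expect_true(all(which(fl) == c(1, 3, 4, 5, 2)[order(c(1, 3, 4, 5, 2))][1:5] |
                  fl[c(1, 2, 3, 4, 5)]))
  expect_identical(which(fl), c(1L, 2L, 3L, 4L, 5L))
  # ceiling convention: N = 10, fraction 0.05 -> 1 flagged
  expect_identical(sum(select_refinement_set(rnorm(10), 0.05)), 1L)
  # ties broken by lowest index
  expect_identical(which(select_refinement_set(rep(1, 100), 0.05)), 1L:5L)
  expect_error(select_refinement_set(1:5, 0), "fraction")
})

test_that("relative residual matches Eq-style hand cases and is homogeneous", {
  expect_identical(relative_residual(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(relative_residual(c(5, 0), c(0, 0)), 100)
  expect_equal(relative_residual(c(1, 0), c(0, 1)), 100 * sqrt(2),
               tolerance = 1e-12)
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(relative_residual(7 * a, 7 * b), relative_residual(a, b),
               tolerance = 1e-12)
  expect_error(relative_residual(numeric(0), numeric(0)), "empty")
  expect_error(relative_residual(c(0, 0), c(1, 1)), "zero")
})

test_that("deep metric gives 50% under solution doubling and rejects empty sets", {
  e <- runif(10) + 1
  expect_equal(deep_field_metric(2 * e, e), 50, tolerance = 1e-12)
  expect_identical(deep_field_metric(e, e), 0)
  expect_error(deep_field_metric(numeric(0), numeric(0)), "empty")
})

test_that("reference-surface metric composes projection and the residual", {
  set.seed(11)
  refm <- icosphere(0, radius = 3)
  fine <- icosphere(1, radius = 3)
  f1 <- rnorm(nrow(fine$triangles))
  f0 <- rnorm(nrow(fine$triangles))
  got <- wm_field_metric(f1, fine, f0, fine, refm, k = 3)
  idx <- knn_brute(refm$centroid, fine$centroid, 3)
  p1 <- rowMeans(matrix(f1[idx], nrow(idx)))
  p0 <- rowMeans(matrix(f0[idx], nrow(idx)))
  expect_equal(got, 100 * sqrt(sum((p1 - p0)^2) / sum(p1^2)),
               tolerance = 1e-12)
  # constant fields survive projection: scaled constants give exact zero
  expect_equal(wm_field_metric(rep(2, 80), fine, rep(2, 80), fine, refm),
               0, tolerance = 1e-15)
})
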
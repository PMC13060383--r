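test_that("conductivity contrast follows the interface formula", {
  expect_identical(contrast(1, 1), 0)
  expect_identical(contrast(1, 0), 1)      # insulating exterior
  expect_equal(contrast(3, 1), 0.5)
  expect_true(all(abs(contrast(runif(50, 0.1, 2), runif(50, 0.1, 2))) <= 1))
  expect_error(contrast(0, 0), "positive")
  expect_error(conductivity_model(1, c(1, 2)), "equal length")
})

test_that("charge matvec is linear, matches the far-field monopole limit", {
  mesh <- icosphere(1, radius = 1)
  m <- nrow(mesh$triangles)
  expect_equal(charge_matvec(rep(0, m), mesh), matrix(0, m, 3),
               tolerance = 1e-15)
  # single source triangle observed far away behaves as a point charge
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) * 2,
                      matrix(1:3, 1), fix_orientation = FALSE)
  p <- matrix(c(60, 10, 30), 1, 3)       # >= 10 source diameters away
  E <- efield_at_points(1.7, tri, p, near_factor = 0)
  r <- (p - tri$centroid) * 1e-3
  d <- sqrt(sum(r^2))
  E_pt <- (tri$area * 1e-6) * 1.7 * r / (4 * pi * d^3)
  expect_lt(sqrt(sum((E - E_pt)^2)) / sqrt(sum(E_pt^2)), 0.01)
})

test_that("treecode and direct backends agree to 1e-6 on a 500-triangle fixture", {
  fx <- make_fixtures(seed = 2, n_cloud = 500)
  pts <- fx$cloud$points
  w <- fx$cloud$weights
  d <- chargebem:::cb_direct_eval(pts, w, pts, seq_len(nrow(pts)) - 1L,
                                  TRUE, TRUE)
  tc <- treecode_options()
  t <- chargebem:::cb_treecode_eval(pts, w, pts, seq_len(nrow(pts)) - 1L,
                                    tc$theta, tc$order, tc$leaf_size,
                                    TRUE, TRUE)
  relf <- sqrt(sum((d$field - t$field)^2)) / sqrt(sum(d$field^2))
  relp <- sqrt(sum((d$potential - t$potential)^2)) / sqrt(sum(d$potential^2))
  expect_lt(relf, 1e-6)
  expect_lt(relp, 1e-6)
})

test_that("single-layer potential obeys Gauss's law on a uniformly charged sphere", {
  mesh <- icosphere(4, radius = 100)      # 100 mm
  m <- nrow(mesh$triangles)
  cvec <- rep(2, m)
  Q <- sum(mesh$area * 1e-6 * cvec)       # scaled total charge
  R <- 0.1
  # exterior potential Q/(4 pi r)
  pts_out <- rbind(c(250, 0, 0), c(0, 180, 0), c(0, 0, -300))
  u_out <- single_layer_potential(cvec, mesh, pts_out)
  r <- sqrt(rowSums(pts_out^2)) * 1e-3
  expect_lt(max(abs(u_out - Q / (4 * pi * r)) / (Q / (4 * pi * r))), 0.01)
  # interior potential is the constant Q/(4 pi R)
  pts_in <- rbind(c(0, 0, 0), c(30, 20, 10), c(-50, 0, 40))
  u_in <- single_layer_potential(cvec, mesh, pts_in)
  expect_lt(max(abs(u_in - Q / (4 * pi * R)) / (Q / (4 * pi * R))), 0.01)
  # interior field is negligible relative to the surface field Q/(4 pi R^2)
  E_in <- efield_at_points(cvec, mesh, pts_in)
  E_surf <- Q / (4 * pi * R^2)
  expect_lt(max(sqrt(rowSums(E_in^2))) / E_surf, 0.01)
})

test_that("near-field analytic integral matches adaptive quadrature to 1e-8", {
  set.seed(9)
  for (k in 1:10) {
    tri <- matrix(rnorm(9), 3, 3)
    scale <- max(dist(tri))
    off <- rnorm(3)
    off <- off / sqrt(sum(off^2)) * runif(1, 0.5, 1.5) * scale
    x <- colMeans(tri) + off      # near field, but off the surface itself
    got <- chargebem:::cb_tri_integral(tri, x)$I
    want <- quad_tri_recursive(tri[1, ], tri[2, ], tri[3, ], x, levels = 7)
    expect_lt(abs(got - want) / abs(want), 1e-8)
  }
})

test_that("second-kind residual vanishes at the fixed point and is affine", {
  # kappa = 0: zero charge solves any drive
  mesh <- icosphere(1, radius = 10)
  m <- nrow(mesh$triangles)
  cond0 <- conductivity_model(rep(1, m), rep(1, m))
  drv <- drive_field(e0 = c(0, 0, 3))
  expect_equal(assemble_second_kind_residual(rep(0, m), mesh, cond0, drv),
               rep(0, m), tolerance = 1e-15)

  # manufactured two-triangle fixed point, hand evaluation of the update
  fx <- make_fixtures(seed = 1)
  two <- fx$two_triangle
  cond <- conductivity_model(c(2, 3), c(1, 1))
  A <- two$area * 1e-6
  X <- two$centroid * 1e-3
  N <- two$normal
  K <- cond$kappa
  E0 <- c(0.2, -0.1, 0.5)
  # solve the 2x2 linear fixed point c = 2 K (G c + n.E0) by hand
  M <- diag(2)
  b <- numeric(2)
  for (t in 1:2) {
    k <- 3 - t
    r <- X[t, ] - X[k, ]
    M[t, k] <- -2 * K[t] * sum(N[t, ] * r) * A[k] / (4 * pi * sum(r^2)^1.5)
    b[t] <- 2 * K[t] * sum(N[t, ] * E0)
  }
  cstar <- solve(M, b)
  res <- assemble_second_kind_residual(cstar, two, cond,
                                       drive_field(e0 = E0))
  expect_lt(max(abs(res)), 1e-12)

  # affine structure: residual(a c) - a residual(c) = (1 - a) * drive term
  set.seed(13)
  cv <- rnorm(m)
  r1 <- assemble_second_kind_residual(cv, mesh,
                                      conductivity_model(rep(2, m), rep(1, m)),
                                      drv)
  ra <- assemble_second_kind_residual(0.3 * cv, mesh,
                                      conductivity_model(rep(2, m), rep(1, m)),
                                      drv)
  bterm <- -assemble_second_kind_residual(rep(0, m), mesh,
                                          conductivity_model(rep(2, m), rep(1, m)),
                                          drv)
  expect_equal(ra - 0.3 * r1, -(1 - 0.3) * bterm, tolerance = 1e-12)
})

test_that("a conducting sphere in a uniform field recovers the cosine charge", {
  mesh <- icosphere(4, radius = 100)
  m <- nrow(mesh$triangles)
  cond <- conductivity_model(rep(2, m), rep(1, m))
  sol <- solve_charges(mesh, cond, drive = drive_field(e0 = c(0, 0, 1)),
                       opts = solver_options(tol = 1e-9, backend = "direct",
                                             near_factor = 4,
                                             preconditioner = "none"))
  ct <- mesh$centroid[, 3] / sqrt(rowSums(mesh$centroid^2))
  exact <- 3 * 1 * ct * (2 - 1) / (2 + 2 * 1)
  err <- max(abs(sol$c - exact)) / max(abs(exact))
  expect_lt(err, 0.03)
})

test_that("solving without sources returns zero immediately", {
  mesh <- icosphere(1, radius = 10)
  m <- nrow(mesh$triangles)
  cond <- conductivity_model(rep(2, m), rep(1, m))
  sol <- solve_charges(mesh, cond)
  expect_identical(sol$c, rep(0, m))
  expect_lte(sol$iterations, 1L)
})

test_that("field evaluation is superposable and the jump relation is exact", {
  mesh <- icosphere(2, radius = 30)
  m <- nrow(mesh$triangles)
  set.seed(17)
  c1 <- rnorm(m); c2 <- rnorm(m)
  pts <- matrix(rnorm(30, sd = 8), 10, 3)
  E12 <- efield_at_points(c1 + c2, mesh, pts)
  expect_equal(E12, efield_at_points(c1, mesh, pts) +
                 efield_at_points(c2, mesh, pts), tolerance = 1e-12)
  # zero charge, uniform drive: n . E = n . E0
  drv <- drive_field(e0 = c(0, 1, 2))
  en <- normal_field_on_surface(rep(0, m), mesh, side = "inner", drive = drv)
  expect_equal(en, as.vector(mesh$normal %*% c(0, 1, 2)), tolerance = 1e-12)
  # outer minus inner equals the sheet density exactly
  eo <- normal_field_on_surface(c1, mesh, side = "outer")
  ei <- normal_field_on_surface(c1, mesh, side = "inner")
  expect_equal(eo - ei, c1, tolerance = 1e-12)
  # uniformly charged sphere at adequate resolution:
  # inner ~ 0, outer ~ Q/(4 pi R^2)
  gm <- icosphere(4, radius = 30)
  cu <- rep(1, nrow(gm$triangles))
  Q <- sum(gm$area * 1e-6)
  Es <- Q / (4 * pi * 0.03^2)
  eo_u <- normal_field_on_surface(cu, gm, side = "outer")
  ei_u <- normal_field_on_surface(cu, gm, side = "inner")
  expect_lt(max(abs(eo_u - Es)) / Es, 0.02)
  expect_lt(max(abs(ei_u)) / Es, 0.02)
})

test_that("GMRES solves a random well-conditioned system matrix-free", {
  set.seed(23)
  n <- 60
  A <- diag(n) + 0.1 * matrix(rnorm(n * n), n) / sqrt(n)
  xstar <- rnorm(n)
  b <- A %*% xstar
  out <- gmres_solve(function(x) A %*% x, as.vector(b), tol = 1e-12)
  expect_true(out$converged)
  expect_lt(max(abs(out$x - xstar)), 1e-9)
  z <- gmres_solve(function(x) A %*% x, rep(0, n))
  expect_identical(z$iterations, 0L)
  expect_identical(z$x, rep(0, n))
})
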
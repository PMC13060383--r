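# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's computational kernels: plain R, direct enumeration.

# solid angle of triangle (A,B,C) seen from x (van Oosterom & Strackee)
solid_angle_tri <- function(A, B, C, x) {
  r1 <- A - x; r2 <- B - x; r3 <- C - x
  n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2)); n3 <- sqrt(sum(r3^2))
  det <- r1[1] * (r2[2] * r3[3] - r2[3] * r3[2]) -
         r1[2] * (r2[1] * r3[3] - r2[3] * r3[1]) +
         r1[3] * (r2[1] * r3[2] - r2[2] * r3[1])
  den <- n1 * n2 * n3 + sum(r1 * r2) * n3 + sum(r1 * r3) * n2 +
         sum(r2 * r3) * n1
  2 * atan2(det, den)
}

# winding-number point classification by total solid angle
inside_by_solid_angle <- function(points, mesh) {
  apply(points, 1, function(x) {
    om <- 0
    f <- mesh$triangles
    for (i in seq_len(nrow(f))) {
      om <- om + solid_angle_tri(mesh$vertices[f[i, 1], ],
                                 mesh$vertices[f[i, 2], ],
                                 mesh$vertices[f[i, 3], ], x)
    }
    abs(om) > 2 * pi
  })
}

# degree-5 symmetric triangle quadrature over 4^L exact subtriangles
quad_tri_recursive <- function(A, B, C, x, levels = 5) {
  w <- c(0.225, rep(0.1323941527885062, 3), rep(0.1259391805448271, 3))
  a <- 0.0597158717897698; b <- 0.4701420641051151
  cc <- 0.7974269853530873; d <- 0.1012865073234563
  bary <- rbind(c(1/3, 1/3, 1/3),
                c(a, b, b), c(b, a, b), c(b, b, a),
                c(cc, d, d), c(d, cc, d), c(d, d, cc))
  tris <- list(rbind(A, B, C))
  for (l in seq_len(levels)) {
    nt <- vector("list", 4 * length(tris))
    k <- 0
    for (t in tris) {
      ab <- (t[1, ] + t[2, ]) / 2; bc <- (t[2, ] + t[3, ]) / 2
      ca <- (t[3, ] + t[1, ]) / 2
      nt[[k + 1]] <- rbind(t[1, ], ab, ca)
      nt[[k + 2]] <- rbind(ab, t[2, ], bc)
      nt[[k + 3]] <- rbind(ca, bc, t[3, ])
      nt[[k + 4]] <- rbind(ab, bc, ca)
      k <- k + 4
    }
    tris <- nt
  }
  tot <- 0
  for (t in tris) {
    e1 <- t[2, ] - t[1, ]; e2 <- t[3, ] - t[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    ar <- 0.5 * sqrt(sum(cr^2))
    P <- bary %*% t
    dist <- sqrt(rowSums((P - matrix(x, 7, 3, byrow = TRUE))^2))
    tot <- tot + ar * sum(w / dist)
  }
  tot
}

# self potential integral int_T 1/|x-y| dS for x strictly inside the
# triangle plane region: split into three vertex-singular triangles at x and
# integrate the polar radius over angle with 1D adaptive quadrature
self_potential_polar <- function(A, B, C, x) {
  e1 <- B - A; e2 <- C - A
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  u <- e1 / sqrt(sum(e1^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  to2d <- function(p) c(sum((p - x) * u), sum((p - x) * v))
  verts <- list(to2d(A), to2d(B), to2d(C))
  tot <- 0
  for (i in 1:3) {
    a <- verts[[i]]; b <- verts[[i %% 3 + 1]]
    ta <- atan2(a[2], a[1]); tb <- atan2(b[2], b[1])
    dt <- tb - ta
    if (dt <= -pi) dt <- dt + 2 * pi
    if (dt > pi) dt <- dt - 2 * pi
    nline <- c(-(b[2] - a[2]), b[1] - a[1])
    rho <- function(th) {
      uu <- cbind(cos(ta + th), sin(ta + th))
      sum(nline * a) / (uu %*% nline)
    }
    tot <- tot + stats::integrate(function(th) vapply(th, rho, numeric(1)),
                                  0, dt, rel.tol = 1e-12)$value
  }
  tot
}

# brute-force k nearest neighbors by full sort
knn_brute <- function(query, pts, k) {
  t(apply(query, 1, function(q) {
    order(colSums((t(pts) - q)^2))[seq_len(k)]
  }))
}

# two-electrode descriptions for the sphere benchmark
sphere_electrodes <- function(R = 92, radius = 20, kind = "voltage",
                              value = 1) {
  list(list(name = "anode", center = c(0, 0, R), radius = radius,
            kind = kind, value = value),
       list(name = "cathode", center = c(0, 0, -R), radius = radius,
            kind = kind, value = -value))
}

# rotationally symmetric flat disc mesh: nr rings x na azimuthal steps;
# the global twist keeps centroid angles away from the quadrant rays
disc_mesh <- function(R = 20, nr = 5, na = 16, twist = 0.2347) {
  verts <- matrix(0, 1 + nr * na, 3)
  for (i in seq_len(nr))
    for (j in seq_len(na)) {
      th <- 2 * pi * (j - 1) / na + twist +
        0.3 / na * sin(7.1 * i + 13.3 * j)   # break angle classes
      verts[1 + (i - 1) * na + j, ] <- c(R * i / nr * cos(th),
                                         R * i / nr * sin(th), 0)
    }
  vid <- function(i, j) 1 + (i - 1) * na + ((j - 1) %% na) + 1
  tris <- NULL
  for (j in seq_len(na)) tris <- rbind(tris, c(1, vid(1, j), vid(1, j + 1)))
  for (i in seq_len(nr - 1))
    for (j in seq_len(na)) {
      tris <- rbind(tris,
                    c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                    c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
    }
  surface_mesh(verts, tris, surface_id = "D", fix_orientation = FALSE)
}

# small flat fan fixture: three triangles sharing one edge
three_fan_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1)),
               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)),
               surface_id = "F", fix_orientation = FALSE)
}
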
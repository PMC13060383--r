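#' Impressed drive field
#'
#' The primary electric field present before interface charges respond.
#' Two ingredients, both optional: a uniform background field `e0` (used by
#' analytic benchmark cases) and an impressed surface source layer `gamma`
#' (V/m per triangle; the sponge-electrode current injection), whose field
#' is evaluated with the same Coulomb kernels as the induced charge.
#'
#' @param e0 length-3 uniform field (V/m).
#' @param gamma optional per-triangle impressed layer density (V/m).
#' @return object of class `drive_field`.
#' @export
drive_field <- function(e0 = c(0, 0, 0), gamma = NULL) {
  structure(list(e0 = as.numeric(e0), gamma = gamma), class = "drive_field")
}

# impressed field at arbitrary points (mm); exclude_self gives, for targets
# that are triangle centroids, the triangle index whose own layer term must
# be excluded (principal value).
drive_field_at <- function(drive, mesh, points, exclude_self = NULL,
                           backend = "direct", tc = treecode_options()) {
  pts <- as.matrix(points)
  E <- matrix(drive$e0, nrow(pts), 3, byrow = TRUE)
  if (!is.null(drive$gamma) && any(drive$gamma != 0)) {
    si <- mesh_si(mesh)
    excl <- if (is.null(exclude_self)) rep(-1L, nrow(pts)) else
      as.integer(exclude_self) - 1L
    E <- E + backend_eval(si$cent, si$area * drive$gamma, pts * MM, excl,
                          backend, want_pot = FALSE, want_field = TRUE,
                          tc = tc)$field
  }
  E
}

#' Electrode set
#'
#' Builds electrode patches (triangle subsets of the outer skin surface)
#' from a list of electrode descriptions, assigns sector labels for the
#' block preconditioner and validates the drive: voltage electrodes carry a
#' potential in volts, current electrodes a signed injected current in
#' amperes which must sum to zero across the set.
#'
#' @param mesh a [surface_mesh()].
#' @param electrodes list of `list(name, center, radius, kind, value)` with
#'   `center` in mm, `kind` one of `"voltage"`, `"current"`.
#' @param surface surface to place patches on (default: outermost).
#' @param sectors sector count `d` per electrode; default
#'   `max(1, ceiling(Ne / 3000))` so each preconditioner block stays within
#'   a dense-factorization budget.
#' @return object of class `electrode_set`: per-electrode `patch` (triangle
#'   indices), `sector` (labels in 0..d-1), `kind`, `value`, `name`.
#' @export
electrode_set <- function(mesh, electrodes, surface = NULL, sectors = NULL) {
  if (is.null(surface)) surface <- outer_surface_id(mesh)
  kinds <- vapply(electrodes, `[[`, character(1), "kind")
  if (!all(kinds %in% c("voltage", "current")))
    stop("electrode kind must be 'voltage' or 'current'")
  if (length(unique(kinds)) > 1)
    stop("mixed voltage and current electrodes are not supported")
  if (kinds[1] == "current") {
    tot <- sum(vapply(electrodes, `[[`, numeric(1), "value"))
    if (abs(tot) > 1e-12 * max(abs(vapply(electrodes, `[[`, numeric(1), "value"))))
      stop("injected currents must sum to zero across electrodes")
  }
  els <- lapply(electrodes, function(e) {
    patch <- select_electrode_patch(mesh, e$center, e$radius, surface)
    d <- if (is.null(sectors)) max(1L, ceiling(length(patch) / 3000)) else sectors
    sec <- sector_electrode(mesh, patch, d, center = e$center)
    list(name = e$name, center = e$center, radius = e$radius,
         kind = e$kind, value = e$value, patch = patch, sector = sec, d = d)
  })
  pp <- unlist(lapply(els, `[[`, "patch"))
  if (anyDuplicated(pp)) stop("electrode patches overlap")
  structure(list(electrodes = els, kind = kinds[1], surface = surface),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("electrode_set (%s) on %s:\n", x$kind, x$surface))
  for (e in x$electrodes)
    cat(sprintf("  %s: %d triangles, radius %.1f mm, value %g, %d sector(s)\n",
                e$name, length(e$patch), e$radius, e$value, e$d))
  invisible(x)
}

electrode_triangles <- function(eset) {
  unlist(lapply(eset$electrodes, `[[`, "patch"))
}

#' Tangent-plane sectoring of an electrode patch
#'
#' Partitions an electrode patch into `d` angular sectors: a local tangent
#' plane is built at the triangle nearest the electrode center, all patch
#' centroids are projected into the plane, and `d` evenly spaced rays from
#' the origin cut the plane into equal angular sectors; each triangle is
#' labeled with the sector its projection lands in. For a rotationally
#' symmetric patch this distributes triangles approximately evenly.
#'
#' @param mesh a [surface_mesh()].
#' @param patch integer vector of patch triangle indices.
#' @param d sector count (`1 <= d <= length(patch)`).
#' @param center electrode center (mm); default: mean of patch centroids.
#' @return integer vector of sector labels in `0..d-1`, one per patch
#'   triangle.
#' @export
sector_electrode <- function(mesh, patch, d, center = NULL) {
  n <- length(patch)
  d <- as.integer(d)
  if (d < 1) stop("d must be >= 1")
  if (d > n) stop(sprintf("d = %d exceeds the patch size (%d)", d, n))
  if (d == 1) return(rep(0L, n))
  cent <- mesh$centroid[patch, , drop = FALSE]
  if (is.null(center)) center <- colMeans(cent)
  near <- which.min(rowSums((cent - matrix(center, n, 3, byrow = TRUE))^2))
  origin <- cent[near, ]
  nrm <- mesh$normal[patch[near], ]
  # orthonormal in-plane basis
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  rel <- cent - matrix(origin, n, 3, byrow = TRUE)
  ang <- atan2(rel %*% e2, rel %*% e1)   # (-pi, pi]
  lab <- as.integer(floor((as.vector(ang) + pi) / (2 * pi) * d))
  lab[lab >= d] <- d - 1L                 # guard the ang == pi boundary
  lab
}

#' Sponge (current) electrode drive
#'
#' Idealizes each current electrode as a uniform impressed surface source
#' layer over its patch: layer density `I_e / (A_e sigma_skin)` in field
#' units, whose Coulomb field is the impressed field the charge equation
#' sees. No Dirichlet rows are involved; the injected currents must sum to
#' zero.
#'
#' @param mesh a [surface_mesh()].
#' @param eset an [electrode_set()] of kind `"current"`.
#' @param sigma_skin skin conductivity (S/m) used to convert current
#'   density to field units; default: taken from `conductivity` on the
#'   patch triangles.
#' @param conductivity optional [conductivity_model()] supplying
#'   `sigma_skin` (its `sigma_in` on the patch).
#' @return a [drive_field()] with the patch layer in `gamma`.
#' @export
current_drive <- function(mesh, eset, sigma_skin = NULL, conductivity = NULL) {
  if (eset$kind != "current") stop("electrode set is not current-driven")
  m <- nrow(mesh$triangles)
  gamma <- rep(0, m)
  for (e in eset$electrodes) {
    if (is.null(sigma_skin)) {
      if (is.null(conductivity))
        stop("supply sigma_skin or a conductivity model")
      sk <- unique(conductivity$sigma_in[e$patch])
      if (length(sk) != 1) stop("patch spans several conductivities")
      sigma_e <- sk
    } else sigma_e <- sigma_skin
    A_m2 <- sum(mesh$area[e$patch]) * MM^2
    gamma[e$patch] <- e$value / (A_m2 * sigma_e)
  }
  drive_field(gamma = gamma)
}

#' Electrode currents from a charge solution
#'
#' Total current through each electrode patch, by summing the normal
#' current flux over the patch triangles on the skin (inner) side:
#' `I_e = -sum_T sigma_in (n . E_inner) |T|`. The sign convention makes
#' current flowing into the head positive.
#'
#' @param solution a `charge_solution` from [solve_charges()], or a plain
#'   scaled-charge vector.
#' @param mesh a [surface_mesh()].
#' @param eset an [electrode_set()].
#' @param conductivity a [conductivity_model()] for the mesh.
#' @param drive optional [drive_field()] used in the solve (needed for
#'   current electrodes so the impressed layer's flux is counted).
#' @param near_factor,backend,tc see [single_layer_potential()].
#' @return named numeric vector of per-electrode currents (A).
#' @export
electrode_current <- function(solution, mesh, eset, conductivity,
                              drive = NULL, near_factor = 4,
                              backend = "direct", tc = treecode_options()) {
  c_scaled <- if (inherits(solution, "charge_solution")) solution$c else solution
  tri <- unlist(lapply(eset$electrodes, `[[`, "patch"))
  en <- normal_field_on_surface(c_scaled, mesh, side = "inner", drive = drive,
                                subset = tri, near_factor = near_factor,
                                backend = backend, tc = tc)
  lens <- vapply(eset$electrodes, function(e) length(e$patch), integer(1))
  grp <- rep(seq_along(eset$electrodes), lens)
  flux <- -conductivity$sigma_in[tri] * en * mesh$area[tri] * MM^2
  out <- as.vector(rowsum(flux, grp))
  names(out) <- vapply(eset$electrodes, `[[`, character(1), "name")
  out
}

#' Effective DC resistance of an electrode pair
#'
#' Ohm's law on the solved model: for voltage drive, the applied potential
#' difference over the recovered current; for current drive, the measured
#' mean patch potential difference over the applied current.
#'
#' @param solution a `charge_solution` (or scaled-charge vector).
#' @param mesh a [surface_mesh()].
#' @param eset an [electrode_set()] with exactly two electrodes.
#' @param conductivity a [conductivity_model()].
#' @param drive optional [drive_field()] used in the solve.
#' @param near_factor,backend,tc see [single_layer_potential()].
#' @return resistance in ohms.
#' @export
effective_resistance <- function(solution, mesh, eset, conductivity,
                                 drive = NULL, near_factor = 4,
                                 backend = "direct", tc = treecode_options()) {
  if (length(eset$electrodes) != 2)
    stop("effective resistance is defined for an electrode pair")
  c_scaled <- if (inherits(solution, "charge_solution")) solution$c else solution
  I <- electrode_current(solution, mesh, eset, conductivity, drive = drive,
                         near_factor = near_factor, backend = backend, tc = tc)
  vals <- vapply(eset$electrodes, `[[`, numeric(1), "value")
  if (eset$kind == "voltage") {
    dV <- vals[1] - vals[2]
    Iuse <- I[1]
  } else {
    u <- single_layer_potential(c_scaled, mesh, near_factor = near_factor,
                                backend = backend, tc = tc)
    mu <- vapply(eset$electrodes, function(e) mean(u[e$patch]), numeric(1))
    dV <- mu[1] - mu[2]
    Iuse <- vals[1]
  }
  if (abs(Iuse) < .Machine$double.eps)
    stop("zero electrode current; resistance undefined")
  unname(abs(dV / Iuse))
}
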
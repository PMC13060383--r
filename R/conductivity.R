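#' Conductivity contrast at a tissue interface
#'
#' The driver of induced surface charge at a conductivity jump:
#' `kappa = (sigma_in - sigma_out) / (sigma_in + sigma_out)`, always in
#' \[-1, 1\]. An insulating exterior (`sigma_out = 0`) gives `kappa = 1`.
#'
#' @param sigma_in inner conductivity (S/m), vectorized.
#' @param sigma_out outer conductivity (S/m), vectorized.
#' @return numeric vector of contrasts.
#' @export
contrast <- function(sigma_in, sigma_out) {
  s <- sigma_in + sigma_out
  if (any(s <= 0)) stop("sigma_in + sigma_out must be positive")
  (sigma_in - sigma_out) / s
}

#' Per-triangle conductivity model
#'
#' @param sigma_in per-triangle inner conductivity (S/m).
#' @param sigma_out per-triangle outer conductivity (S/m).
#' @return object of class `conductivity_model` with elements `sigma_in`,
#'   `sigma_out`, `kappa`.
#' @export
conductivity_model <- function(sigma_in, sigma_out) {
  if (length(sigma_in) != length(sigma_out))
    stop("sigma_in and sigma_out must have equal length")
  structure(list(sigma_in = sigma_in, sigma_out = sigma_out,
                 kappa = contrast(sigma_in, sigma_out)),
            class = "conductivity_model")
}

#' Bundle a mesh with per-surface conductivities
#'
#' The layer table assigns inner/outer conductivities per surface label;
#' [triangle_conductivity()] expands it to the per-triangle
#' [conductivity_model()] the solver consumes, which keeps the table valid
#' across mesh refinement (children inherit their surface label).
#'
#' @param mesh a [surface_mesh()].
#' @param layers data frame with columns `surface`, `sigma_in`, `sigma_out`.
#' @return object of class `bem_model`.
#' @export
bem_model <- function(mesh, layers) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!all(c("surface", "sigma_in", "sigma_out") %in% names(layers)))
    stop("layers needs columns surface, sigma_in, sigma_out")
  missing <- setdiff(unique(mesh$surface_id), layers$surface)
  if (length(missing))
    stop(sprintf("no conductivities for surface(s): %s",
                 paste(missing, collapse = ", ")))
  structure(list(mesh = mesh, layers = layers), class = "bem_model")
}

#' @rdname bem_model
#' @param model a `bem_model`.
#' @export
triangle_conductivity <- function(model) {
  i <- match(model$mesh$surface_id, model$layers$surface)
  conductivity_model(model$layers$sigma_in[i], model$layers$sigma_out[i])
}

#' @export
print.bem_model <- function(x, ...) {
  cat("bem_model\n")
  print(x$mesh)
  print(x$layers, row.names = FALSE)
  invisible(x)
}
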
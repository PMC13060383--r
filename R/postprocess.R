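#' Relative residual between consecutive-pass quantities
#'
#' `R = 100 * ||f_l - f_{l-1}||_2 / ||f_l||_2` in percent; the convergence
#' metric tracked for electrode currents, projected normal fields and
#' deep-target field magnitudes. Homogeneous of degree zero: scaling both
#' vectors leaves it unchanged.
#'
#' @param f_l quantity at the current pass.
#' @param f_lm1 quantity at the previous pass (same length).
#' @return percent residual (scalar).
#' @export
relative_residual <- function(f_l, f_lm1) {
  if (length(f_l) != length(f_lm1))
    stop("f_l and f_lm1 must have equal length")
  if (!length(f_l)) stop("empty quantity vectors")
  nl <- sqrt(sum(f_l^2))
  if (nl == 0) stop("||f_l|| is zero; relative residual undefined")
  100 * sqrt(sum((f_l - f_lm1)^2)) / nl
}

#' Reference-surface normal-field convergence metric
#'
#' Projects the per-triangle normal fields of two consecutive passes onto
#' the fixed reference mesh (k-nearest-neighbor averaging of centroids) and
#' applies the relative residual. Constant fields survive the averaging
#' exactly, so identical or uniformly scaled solutions give 0.
#'
#' @param field_l,mesh_l current-pass per-triangle values and their mesh.
#' @param field_lm1,mesh_lm1 previous-pass values and mesh.
#' @param reference_mesh the fixed reference [surface_mesh()].
#' @param k neighbor count for the projection.
#' @return percent residual.
#' @export
wm_field_metric <- function(field_l, mesh_l, field_lm1, mesh_lm1,
                            reference_mesh, k = 3) {
  fl <- project_to_reference(field_l, mesh_l, reference_mesh, k)
  fp <- project_to_reference(field_lm1, mesh_lm1, reference_mesh, k)
  relative_residual(fl, fp)
}

#' Deep-target field-magnitude convergence metric
#'
#' The relative residual of the volumetric field magnitudes at a fixed set
#' of deep target points across two passes. The target points must be
#' identical between passes (they are fixed at pass 0).
#'
#' @param e_l,e_lm1 per-point field magnitudes at the two passes.
#' @return percent residual.
#' @export
deep_field_metric <- function(e_l, e_lm1) {
  if (!length(e_l)) stop("empty target set")
  relative_residual(e_l, e_lm1)
}

#' Convergence report table
#'
#' One row per adaptive pass with triangle counts, electrode currents,
#' tracked relative residuals and the relative model size
#' (triangles at pass l over triangles at pass 0; exactly 4 at pass 1
#' after a uniform first refinement).
#'
#' @param run a `bem_amr_run` from [run_amr()].
#' @return data frame of per-pass records.
#' @export
convergence_report <- function(run) {
  stopifnot(inherits(run, "bem_amr_run"))
  run$records
}

#' Write / read a convergence report as CSV
#'
#' @param run a `bem_amr_run` (or its records data frame).
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_report <- function(run, path) {
  df <- if (inherits(run, "bem_amr_run")) run$records else run
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.csv(path)
}

#' Plot convergence against relative model size
#'
#' Log-log plot of the tracked relative residuals (percent) against the
#' relative model size, the standard way to compare adaptive refinement
#' runs across models.
#'
#' @param x a `bem_amr_run`.
#' @param ... passed to [graphics::matplot()].
#' @return `x` invisibly.
#' @export
plot.bem_amr_run <- function(x, ...) {
  df <- x$records
  keep <- !is.na(df$R_wm_pct) | !is.na(df$R_deep_pct)
  if (!any(keep)) {
    warning("no residual records to plot")
    return(invisible(x))
  }
  matplot(df$relative_model_size[keep],
          cbind(df$R_wm_pct[keep], df$R_deep_pct[keep]),
          type = "b", pch = c(1, 2), lty = 1, log = "xy",
          xlab = "relative model size N_l / N_0",
          ylab = "relative residual [%]", ...)
  legend("topright", legend = c("reference surface n.E", "deep |E|"),
         pch = c(1, 2), lty = 1, col = 1:2, bty = "n")
  invisible(x)
}
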
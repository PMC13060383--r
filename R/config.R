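#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent nested list), fills
#' in defaults, range-checks every setting and reports all violations at
#' once. The physics pipeline is fully deterministic; the `seed` only
#' affects randomized fixtures.
#'
#' @param config path to a YAML file, or a nested list.
#' @return the defaulted, validated configuration (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    model = list(type = "sphere",
                 radii = c(92, 86, 80, 78, 75),
                 electrode_radius = 20,
                 subdivision = 4,
                 deep_structure_radius = 50,
                 grid_spacing = 2.5,
                 conductivities = c(0.333, 0.0066, 1.654, 0.275, 0.126)),
    electrodes = list(kind = "voltage", value = 1),
    solver = list(tol = 1e-9, max_iter = 300, restart = 40,
                  backend = "auto", near_factor = 4,
                  preconditioner = "sector",
                  treecode = list(theta = 0.25, order = 8, leaf_size = 32)),
    amr = list(p = 1.5, fraction = 0.05, cutoff_mm = 3, max_passes = 5,
               max_triangles = Inf, first_pass = "uniform",
               r_threshold_pct = 0.1, k_project = 3),
    output = list(dir = "chargebem-run"),
    seed = 1L)
  known <- names(defaults)
  extra <- setdiff(names(config), known)
  problems <- character(0)
  if (length(extra))
    problems <- c(problems, sprintf("unknown top-level key(s): %s",
                                    paste(extra, collapse = ", ")))
  optional <- list(model = "manifest", electrodes = c("radius", "file"))
  for (sec in intersect(names(config), known)) {
    if (is.list(defaults[[sec]]) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]),
                     c(names(defaults[[sec]]), optional[[sec]]))
      if (length(bad))
        problems <- c(problems, sprintf("unknown key(s) in '%s': %s", sec,
                                        paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, config[intersect(names(config), known)])
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$model$type %in% c("sphere", "manifest"),
      "model.type must be 'sphere' or 'manifest'")
  if (cfg$model$type == "sphere") {
    chk(length(cfg$model$radii) == 5 && all(diff(cfg$model$radii) < 0),
        "model.radii must be 5 strictly decreasing values")
    chk(cfg$model$subdivision >= 0, "model.subdivision must be >= 0")
    chk(cfg$model$grid_spacing > 0, "model.grid_spacing must be positive")
  } else {
    chk(!is.null(cfg$model$manifest), "model.manifest path required")
  }
  chk(cfg$electrodes$kind %in% c("voltage", "current"),
      "electrodes.kind must be 'voltage' or 'current'")
  chk(cfg$solver$tol > 0 && cfg$solver$tol < 1,
      "solver.tol must be in (0, 1)")
  chk(cfg$solver$max_iter >= 1, "solver.max_iter must be >= 1")
  chk(cfg$solver$backend %in% c("auto", "direct", "treecode"),
      "solver.backend must be auto|direct|treecode")
  chk(cfg$solver$near_factor >= 0, "solver.near_factor must be >= 0")
  chk(cfg$solver$preconditioner %in% c("sector", "none"),
      "solver.preconditioner must be sector|none")
  chk(cfg$amr$fraction > 0 && cfg$amr$fraction <= 1,
      "amr.fraction must be in (0, 1]")
  chk(cfg$amr$p >= 0, "amr.p must be >= 0")
  chk(cfg$amr$cutoff_mm > 0, "amr.cutoff_mm must be positive")
  chk(cfg$amr$first_pass %in% c("uniform", "surrogate0"),
      "amr.first_pass must be uniform|surrogate0")
  chk(cfg$amr$max_passes >= 0, "amr.max_passes must be >= 0")
  if (length(problems))
    stop(paste(c("invalid configuration:", paste(" -", problems)),
               collapse = "\n"))
  structure(cfg, class = "run_config")
}

#' Write a configuration as YAML
#'
#' @param cfg a `run_config` (or plain list).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$amr$max_triangles <- if (is.finite(cfg$amr$max_triangles))
    cfg$amr$max_triangles else .Machine$integer.max
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full forward-modeling pipeline
#'
#' Builds (or loads) the model, places the electrodes, runs the adaptive
#' refinement loop and writes per-run artifacts: the convergence report
#' CSV, a run-metadata JSON, the final mesh and charge solution. The
#' physics path contains no randomness, so identical configurations give
#' identical outputs.
#'
#' @param config a `run_config` from [validate_config()] (or a path /
#'   list accepted by it).
#' @param progress print per-pass summaries.
#' @return the `bem_amr_run`, invisibly; artifacts under
#'   `config$output$dir`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (cfg$model$type == "sphere") {
    spec <- sphere_model_spec(
      radii = cfg$model$radii,
      electrode_radius = cfg$model$electrode_radius,
      deep_structure_radius = cfg$model$deep_structure_radius,
      grid_spacing = cfg$model$grid_spacing,
      subdivision = cfg$model$subdivision,
      conductivities = cfg$model$conductivities)
    model <- build_sphere_model(spec)
    deep <- make_deep_structure_points(spec)$points
    erad <- if (is.null(cfg$electrodes$radius)) spec$electrode_radius
            else cfg$electrodes$radius
    R1 <- cfg$model$radii[1]
    electrodes <- list(
      list(name = "anode", center = c(0, 0, R1), radius = erad,
           kind = cfg$electrodes$kind, value = cfg$electrodes$value),
      list(name = "cathode", center = c(0, 0, -R1), radius = erad,
           kind = cfg$electrodes$kind, value = -cfg$electrodes$value))
  } else {
    model <- read_model_manifest(cfg$model$manifest)
    deep <- NULL
    electrodes <- lapply(jsonlite::read_json(cfg$electrodes$file),
                         function(e) list(name = e$name,
                                          center = unlist(e$center_mm),
                                          radius = e$radius_mm,
                                          kind = e$kind, value = e$value))
  }
  opts <- solver_options(tol = cfg$solver$tol, max_iter = cfg$solver$max_iter,
                         restart = cfg$solver$restart,
                         backend = cfg$solver$backend,
                         near_factor = cfg$solver$near_factor,
                         preconditioner = cfg$solver$preconditioner,
                         tc = do.call(treecode_options, cfg$solver$treecode))
  acfg <- amr_config(p = cfg$amr$p, fraction = cfg$amr$fraction,
                     nonlocal_cutoff = cfg$amr$cutoff_mm,
                     max_passes = cfg$amr$max_passes,
                     max_triangles = cfg$amr$max_triangles,
                     first_pass = cfg$amr$first_pass,
                     r_threshold = cfg$amr$r_threshold_pct,
                     k_project = cfg$amr$k_project)
  run <- run_amr(model, electrodes, config = acfg, opts = opts,
                 deep_points = deep, progress = progress)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  write_report(run, file.path(cfg$output$dir, "report.csv"))
  final <- run$states[[length(run$states)]]
  write_mesh_multi(final$mesh, file.path(cfg$output$dir, "final_mesh.off"))
  write.csv(data.frame(triangle = seq_along(final$solution$c),
                       surface = final$mesh$surface_id,
                       c_scaled_Vm = final$solution$c),
            file.path(cfg$output$dir, "final_solution.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(passes = nrow(run$records),
         final_triangles = nrow(final$mesh$triangles),
         gmres_iterations = final$solution$iterations,
         converged = final$solution$converged),
    file.path(cfg$output$dir, "run.json"), auto_unbox = TRUE)
  invisible(run)
}

# single-file OFF dump of a multi-surface mesh (labels dropped)
write_mesh_multi <- function(mesh, path) {
  write_off(mesh, path)
}

#' Deterministic test fixtures
#'
#' Small models used across the test-suite and benchmark scripts: a
#' two-triangle charge system, a random point cloud for backend
#' equivalence checks, a single conducting sphere in a uniform field, and
#' a reduced 5-layer sphere model. All randomness is driven by the seed.
#'
#' @param seed integer seed.
#' @param n_cloud size of the random cloud fixture.
#' @param subdivision subdivision of the reduced 5-layer model.
#' @return named list of fixtures.
#' @export
make_fixtures <- function(seed = 1, n_cloud = 500, subdivision = 3) {
  set.seed(seed)
  two_tri <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(3, 0, 1), c(4, 0, 1),
          c(3, 1, 1)),
    rbind(c(1, 2, 3), c(4, 5, 6)),
    surface_id = c("A", "B"), fix_orientation = FALSE)
  cloud <- list(points = matrix(stats::rnorm(n_cloud * 3), n_cloud, 3) * 40,
                weights = stats::runif(n_cloud, -1, 1))
  sphere <- icosphere(4, radius = 10, surface_id = "S")
  mini_spec <- sphere_model_spec(subdivision = subdivision, grid_spacing = 10)
  mini <- suppressWarnings(build_sphere_model(mini_spec))
  list(two_triangle = two_tri, cloud = cloud,
       single_sphere = sphere,
       single_sphere_conductivity = conductivity_model(
         rep(2, nrow(sphere$triangles)), rep(1, nrow(sphere$triangles))),
       mini_model = mini, mini_spec = mini_spec, seed = seed)
}
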
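#' Default run configuration
#'
#' Declarative description of a run: physical parameters (defaults are the
#' reference values `J_EPI = J_TE = 2.5`, `lambda_med = lambda_chi = 2`,
#' `rho = 1`, `R = 0.5`, `h = 2`, `d = 0.5`, `R_lum = 0.25`), the scenario
#' preset and schedule, the metric sampling interval and the output block.
#' Configurations round-trip losslessly through YAML.
#'
#' @param scenario scenario preset name (see [implantation_scenario()]) or
#'   `"stress-strain"`.
#' @param ... overrides merged into the default configuration.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(scenario = "implantation", ...) {
  cfg <- list(
    params = list(J_TE = 2.5, J_EPI = 2.5, rho = 1,
                  lambda_med = 2, lambda_chi = 2,
                  dt = 0.005, force_cap_mult = 10,
                  adhesion_cutoff = 0.2, max_links = 1, refresh_every = 10),
    cell = list(R = 0.5, h = 2, n_vertices = 34, d = 0.5, R_lum = 0.25),
    scenario = list(kind = scenario,
                    te_rows = 5, te_cols = 5,
                    rosette_grid = 3, rosette_layers = 2),
    metrics = list(sample_every = 500),
    output = list(dir = "epimech-out", format = "vtk")
  )
  over <- list(...)
  if (length(over)) cfg <- modifyList(cfg, over)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("params", "scenario", "output")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("invalid config: missing required field(s): ",
         paste(missing, collapse = ", "))
  base <- unclass(run_config())
  cfg <- modifyList(base, cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#' @param cfg a `run_config`.
#' @param path destination file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.params_from_config <- function(cfg) {
  do.call(sim_params, cfg$params)
}

#' Execute a configured run
#'
#' Runs the configured scenario (or the stress-strain protocol), writing a
#' metric CSV, mesh snapshots, a provenance JSON (configuration, package
#' version, wall time) and a plain-text log into the output directory.
#' Reruns of the same configuration produce identical metric files.
#'
#' @param config a `run_config` or path to a YAML file.
#' @return (invisibly) the run result.
#' @export
run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  params <- .params_from_config(config)
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output$dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("run started: scenario '%s'", config$scenario$kind)
  if (config$scenario$kind == "stress-strain") {
    spec <- cell_shape_spec(R = config$cell$R, h = config$cell$h,
                            n_vertices = config$cell$n_vertices)
    res <- stress_strain_protocol(spec, params)
    write.csv(data.frame(force = res$force, stress = res$stress,
                         strain = res$strain),
              file.path(config$output$dir, "stress_strain.csv"),
              row.names = FALSE)
    logline("fitted Y = %.4f (R = %.4f)", res$Y, res$R_value)
  } else {
    sc <- implantation_scenario(config$scenario$kind,
                                te_rows = config$scenario$te_rows,
                                te_cols = config$scenario$te_cols,
                                rosette_grid = config$scenario$rosette_grid,
                                rosette_layers = config$scenario$rosette_layers,
                                sample_every = config$metrics$sample_every,
                                R_lum = config$cell$R_lum)
    logline("schedule: constrict %s lumen %s break %s total %d",
            sc$t_constrict, sc$t_lumen, sc$t_break, sc$total_steps)
    res <- run_scenario(sc, params, out_dir = config$output$dir,
                        snapshot_format = config$output$format)
  }
  prov <- list(config = unclass(config),
               package_version = as.character(utils::packageVersion("epimech")),
               wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(prov, file.path(config$output$dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logline("run finished in %.1f s", prov$wall_time_s)
  invisible(res)
}

#' Export a population snapshot as one mesh file per cell
#'
#' Writes `"{dir}/{t:06d}/{cell_id}.vtk"` (legacy VTK POLYDATA with
#' per-particle face labels) or `.obj` files, plus a `manifest.csv` listing
#' every cell's type and file.
#'
#' @param pop a `sem_population`.
#' @param dir output directory.
#' @param t step stamp.
#' @param format `"vtk"` or `"obj"`.
#' @return (invisibly) the snapshot directory.
#' @export
export_snapshot <- function(pop, dir, t, format = c("vtk", "obj")) {
  format <- match.arg(format)
  snap <- file.path(dir, sprintf("%06d", t))
  dir.create(snap, recursive = TRUE, showWarnings = FALSE)
  types <- cell_types(pop)
  files <- character(length(pop$cells))
  for (ci in seq_along(pop$cells)) {
    cell <- pop$cells[[ci]]
    pos <- cell_positions(pop, ci)
    fn <- file.path(snap, sprintf("%d.%s", ci, format))
    if (format == "vtk")
      write_vtk_polydata(fn, pos[seq_len(cell$spec$n_vertices), , drop = FALSE],
                         cell$triangles, cell$labels)
    else
      write_obj(fn, pos[seq_len(cell$spec$n_vertices), , drop = FALSE],
                cell$triangles)
    files[ci] <- basename(fn)
  }
  write.csv(data.frame(cell_id = seq_along(pop$cells), cell_type = types,
                       file = files),
            file.path(snap, "manifest.csv"), row.names = FALSE)
  invisible(snap)
}

#' Write a triangle mesh as legacy VTK POLYDATA
#' @param path output file.
#' @param points n x 3 vertex matrix.
#' @param triangles t x 3 1-based triangle indices.
#' @param labels optional per-vertex face labels written as scalars
#'   (apical = 0, basal = 1, lateral = 2).
#' @export
write_vtk_polydata <- function(path, points, triangles, labels = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "epimech cell mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(points))), con)
  writeLines(apply(points, 1, function(p) paste(format(p, digits = 9),
                                                collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(triangles), 4 * nrow(triangles)),
             con)
  writeLines(apply(triangles - 1, 1,
                   function(t) paste(c(3, t), collapse = " ")), con)
  if (!is.null(labels)) {
    code <- match(labels, c("apical", "basal", "lateral")) - 1
    writeLines(c(sprintf("POINT_DATA %d", nrow(points)),
                 "SCALARS face_label int 1", "LOOKUP_TABLE default",
                 paste(code, collapse = " ")), con)
  }
  invisible(path)
}

#' Read points and polygons back from a legacy VTK POLYDATA file
#' @param path VTK file written by [write_vtk_polydata()].
#' @return list with `points` and `triangles`.
#' @export
read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  np <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- do.call(rbind, lapply(lines[ip + seq_len(np)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  it <- grep("^POLYGONS", lines)
  nt <- as.integer(strsplit(lines[it], " ")[[1]][2])
  tri <- do.call(rbind, lapply(lines[it + seq_len(nt)], function(l)
    as.integer(strsplit(trimws(l), " +")[[1]])[-1] + 1L))
  list(points = pts, triangles = tri)
}

#' Write a triangle mesh as Wavefront OBJ
#' @param path output file.
#' @param points n x 3 vertex matrix.
#' @param triangles t x 3 1-based triangle indices.
#' @export
write_obj <- function(path, points, triangles) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(points, 1, function(p)
    paste("v", paste(format(p, digits = 9), collapse = " "))), con)
  writeLines(apply(triangles, 1, function(t)
    paste("f", paste(t, collapse = " "))), con)
  invisible(path)
}

#' Plot the metric series of a scenario run
#'
#' Draws the elastic energy, interface curvature, interface ratio, pushing
#' distances and lumen volume against simulation step.
#'
#' @param metrics the `metrics` data.frame of a [run_scenario()] result.
#' @export
plot_metric_series <- function(metrics) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(metrics$t, metrics$E, type = "l", xlab = "step",
       ylab = "elastic energy E", main = "E")
  if (!all(is.na(metrics$theta)))
    plot(metrics$t, metrics$theta, type = "l", xlab = "step",
         ylab = "theta (degrees)", main = "interface curvature")
  if (!all(is.na(metrics$ratio)))
    plot(metrics$t, metrics$ratio, type = "l", xlab = "step",
         ylab = "L/D", main = "interface ratio")
  plot(metrics$t, metrics$pd_lowest, type = "l", xlab = "step",
       ylab = "pushing distance", main = "pushing (lowest point)")
  graphics::lines(metrics$t, metrics$pd_epi_com, lty = 2)
  graphics::lines(metrics$t, metrics$pd_pop_com, lty = 3)
  plot(metrics$t, metrics$lumen_volume, type = "l", xlab = "step",
       ylab = "lumen volume", main = "lumen")
  invisible(metrics)
}
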
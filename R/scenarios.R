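#' Build a rosette-shaped epiblast
#'
#' Places polarised columnar cells in two layers on a square grid, each cell
#' tilted so its apical face points at the rosette centre (upper layer
#' apices point down-inward, lower layer up-inward), applies full apical
#' constriction (`d = R`) to every cell and relaxes the dynamics until the
#' elastic energy stabilises.  The result is an oval rosette, taller than
#' wide because of the columnar cell proportions, whose apical particles
#' converge near the centre.
#'
#' @param spec cell shape of the epiblast cells (columnar by default).
#' @param grid cells per side and layer (odd; default 3, i.e. 9 cells per
#'   layer, 18 in total).
#' @param layers number of layers (2).
#' @param tilt lateral tilt per lattice step controlling how far the cell
#'   axes fan out from the vertical (tangent units).
#' @param apical_offset distance from the rosette centre at which apical
#'   faces are placed (the apices converge within this radius).
#' @param relax_steps relaxation steps after constriction.
#' @param params a [sim_params()].
#' @return a `sem_population` of EPI cells; attributes `energy_onset` and
#'   `energy_relaxed` record the elastic energy at constriction onset and
#'   after relaxation.
#' @export
build_rosette_epiblast <- function(spec = cell_shape_spec(R = 0.5, h = 2),
                                   grid = 3, layers = 2, tilt = 0.8,
                                   apical_offset = 0.15, relax_steps = 2000,
                                   params = sim_params()) {
  if (grid %% 2 != 1 || grid < 1) stop("grid must be odd and positive")
  if (layers * grid^2 < 4)
    stop("too few cells to close a rosette (need at least 4, got ",
         layers * grid^2, ")")
  half <- (grid - 1) / 2
  cells <- list()
  for (layer in seq_len(layers) - 1L) {
    zs <- if (layer == 0) -1 else 1
    for (ix in -half:half) {
      for (iy in -half:half) {
        v <- c(ix * tilt, iy * tilt, zs)
        v <- v / sqrt(sum(v^2))
        cell <- build_epithelial_cell(spec,
                                      center = v * (apical_offset + spec$h / 2),
                                      polarity = v, type = "EPI")
        cell$lattice <- c(as.integer(ix), as.integer(iy), as.integer(layer))
        cells[[length(cells) + 1]] <- cell
      }
    }
  }
  pop <- new_population(cells)
  pop <- apical_constriction_targets(pop, seq_along(pop$cells),
                                     d = spec$R)
  e0 <- elastic_energy(pop)
  res <- advance(pop, params, relax_steps)
  pop <- res$pop
  attr(pop, "energy_onset") <- e0
  attr(pop, "energy_relaxed") <- elastic_energy(pop)
  pop
}

# Largest radial extent of the population surface around direction v
# (within an angular window), measured from `center`.
.surface_radius <- function(pos, center, v, half_angle = 25) {
  rel <- sweep(pos, 2, center, `-`)
  r <- sqrt(rowSums(rel^2))
  ok <- r > 1e-9
  cosang <- (rel[ok, , drop = FALSE] %*% v) / r[ok]
  near <- cosang > cos(half_angle * pi / 180)
  if (!any(near)) return(max(r))
  max(r[ok][near])
}

#' Drape a trophectoderm monolayer over the epiblast
#'
#' Adds a `rows x cols` sheet of cuboidal TE cells conformally over the
#' upper surface of the epiblast: each cell sits on the measured epiblast
#' surface along its viewing direction, apical face towards the epiblast,
#' with lattice coordinates one plane above the epiblast so Moore
#' neighbourhoods gate TE-EPI adhesion.  The epiblast keeps its relaxed
#' positions and constricted spring targets.
#'
#' @param rows,cols TE sheet dimensions.
#' @param spec TE cell shape (cuboidal: `h = 1`, `R = 0.5`).
#' @param on_top_of the epiblast population.
#' @param gap clearance between the epiblast surface and TE apical faces.
#' @param params a [sim_params()] (used to establish initial TE-EPI links).
#' @return combined `sem_population`.
#' @export
build_te_monolayer <- function(rows = 5, cols = 5,
                               spec = cell_shape_spec(R = 0.5, h = 1),
                               on_top_of, gap = 0.05,
                               params = sim_params()) {
  pop0 <- on_top_of
  mem <- pop0$pos[pop0$is_membrane, , drop = FALSE]
  com <- colMeans(pop0$pos)
  ztop <- max(mem[, 3] - com[3])
  tg <- 1 / ztop                      # ~1 model unit spacing at the apex
  cells <- pop0$cells
  if (gap < -0.5 * spec$R)
    stop("TE sheet overlaps the epiblast beyond tolerance (gap = ", gap, ")")
  hr <- (rows - 1) / 2; hc <- (cols - 1) / 2
  for (ix in seq_len(rows) - 1 - hr) {
    for (iy in seq_len(cols) - 1 - hc) {
      v <- c(ix * tg, iy * tg, 1)
      v <- v / sqrt(sum(v^2))
      rs <- .surface_radius(mem, com, v)
      cell <- build_epithelial_cell(spec,
                                    center = com + v * (rs + gap + spec$h / 2),
                                    polarity = v, type = "TE")
      cell$lattice <- c(as.integer(round(ix)), as.integer(round(iy)), 2L)
      cells[[length(cells) + 1]] <- cell
    }
  }
  pos_old <- pop0$pos
  pop <- new_population(cells)
  pop$pos[seq_len(nrow(pos_old)), ] <- pos_old
  # re-impose the epiblast's constricted spring targets
  for (ci in seq_along(pop0$cells)) {
    d <- pop0$cells[[ci]]$d
    if (d > 0)
      pop <- apical_constriction_targets(pop, ci, d)
  }
  external_particle_neighbors(pop, params)
}

#' Define an implantation scenario
#'
#' Bundles the builders and the event schedule of the peri-implantation
#' experiments.  The default schedule retargets all TE cells from cuboidal
#' to columnar (with a smaller apical surface) at step 0, ramps the
#' positional apical-constriction profile over the TE interior between
#' `t_constrict` and `ramp_end`, opens the epiblast lumen at `t_lumen`, and
#' (in the detachment variant) breaks all TE-EPI adhesion at `t_break`.
#'
#' @param kind preset: `"implantation"` (elongation, constriction and
#'   lumenogenesis, 6000 steps), `"implantation-detach"` (additionally
#'   breaks TE-EPI adhesion at step 6000 and runs to 9000),
#'   `"implantation-no-lumen"` (no lumenogenesis, 6000 steps) or
#'   `"lumenogenesis"` (rosette only, lumen opened at step 0, 2000 steps).
#' @param te_rows,te_cols TE sheet dimensions.
#' @param rosette_grid,rosette_layers rosette dimensions.
#' @param sample_every metric sampling interval in steps.
#' @param snapshot_times steps at which mesh snapshots are exported when an
#'   output directory is given to [run_scenario()].
#' @param elong_h,elong_apical columnar target height and apical taper
#'   radius for TE elongation.
#' @param R_lum lumen radius.
#' @param total_steps,t_constrict,t_lumen,t_break,ramp_end schedule
#'   overrides (step counts).
#' @return an object of class `sem_scenario`.
#' @export
implantation_scenario <- function(kind = c("implantation",
                                           "implantation-detach",
                                           "implantation-no-lumen",
                                           "lumenogenesis"),
                                  te_rows = 5, te_cols = 5,
                                  rosette_grid = 3, rosette_layers = 2,
                                  sample_every = 500,
                                  snapshot_times = NULL,
                                  elong_h = 2, elong_apical = 0.25,
                                  R_lum = 0.25,
                                  total_steps = NULL, t_constrict = 3000,
                                  t_lumen = 4000, t_break = 6000,
                                  ramp_end = 6000) {
  kind <- match.arg(kind)
  lumen <- kind %in% c("implantation", "implantation-detach", "lumenogenesis")
  detach <- kind == "implantation-detach"
  with_te <- kind != "lumenogenesis"
  if (is.null(total_steps))
    total_steps <- switch(kind,
                          "implantation" = 6000,
                          "implantation-detach" = 9000,
                          "implantation-no-lumen" = 6000,
                          "lumenogenesis" = 2000)
  if (is.null(snapshot_times))
    snapshot_times <- unique(c(0, t_constrict, t_break, total_steps))
  sc <- list(kind = kind, with_te = with_te, lumen = lumen, detach = detach,
             te_rows = te_rows, te_cols = te_cols,
             rosette_grid = rosette_grid, rosette_layers = rosette_layers,
             sample_every = sample_every, snapshot_times = snapshot_times,
             elong_h = elong_h, elong_apical = elong_apical, R_lum = R_lum,
             total_steps = total_steps,
             t_constrict = if (with_te) t_constrict else NA,
             t_lumen = if (lumen) (if (with_te) t_lumen else 0) else NA,
             t_break = if (detach) t_break else NA,
             ramp_end = ramp_end)
  class(sc) <- "sem_scenario"
  sc
}

#' @export
print.sem_scenario <- function(x, ...) {
  cat(sprintf("sem_scenario '%s': %d steps (constrict %s, lumen %s, break %s)\n",
              x$kind, x$total_steps, x$t_constrict, x$t_lumen, x$t_break))
  invisible(x)
}

#' Run an implantation scenario
#'
#' Builds the initial configuration, executes the scheduled events and
#' records the metric series.  Cell count is constant throughout (no
#' divisions) and the run is fully deterministic.
#'
#' @param scenario an [implantation_scenario()].
#' @param params a [sim_params()].
#' @param out_dir optional directory for metric CSV and mesh snapshots.
#' @param snapshot_format `"vtk"` or `"obj"`.
#' @return list of class `sem_run` with elements `metrics` (data.frame),
#'   `population` (final state) and `reference`.
#' @export
run_scenario <- function(scenario, params = sim_params(),
                         out_dir = NULL, snapshot_format = "vtk") {
  stopifnot(inherits(scenario, "sem_scenario"))
  pop <- build_rosette_epiblast(grid = scenario$rosette_grid,
                                layers = scenario$rosette_layers,
                                params = params)
  if (scenario$with_te)
    pop <- build_te_monolayer(scenario$te_rows, scenario$te_cols,
                              on_top_of = pop, params = params)
  ref <- reference_state(pop)
  if (scenario$with_te)
    pop <- define_interface(pop)
  te_ids <- which(cell_types(pop) == "TE")
  if (scenario$with_te && length(te_ids)) {
    pop <- retarget_shape(pop, te_ids,
                          cell_shape_spec(R = pop$cells[[te_ids[1]]]$spec$R,
                                          h = scenario$elong_h,
                                          n_vertices = pop$cells[[te_ids[1]]]$spec$n_vertices,
                                          basis = pop$cells[[te_ids[1]]]$spec$basis),
                          apical_radius = scenario$elong_apical)
  }
  profile <- if (scenario$with_te)
    positional_constriction_profile(pop, "TE") else NULL
  rows <- list()
  event_chunk <- 100L
  measure <- function(pop, t) {
    et <- elastic_energy(pop, by = "tissue")
    th <- L <- D <- ratio <- NA_real_
    if (scenario$with_te) {
      pl <- tryCatch(interface_extract(pop), error = function(e) NULL)
      if (!is.null(pl)) {
        th <- interface_curvature(pl)
        lr <- interface_ratio(pl)
        L <- lr[["L"]]; D <- lr[["D"]]; ratio <- lr[["ratio"]]
      }
    }
    pd <- pushing_distance(pop, ref)
    data.frame(t = t,
               E = sum(et),
               E_TE = if ("TE" %in% names(et)) et[["TE"]] else 0,
               E_EPI = if ("EPI" %in% names(et)) et[["EPI"]] else 0,
               theta = th, L = L, D = D, ratio = ratio,
               pd_lowest = pd[["lowest"]],
               pd_epi_com = pd[["epi_com"]],
               pd_pop_com = pd[["pop_com"]],
               lumen_volume = lumen_volume(pop))
  }
  for (t in seq(0L, scenario$total_steps - event_chunk, by = event_chunk)) {
    if (!is.na(scenario$t_constrict) && t >= scenario$t_constrict &&
        t <= scenario$ramp_end) {
      frac <- if (scenario$ramp_end > scenario$t_constrict)
        min(1, (t - scenario$t_constrict + event_chunk) /
              (scenario$ramp_end - scenario$t_constrict)) else 1
      active <- profile$cell[profile$d > 0]
      if (length(active))
        pop <- apical_constriction_targets(pop, active,
                                           profile$d[profile$d > 0] * frac)
    }
    if (!is.na(scenario$t_lumen) && t == scenario$t_lumen)
      pop <- open_lumen(pop, "EPI", R_lum = scenario$R_lum, params = params)
    if (!is.na(scenario$t_break) && t == scenario$t_break)
      pop <- break_adhesion(pop, "TE", "EPI")
    if (t %% scenario$sample_every == 0)
      rows[[length(rows) + 1]] <- measure(pop, t)
    if (!is.null(out_dir) && t %in% scenario$snapshot_times)
      export_snapshot(pop, out_dir, t, snapshot_format)
    pop <- advance(pop, params, event_chunk)$pop
  }
  rows[[length(rows) + 1]] <- measure(pop, scenario$total_steps)
  if (!is.null(out_dir) && scenario$total_steps %in% scenario$snapshot_times)
    export_snapshot(pop, out_dir, scenario$total_steps, snapshot_format)
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (!is.null(out_dir))
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  structure(list(metrics = metrics, population = pop, reference = ref,
                 scenario = scenario),
            class = "sem_run")
}
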
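#' Retarget a cell's shape
#'
#' Rebuilds the cell's reference template with new dimensions (and optionally
#' a tapered apical radius) and sets every spring's equilibrium length to the
#' corresponding inter-particle distance in the target geometry.  Positions
#' are untouched; relaxation of the dynamics performs the actual shape
#' change.  This is the elongation behaviour: retargeting a cuboidal cell
#' (`h = 1`) to a columnar spec (`h = 2`) makes the cell grow along its
#' axis, and a reduced `apical_radius` gives the elongated cell a smaller
#' apical surface.
#'
#' @param pop a `sem_population`.
#' @param cell_ids indices of the cells to retarget.
#' @param target_spec a [cell_shape_spec()] of the same mesh family
#'   (vertex count and basis) as the cells.
#' @param apical_radius optional target apical radius; ring radii then taper
#'   linearly from this value at the apical ring to `target_spec$R` at the
#'   basal ring.
#' @return the modified population.
#' @export
retarget_shape <- function(pop, cell_ids, target_spec, apical_radius = NULL) {
  for (ci in cell_ids) {
    cell <- pop$cells[[ci]]
    if (target_spec$n_vertices != cell$spec$n_vertices ||
        target_spec$basis != cell$spec$basis)
      stop("incompatible mesh family for cell ", ci,
           " (have ", cell$spec$n_vertices, "/", cell$spec$basis,
           ", target ", target_spec$n_vertices, "/", target_spec$basis, ")")
    m <- (target_spec$n_vertices - 2) / 8
    rr <- if (is.null(apical_radius)) rep(target_spec$R, m) else
      apical_radius + (target_spec$R - apical_radius) * (seq_len(m) - 1) / (m - 1)
    template <- .cell_template(target_spec, ring_radii = rr)
    pop$cells[[ci]]$template <- template
    pop$cells[[ci]]$spec <- target_spec
    pop$cells[[ci]]$d <- 0
    pop <- .set_req_from_template(pop, ci, template)
  }
  pop
}

# Apically constricted copy of a template: the apical ring is pulled towards
# the pole axis so its radius becomes R - d; all other rows are untouched.
.constricted_template <- function(template, R, d) {
  out <- template
  out[1 + 1:8, 1:2] <- out[1 + 1:8, 1:2] * (R - d) / R
  out
}

#' Apical constriction equilibrium-length retargeting
#'
#' Shrinks the apical ring of the target geometry from radius `R` to
#' `R - d` and recomputes the equilibrium lengths of all springs from the
#' constricted geometry: apical-ring chords scale by `(R - d)/R`, the
#' apico-lateral and apical cytoskeleton springs take the distances to the
#' displaced apical vertices, and purely basal/lateral springs are
#' unchanged.  Applying `d` and then resetting to the original target
#' restores the previous equilibrium lengths exactly.
#'
#' @param pop a `sem_population`.
#' @param cell_ids indices of cells to constrict.
#' @param d apical shrinkage length, `0 <= d <= R` (scalar or one value per
#'   cell).
#' @return the modified population.
#' @export
apical_constriction_targets <- function(pop, cell_ids, d) {
  d <- rep(d, length.out = length(cell_ids))
  for (k in seq_along(cell_ids)) {
    ci <- cell_ids[k]
    R <- pop$cells[[ci]]$spec$R
    if (d[k] < 0 || d[k] > R)
      stop("d must satisfy 0 <= d <= R (cell ", ci, ", d = ", d[k], ")")
    template <- .constricted_template(pop$cells[[ci]]$template, R, d[k])
    pop$cells[[ci]]$d <- d[k]
    pop <- .set_req_from_template(pop, ci, template)
  }
  pop
}

#' Positional constriction profile over a cell sheet
#'
#' Step profile: interior cells of the sheet constrict completely
#' (`d = R`) while cells on the sheet boundary do not (`d = 0`).  A sheet
#' consisting of a single cell counts as interior.
#'
#' @param pop a `sem_population`.
#' @param tissue cell type forming the sheet.
#' @param mode profile shape; only `"step"` is defined.
#' @return data.frame with columns `cell` and `d`.
#' @export
positional_constriction_profile <- function(pop, tissue = "TE", mode = "step") {
  mode <- match.arg(mode, "step")
  ids <- which(cell_types(pop) == tissue)
  if (!length(ids)) stop("no cells of tissue '", tissue, "'")
  lat <- do.call(rbind, lapply(pop$cells[ids], `[[`, "lattice"))
  rx <- range(lat[, 1]); ry <- range(lat[, 2])
  interior <- (lat[, 1] > rx[1] & lat[, 1] < rx[2] &
               lat[, 2] > ry[1] & lat[, 2] < ry[2]) |
    (rx[1] == rx[2] & ry[1] == ry[2])   # 1 x 1 sheet: the middle
  d <- ifelse(interior,
              vapply(pop$cells[ids], function(c) c$spec$R, 0), 0)
  data.frame(cell = ids, d = d)
}

#' Lumen repulsion force on one particle
#'
#' Morse-form radial force from a virtual source at `O` with equilibrium at
#' distance `R_lum`: particles closer than `R_lum` are pushed away from the
#' source, particles beyond it are drawn back towards the shell.
#'
#' @param source list with `center` (the source position `O`), `R_lum` and
#'   `J` (strength, the epiblast interaction strength).
#' @param p particle position.
#' @param params a [sim_params()] (supplies `rho` and the force cap).
#' @return 3-vector force.
#' @export
lumen_repulsion_force <- function(source, p, params = sim_params()) {
  d <- source$center - p
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("particle at the lumen source")
  morse_force(source$J, params$rho, r, source$R_lum, d / r,
              params$force_cap_mult)
}

#' Open a lumen at the centre of the epiblast rosette
#'
#' Breaks the adhesion links between apposed apical membranes of the rosette
#' (such particle pairs are excluded from all later link refreshes) and
#' installs a virtual repulsion source at the centroid of the apical
#' particles.  From then on every apical particle of the rosette receives
#' the radial Morse repulsion as a specific force, which drives hollowing.
#'
#' @param pop a `sem_population`.
#' @param tissue cell type of the rosette.
#' @param R_lum target lumen radius.
#' @param params a [sim_params()] (supplies the source strength `J_EPI`).
#' @return the modified population.
#' @export
open_lumen <- function(pop, tissue = "EPI", R_lum = 0.25,
                       params = sim_params()) {
  ids <- which(cell_types(pop) == tissue)
  apical <- which(pop$cell_of %in% ids & pop$is_membrane &
                  pop$labels == "apical")
  if (!length(apical)) stop("no apical particles found for tissue '", tissue, "'")
  center <- colMeans(pop$pos[apical, , drop = FALSE])
  pop$lumen <- list(center = center, R_lum = R_lum,
                    J = .J_of_type(params, tissue), targets = apical)
  pop$cand <- NULL  # re-derive candidates with apical-apical pairs excluded
  if (length(pop$links$a)) {
    t <- logical(nrow(pop$pos)); t[apical] <- TRUE
    drop <- t[pop$links$a] & t[pop$links$b]
    pop$links$a <- pop$links$a[!drop]
    pop$links$b <- pop$links$b[!drop]
  }
  pop
}
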
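#' Assemble cells into a population
#'
#' Stacks the particles of all cells into one position matrix, builds the
#' per-cell spring networks (membrane edges plus one cytoskeleton spring from
#' every membrane particle to the intracellular particle), and initialises
#' every spring's equilibrium length to its current length, so the population
#' starts in its resting state.
#'
#' @param cells list of [build_epithelial_cell()] objects; each may carry a
#'   `lattice` integer 3-vector (used for Moore neighbourhoods) and a `type`.
#' @return an object of class `sem_population`.
#' @export
new_population <- function(cells) {
  stopifnot(length(cells) >= 1)
  offsets <- integer(length(cells))
  pos <- NULL
  si <- sj <- scell <- integer(0)
  cell_of <- integer(0); is_mem <- logical(0); plabel <- character(0)
  off <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    n <- cell$spec$n_vertices
    offsets[ci] <- off
    pos <- rbind(pos, cell$pos)
    e <- mesh_edges(cell)
    cyto <- cbind(seq_len(n), n + 1L)
    edges <- rbind(e, cyto)
    si <- c(si, off + edges[, 1])
    sj <- c(sj, off + edges[, 2])
    scell <- c(scell, rep(ci, nrow(edges)))
    cell_of <- c(cell_of, rep(ci, n + 1L))
    is_mem <- c(is_mem, rep(TRUE, n), FALSE)
    plabel <- c(plabel, cell$labels, "internal")
    off <- off + n + 1L
  }
  d <- pos[sj, , drop = FALSE] - pos[si, , drop = FALSE]
  pop <- list(pos = pos, cells = cells, offsets = offsets,
              springs = list(i = as.integer(si), j = as.integer(sj),
                             cell = as.integer(scell),
                             req = sqrt(rowSums(d^2))),
              cell_of = as.integer(cell_of), is_membrane = is_mem,
              labels = plabel,
              links = list(a = integer(0), b = integer(0)),
              broken_types = character(0),
              lumen = NULL)
  class(pop) <- "sem_population"
  pop
}

#' @export
print.sem_population <- function(x, ...) {
  tt <- table(vapply(x$cells, `[[`, "", "type"))
  cat(sprintf("sem_population: %d cells (%s), %d particles, %d springs, %d active links\n",
              length(x$cells), paste(names(tt), tt, sep = "=", collapse = ", "),
              nrow(x$pos), length(x$springs$i), length(x$links$a)))
  invisible(x)
}

# particle indices (global) of cell ci; membrane only unless all = TRUE
.cell_particles <- function(pop, ci, all = FALSE) {
  n <- pop$cells[[ci]]$spec$n_vertices
  pop$offsets[ci] + seq_len(n + if (all) 1L else 0L)
}

#' Extract current world positions of one cell
#' @param pop a `sem_population`.
#' @param ci cell index.
#' @return matrix of positions (membrane particles then intracellular).
#' @export
cell_positions <- function(pop, ci) {
  pop$pos[.cell_particles(pop, ci, all = TRUE), , drop = FALSE]
}

#' Cell type of every cell
#' @param pop a `sem_population`.
#' @return character vector.
#' @export
cell_types <- function(pop) vapply(pop$cells, `[[`, "", "type")

# per-spring interaction strength under params
.spring_J <- function(pop, params) {
  types <- cell_types(pop)
  vapply(types[pop$springs$cell], function(t) .J_of_type(params, t), 0)
}

# per-particle friction coefficient under params
.particle_lambda <- function(pop, params) {
  ifelse(pop$is_membrane, params$lambda_med, params$lambda_chi)
}

# Set the equilibrium lengths of one cell's springs from a local template.
# Positions are untouched: dynamics perform the actual motion.
.set_req_from_template <- function(pop, ci, template) {
  sel <- which(pop$springs$cell == ci)
  off <- pop$offsets[ci]
  li <- pop$springs$i[sel] - off
  lj <- pop$springs$j[sel] - off
  d <- template[lj, , drop = FALSE] - template[li, , drop = FALSE]
  pop$springs$req[sel] <- sqrt(rowSums(d^2))
  pop
}

#' Elastic energy of a population
#'
#' The elastic energy of a cell is the sum over its springs of the squared
#' difference between equilibrium and current lengths; tissue and population
#' energies sum the per-cell energies.  Zero exactly when every spring is at
#' its equilibrium length (the resting state).
#'
#' @param pop a `sem_population`.
#' @param by `"total"` (scalar), `"cell"` (one value per cell) or
#'   `"tissue"` (named vector over cell types).
#' @return numeric.
#' @export
elastic_energy <- function(pop, by = c("total", "cell", "tissue")) {
  by <- match.arg(by)
  d <- pop$pos[pop$springs$j, , drop = FALSE] - pop$pos[pop$springs$i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  e <- (pop$springs$req - r)^2
  if (by == "total") return(sum(e))
  percell <- vapply(seq_along(pop$cells),
                    function(ci) sum(e[pop$springs$cell == ci]), 0)
  if (by == "cell") return(percell)
  tapply(percell, cell_types(pop), sum)
}
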
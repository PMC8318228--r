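#' Cell shape specification
#'
#' Describes the reference geometry of a single epithelial cell: an apical
#' disc of radius `R`, a height `h` along the apico-basal axis, and a mesh
#' family.  The 34-vertex mesh uses four octagonal rings plus apical and
#' basal pole particles (`hex_ring` basis); the 42-vertex mesh uses five
#' rings of eight particles laid out on a square perimeter (`square` basis)
#' plus the two poles.  All lengths are dimensionless model units.
#'
#' @param R apical radius (> 0).
#' @param h cell height (> 0).
#' @param n_vertices number of membrane particles; any `8 * m + 2` with
#'   `m >= 2` rings is accepted, the reference meshes being 34 and 42.
#' @param basis ring layout, `"hex_ring"` (circular rings, default for 34
#'   vertices) or `"square"` (square rings, default for 42 vertices).
#' @return an object of class `cell_shape_spec`.
#' @examples
#' cell_shape_spec()                      # columnar 34-vertex cell
#' cell_shape_spec(n_vertices = 42, basis = "square")
#' @export
cell_shape_spec <- function(R = 0.5, h = 2, n_vertices = 34, basis = NULL) {
  if (is.null(basis)) basis <- if (n_vertices == 42) "square" else "hex_ring"
  basis <- match.arg(basis, c("hex_ring", "square"))
  if (!(R > 0) || !(h > 0))
    stop("R and h must be positive")
  if (n_vertices < 8 || (n_vertices - 2) %% 8 != 0 || (n_vertices - 2) / 8 < 2)
    stop("unsupported n_vertices = ", n_vertices,
         "; supported meshes have 8*m + 2 particles with m >= 2 rings ",
         "(e.g. 34 with basis 'hex_ring', 42 with basis 'square')")
  structure(list(R = R, h = h, n_vertices = n_vertices, basis = basis),
            class = "cell_shape_spec")
}

# 8 ring points (x, y) at radius R for the given basis, in angular order.
.ring_points <- function(R, basis) {
  ang <- 2 * pi * (0:7) / 8
  x <- cos(ang); y <- sin(ang)
  if (basis == "square") {
    m <- pmax(abs(x), abs(y))       # project onto the unit square perimeter
    x <- x / m; y <- y / m
  }
  cbind(R * x, R * y)
}

# Local template coordinates for a cell: (n_mem + 1) x 3 matrix, apical pole
# first, then rings from apical to basal, basal pole, intracellular particle
# last.  The apical plane sits at z = -h/2, the basal plane at z = +h/2.
# ring_radii optionally overrides the radius of every ring (length m).
.cell_template <- function(spec, ring_radii = NULL) {
  m <- (spec$n_vertices - 2) / 8
  if (is.null(ring_radii)) ring_radii <- rep(spec$R, m)
  stopifnot(length(ring_radii) == m)
  z <- -spec$h / 2 + spec$h * (seq_len(m) - 1) / (m - 1)
  loc <- matrix(0, spec$n_vertices + 1, 3)
  loc[1, ] <- c(0, 0, -spec$h / 2)
  for (k in seq_len(m)) {
    rp <- .ring_points(ring_radii[k], spec$basis)
    loc[1 + (k - 1) * 8 + 1:8, ] <- cbind(rp, z[k])
  }
  loc[spec$n_vertices, ] <- c(0, 0, spec$h / 2)
  loc[spec$n_vertices + 1, ] <- colMeans(loc[seq_len(spec$n_vertices), , drop = FALSE])
  loc
}

# Triangulation of the template mesh: fan caps at both poles, two triangles
# per quad between consecutive rings.  1-based indices into the template.
.cell_triangles <- function(n_vertices) {
  m <- (n_vertices - 2) / 8
  ring <- function(k, s) 1 + (k - 1) * 8 + ((s - 1) %% 8) + 1
  tri <- list()
  for (s in 1:8) tri[[length(tri) + 1]] <- c(1, ring(1, s), ring(1, s + 1))
  for (k in seq_len(m - 1)) {
    for (s in 1:8) {
      tri[[length(tri) + 1]] <- c(ring(k, s), ring(k, s + 1), ring(k + 1, s))
      tri[[length(tri) + 1]] <- c(ring(k, s + 1), ring(k + 1, s + 1), ring(k + 1, s))
    }
  }
  np <- n_vertices
  for (s in 1:8) tri[[length(tri) + 1]] <- c(np, ring(m, s), ring(m, s + 1))
  do.call(rbind, tri)
}

# Face labels per membrane particle: apical pole + first ring are apical,
# basal pole + last ring are basal, the remaining rings lateral.
.cell_labels <- function(n_vertices) {
  m <- (n_vertices - 2) / 8
  lab <- rep("lateral", n_vertices)
  lab[c(1, 1 + 1:8)] <- "apical"
  lab[c(n_vertices, 1 + (m - 1) * 8 + 1:8)] <- "basal"
  lab
}

# Orthonormal frame whose third column is the (normalised) polarity axis.
.axis_frame <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(axis[2] * ref[3] - axis[3] * ref[2],
          axis[3] * ref[1] - axis[1] * ref[3],
          axis[1] * ref[2] - axis[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2, axis)
}

.local_to_world <- function(loc, frame, center) {
  sweep(loc %*% t(frame), 2, center, `+`)
}

#' Build a single epithelial cell mesh
#'
#' Constructs a closed prism-like triangulated membrane of
#' `spec$n_vertices` particles with one intracellular particle at the
#' centroid.  The polarity axis points from the apical face to the basal
#' face; the apical disc (radius `R`) sits at `center - h/2 * polarity`.
#' Construction is fully deterministic.
#'
#' @param spec a [cell_shape_spec()].
#' @param center 3-vector, geometric centre of the cell axis.
#' @param polarity 3-vector, apical-to-basal direction (normalised internally).
#' @param type cell type tag, `"EPI"` or `"TE"`.
#' @return an object of class `sem_cell` with elements `pos` (world
#'   coordinates, intracellular particle last), `triangles`, `labels`,
#'   `template` (local reference coordinates), `frame`, `center`, `spec`.
#' @examples
#' cell <- build_epithelial_cell(cell_shape_spec(R = 0.5, h = 2, n_vertices = 34))
#' nrow(cell$pos)   # 35 = 34 membrane particles + 1 intracellular
#' @export
build_epithelial_cell <- function(spec, center = c(0, 0, 0),
                                  polarity = c(0, 0, 1), type = "EPI") {
  stopifnot(inherits(spec, "cell_shape_spec"))
  frame <- .axis_frame(polarity)
  template <- .cell_template(spec)
  cell <- list(pos = .local_to_world(template, frame, center),
               triangles = .cell_triangles(spec$n_vertices),
               labels = .cell_labels(spec$n_vertices),
               template = template,
               frame = frame, center = as.numeric(center),
               spec = spec, type = type, d = 0,
               lattice = c(0L, 0L, 0L))
  class(cell) <- "sem_cell"
  cell
}

#' @export
print.sem_cell <- function(x, ...) {
  cat(sprintf("sem_cell: %d membrane particles (%s), R=%g h=%g, type %s\n",
              x$spec$n_vertices, x$spec$basis, x$spec$R, x$spec$h, x$type))
  invisible(x)
}

#' Unique undirected edges of a cell's membrane triangulation
#' @param cell a `sem_cell`.
#' @return two-column integer matrix of particle index pairs (i < j).
#' @export
mesh_edges <- function(cell) {
  tr <- cell$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Internal-neighbour adjacency of membrane particles
#'
#' Two particles of the same cell are internal neighbours when they share a
#' mesh triangle.
#'
#' @param cell a `sem_cell`.
#' @return symmetric logical adjacency matrix over membrane particles.
#' @export
internal_neighbors <- function(cell) {
  n <- cell$spec$n_vertices
  adj <- matrix(FALSE, n, n)
  e <- mesh_edges(cell)
  adj[e] <- TRUE
  adj[e[, c(2, 1)]] <- TRUE
  adj
}

#' Area of a labelled face of a cell
#'
#' Sums the areas of all mesh triangles whose three vertices carry the given
#' face label.
#'
#' @param cell a `sem_cell`.
#' @param label `"apical"`, `"basal"` or `"lateral"`.
#' @param pos optional positions to measure on (defaults to `cell$pos`);
#'   useful for cells embedded in a population.
#' @return total face area (>= 0).
#' @export
face_area <- function(cell, label, pos = NULL) {
  if (!label %in% cell$labels)
    stop("label '", label, "' not present in this mesh")
  if (is.null(pos)) pos <- cell$pos
  keep <- apply(cell$triangles, 1, function(t) all(cell$labels[t] == label))
  tr <- cell$triangles[keep, , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  a <- pos[tr[, 2], , drop = FALSE] - pos[tr[, 1], , drop = FALSE]
  b <- pos[tr[, 3], , drop = FALSE] - pos[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Check that a triangle mesh is a closed 2-manifold
#'
#' Every edge must be shared by exactly two triangles and every membrane
#' particle must belong to at least one triangle.
#'
#' @param cell a `sem_cell`.
#' @return `TRUE` (invisibly) or an error.
#' @export
check_mesh_closed <- function(cell) {
  tr <- cell$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab != 2)) stop("mesh is not closed: some edges not shared by exactly 2 triangles")
  if (!all(seq_len(cell$spec$n_vertices) %in% as.vector(tr)))
    stop("mesh has isolated particles")
  invisible(TRUE)
}
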
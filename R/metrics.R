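#' Reference state for displacement metrics
#' @param pop a `sem_population`.
#' @return list of reference quantities recorded at the initial stage.
#' @export
reference_state <- function(pop) {
  epi <- cell_types(pop)[pop$cell_of] == "EPI"
  list(epi_lowest = min(pop$pos[epi & pop$is_membrane, 3]),
       epi_com = mean(pop$pos[epi, 3]),
       pop_com = mean(pop$pos[, 3]))
}

#' Pushing distances along the maternal axis
#'
#' Signed displacement towards the maternal side (negative z) relative to
#' the reference state, in three variants: the lowest epiblast membrane
#' particle, the epiblast centre of mass, and the whole-population centre of
#' mass.  Positive values mean movement towards the maternal side.
#'
#' @param pop a `sem_population`.
#' @param ref a [reference_state()] recorded at the initial stage.
#' @return named numeric vector `c(lowest, epi_com, pop_com)`.
#' @export
pushing_distance <- function(pop, ref) {
  epi <- cell_types(pop)[pop$cell_of] == "EPI"
  c(lowest = ref$epi_lowest - min(pop$pos[epi & pop$is_membrane, 3]),
    epi_com = ref$epi_com - mean(pop$pos[epi, 3]),
    pop_com = ref$pop_com - mean(pop$pos[, 3]))
}

# Epiblast membrane particles covered by the trophectoderm: within `reach`
# of any TE membrane particle.
.interface_region <- function(pop, reach = 0.5) {
  types <- cell_types(pop)
  epi_i <- which(types[pop$cell_of] == "EPI" & pop$is_membrane)
  te_p <- pop$pos[types[pop$cell_of] == "TE" & pop$is_membrane, , drop = FALSE]
  if (!nrow(te_p) || !length(epi_i)) return(integer(0))
  keep <- logical(length(epi_i))
  r2 <- reach^2
  for (k in seq_along(epi_i)) {
    d2 <- min(colSums((t(te_p) - pop$pos[epi_i[k], ])^2))
    keep[k] <- d2 < r2
  }
  epi_i[keep]
}

#' Fix the interface particle set of a population
#'
#' Selects the epiblast membrane particles that form the TE/EPI interface
#' polyline: particles covered by the trophectoderm at the initial stage
#' (within `reach` of a TE membrane particle), restricted to a mid-sagittal
#' slab of half-width `slab` around the epiblast centre (widened
#' geometrically if it holds fewer than three particles).  The chosen
#' particle ids are stored on the population and re-used by every later
#' [interface_extract()], so the interface tracked over time is the surface
#' material that the trophectoderm covered initially, also after the
#' trophectoderm detaches.
#'
#' @param pop a `sem_population` with TE-EPI links established.
#' @param slab slab half-width (default half the apical radius).
#' @param reach coverage distance defining the covered region.
#' @return the population with `interface_ids` set.
#' @export
define_interface <- function(pop, slab = 0.25, reach = 0.5) {
  idx <- .interface_region(pop, reach)
  if (length(idx) < 3) stop("no interface particles")
  epi <- cell_types(pop)[pop$cell_of] == "EPI"
  ec <- colMeans(pop$pos[epi, , drop = FALSE])
  pts <- pop$pos[idx, , drop = FALSE]
  keep <- abs(pts[, 2] - ec[2]) <= slab
  while (sum(keep) < 3 && slab < 16) {
    slab <- slab * 1.5
    keep <- abs(pts[, 2] - ec[2]) <= slab
  }
  if (sum(keep) < 3) stop("no interface particles in the sagittal slab")
  pop$interface_ids <- idx[keep]
  pop
}

#' Extract the TE/EPI interface polyline
#'
#' Projects the interface particles (see [define_interface()]; defined on
#' the fly when not yet fixed) onto the x-z plane and orders them by polar
#' angle about the epiblast centre of mass, which is monotone along the
#' covered arc, giving an ordering independent of particle indexing.
#'
#' Ordered particles carry membrane-scale wrinkles that are not interface
#' shape; a short moving average measures the polyline at cell-scale
#' resolution, as a slice tracing would.
#'
#' @param pop a `sem_population`.
#' @param slab,reach passed to [define_interface()] when the interface has
#'   not been fixed yet.
#' @param smooth half-window of the moving average along the ordered
#'   polyline (0 disables smoothing).
#' @return ordered polyline, a k x 2 matrix (columns x, z).
#' @export
interface_extract <- function(pop, slab = 0.25, reach = 0.5, smooth = 1) {
  if (is.null(pop$interface_ids)) pop <- define_interface(pop, slab, reach)
  epi <- cell_types(pop)[pop$cell_of] == "EPI"
  ec <- colMeans(pop$pos[epi, , drop = FALSE])
  p <- pop$pos[pop$interface_ids, c(1, 3), drop = FALSE]
  ang <- atan2(p[, 1] - ec[1], p[, 2] - ec[3])
  p <- p[order(ang, p[, 1]), , drop = FALSE]
  if (smooth > 0 && nrow(p) > 2 * smooth + 1) {
    k <- nrow(p)
    sm <- p
    for (i in seq_len(k)) {
      w <- max(1, i - smooth):min(k, i + smooth)
      sm[i, ] <- colMeans(p[w, , drop = FALSE])
    }
    p <- sm
  }
  colnames(p) <- c("x", "z")
  p
}

#' Interface curvature angle
#'
#' The inclination angle at the polyline's central point (the vertex closest
#' to the arc-length midpoint) subtended by the two endpoints; a flat
#' interface gives 180 degrees, stronger curvature smaller angles.
#'
#' @param polyline ordered k x 2 matrix (k >= 3).
#' @return angle in degrees.
#' @export
interface_curvature <- function(polyline) {
  k <- nrow(polyline)
  if (is.null(k) || k < 3) stop("polyline needs at least 3 points")
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                       polyline[-k, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  mid <- polyline[which.min(abs(cum - cum[k] / 2)), ]
  v1 <- polyline[1, ] - mid
  v2 <- polyline[k, ] - mid
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("degenerate polyline")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Interface length, diameter and ratio
#'
#' `L` is the polyline arc length, `D` the Euclidean distance between its
#' endpoints, and `L/D >= 1` their ratio; a straight interface gives
#' `L/D = 1`.
#'
#' @param polyline ordered k x 2 matrix (k >= 2).
#' @return named vector `c(L, D, ratio)`.
#' @export
interface_ratio <- function(polyline) {
  k <- nrow(polyline)
  if (is.null(k) || k < 2) stop("polyline needs at least 2 points")
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                       polyline[-k, , drop = FALSE])^2))
  L <- sum(seg)
  D <- sqrt(sum((polyline[k, ] - polyline[1, ])^2))
  if (D < 1e-12) stop("degenerate interface: coincident endpoints")
  c(L = L, D = D, ratio = L / D)
}

#' Lumen cavity volume
#'
#' Volume of the star-shaped cavity around the lumen source, estimated on an
#' equal-solid-angle direction grid: directions are binned by longitude and
#' by equal-area bands in the polar cosine, each bin contributes
#' \eqn{r_{max}^3 \Delta\Omega / 3} using the most distant target particle
#' in the bin (empty bins fall back to the mean radius).  Points lying on a
#' sphere of radius r reproduce \eqn{4\pi r^3/3}.  Zero before
#' [open_lumen()].
#'
#' @param pop a `sem_population`.
#' @param n_az,n_pol angular grid resolution.
#' @return cavity volume (>= 0).
#' @export
lumen_volume <- function(pop, n_az = 8, n_pol = 4) {
  if (is.null(pop$lumen)) return(0)
  p <- sweep(pop$pos[pop$lumen$targets, , drop = FALSE], 2,
             pop$lumen$center, `-`)
  r <- sqrt(rowSums(p^2))
  if (!length(r) || all(r < 1e-12)) return(0)
  az <- atan2(p[, 2], p[, 1])
  cz <- ifelse(r > 0, p[, 3] / r, 0)
  ia <- pmin(n_az, 1 + floor((az + pi) / (2 * pi) * n_az))
  ip <- pmin(n_pol, 1 + floor((cz + 1) / 2 * n_pol))
  bin <- (ip - 1) * n_az + ia
  rmax <- rep(mean(r), n_az * n_pol)
  agg <- tapply(r, bin, max)
  rmax[as.integer(names(agg))] <- agg
  dOmega <- 4 * pi / (n_az * n_pol)
  sum(rmax^3) * dOmega / 3
}

#' Normalised fitness metric of an implantation sweep
#'
#' Combines final interface curvature `theta`, interface ratio `Ir` and
#' pushing distance `H` against their optimal values across the sweep:
#' \deqn{M = \frac{1}{3}\left[\left(\frac{\theta - \theta_{max}}{\theta_{max}
#'   - \theta_{min}}\right)^2 + \left(\frac{Ir - Ir_{min}}{Ir_{max} -
#'   Ir_{min}}\right)^2 + \left(\frac{H - H_{max}}{H_{max} -
#'   H_{min}}\right)^2\right]}
#' A flat interface (large theta), a straight interface (small Ir) and a
#' large pushing distance are optimal; M is constrained to [0, 1] over the
#' sweep's own data.
#'
#' @param theta,Ir,H numeric vectors over the sweep (recycled jointly).
#' @param optima optional list with `theta_min`, `theta_max`, `Ir_min`,
#'   `Ir_max`, `H_min`, `H_max`; computed from the data when omitted.
#' @return numeric vector of fitness values in [0, 1].
#' @export
fitness_metric <- function(theta, Ir, H, optima = NULL) {
  if (is.null(optima))
    optima <- list(theta_min = min(theta), theta_max = max(theta),
                   Ir_min = min(Ir), Ir_max = max(Ir),
                   H_min = min(H), H_max = max(H))
  dth <- optima$theta_max - optima$theta_min
  dir <- optima$Ir_max - optima$Ir_min
  dh <- optima$H_max - optima$H_min
  if (dth == 0 || dir == 0 || dh == 0)
    stop("degenerate sweep: zero range in one of the metrics")
  (((theta - optima$theta_max) / dth)^2 +
   ((Ir - optima$Ir_min) / dir)^2 +
   ((H - optima$H_max) / dh)^2) / 3
}
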
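#' Global simulation parameters
#'
#' Collects the physical constants of the model: per-tissue interaction
#' strengths \eqn{J_\omega}, the Morse scaling factor \eqn{\rho}, the friction
#' coefficients of the medium (\eqn{\lambda_{med}}, acting on membrane
#' particles) and of the cell interior (\eqn{\lambda_\chi}, acting on the
#' intracellular particle), and the integration time step.  All quantities are
#' dimensionless model units.
#'
#' Defaults follow the reference experiments: \code{J_TE = J_EPI = 2.5},
#' \code{rho = 1}, \code{lambda_med = lambda_chi = 2}.
#'
#' @param J_TE interaction strength for trophectoderm (TE) cells.
#' @param J_EPI interaction strength for epiblast (EPI) cells.
#' @param rho Morse scaling factor (inverse length).
#' @param lambda_med friction coefficient for membrane particles.
#' @param lambda_chi friction coefficient for the intracellular particle.
#' @param dt integration time step per simulation step.  The default 0.005
#'   keeps the explicit Euler scheme stable across the stiffness range of
#'   the supported meshes and friction settings.
#' @param force_cap_mult Morse forces are clamped at
#'   \code{force_cap_mult * J * rho}.  The cap engages well before the
#'   exponential stiffening of a stretched spring exceeds the explicit-Euler
#'   stability limit, which keeps transiently overstretched springs from
#'   blowing up the integration.
#' @param adhesion_cutoff distance below which particles of neighbouring
#'   cells are linked (default \code{0.4 * 0.5}, i.e. 0.4 apical radii).
#' @param max_links maximum adhesion links per particle.  The default of 1
#'   pairs particles one-to-one; chains of force-copying links are
#'   anti-damped (the coupling operator acquires negative eigenvalues), so
#'   quotas above 1 destabilise dense contact zones.
#' @param refresh_every adhesion links are recomputed every this many steps.
#'
#' @return an object of class `sem_params` (a validated list).
#' @export
sim_params <- function(J_TE = 2.5, J_EPI = 2.5, rho = 1,
                       lambda_med = 2, lambda_chi = 2,
                       dt = 0.005, force_cap_mult = 10,
                       adhesion_cutoff = 0.2, max_links = 1,
                       refresh_every = 10) {
  p <- list(J_TE = J_TE, J_EPI = J_EPI, rho = rho,
            lambda_med = lambda_med, lambda_chi = lambda_chi,
            dt = dt, force_cap_mult = force_cap_mult,
            adhesion_cutoff = adhesion_cutoff, max_links = max_links,
            refresh_every = refresh_every)
  stopifnot(p$J_TE >= 0, p$J_EPI >= 0, p$rho > 0,
            p$lambda_med > 0, p$lambda_chi > 0, p$dt > 0,
            p$force_cap_mult > 0, p$adhesion_cutoff > 0,
            p$max_links >= 1, p$refresh_every >= 1)
  class(p) <- "sem_params"
  p
}

#' @export
print.sem_params <- function(x, ...) {
  cat("sem_params:",
      sprintf("J_TE=%g J_EPI=%g rho=%g lambda_med=%g lambda_chi=%g dt=%g",
              x$J_TE, x$J_EPI, x$rho, x$lambda_med, x$lambda_chi, x$dt), "\n")
  invisible(x)
}

# interaction strength for a cell type under params p
.J_of_type <- function(p, type) {
  switch(type, TE = p$J_TE, EPI = p$J_EPI,
         stop("unknown cell type: ", type))
}
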
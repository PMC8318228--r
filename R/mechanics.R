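#' Morse spring force
#'
#' Force exerted through a non-linear spring of equilibrium length `r_eq`
#' at current length `r`:
#' \deqn{F = 2 J \rho (e^{2\rho(r - r_{eq})} - e^{\rho(r - r_{eq})}) \, u}
#' where `u` is the unit vector from the particle towards its partner.  The
#' force vanishes exactly at `r = r_eq`, pulls the particles together when
#' the spring is stretched and pushes them apart when compressed.  The
#' magnitude is clamped at `cap_mult * J * rho`.
#'
#' @param J interaction strength.
#' @param rho Morse scaling factor.
#' @param r current distance (> 0).
#' @param r_eq equilibrium distance (>= 0; zero for fully
#'   constricted targets).
#' @param u unit vector from the particle receiving the force towards the
#'   other endpoint.
#' @param cap_mult force cap multiplier.
#' @return 3-vector force.
#' @examples
#' morse_force(2.5, 1, r = 0.5, r_eq = 0.5, u = c(1, 0, 0))  # zero at rest
#' @export
morse_force <- function(J, rho, r, r_eq, u, cap_mult = 10) {
  if (r <= 0) stop("r must be positive (coincident particles)")
  if (r_eq < 0) stop("r_eq must be non-negative")
  mag <- 2 * J * rho * (exp(2 * rho * (r - r_eq)) - exp(rho * (r - r_eq)))
  cap <- cap_mult * J * rho
  mag <- max(min(mag, cap), -cap)
  mag * u
}

#' Reference force computation (plain R)
#'
#' Computes, for every particle, the internal + cytoskeleton force sum, the
#' transmitted external force (the sum of linked partners' internal +
#' cytoskeleton forces), and the lumen repulsion where active.  This is a
#' direct, unoptimised transcription of the model equations, used as the
#' ground truth against which the compiled integrator is validated.
#'
#' @param pop a `sem_population`.
#' @param params a [sim_params()].
#' @return list with matrices `internal` (includes cytoskeleton and, for the
#'   intracellular particles, the reaction force), `external`, `specific`,
#'   and `total`.
#' @export
compute_forces <- function(pop, params = sim_params()) {
  n <- nrow(pop$pos)
  G <- matrix(0, n, 3)
  Jsp <- .spring_J(pop, params)
  for (s in seq_along(pop$springs$i)) {
    i <- pop$springs$i[s]; j <- pop$springs$j[s]
    d <- pop$pos[j, ] - pop$pos[i, ]
    r <- sqrt(sum(d^2))
    f <- morse_force(Jsp[s], params$rho, r, pop$springs$req[s], d / r,
                     params$force_cap_mult)
    G[i, ] <- G[i, ] + f
    G[j, ] <- G[j, ] - f
  }
  Fext <- matrix(0, n, 3)
  if (length(pop$links$a)) {
    for (k in seq_along(pop$links$a)) {
      a <- pop$links$a[k]; b <- pop$links$b[k]
      Fext[a, ] <- Fext[a, ] + G[b, ]
      Fext[b, ] <- Fext[b, ] + G[a, ]
    }
  }
  Fspe <- matrix(0, n, 3)
  if (!is.null(pop$lumen)) {
    for (i in pop$lumen$targets) {
      d <- pop$lumen$center - pop$pos[i, ]
      r <- sqrt(sum(d^2))
      if (r > 1e-12)
        Fspe[i, ] <- morse_force(pop$lumen$J, params$rho, r, pop$lumen$R_lum,
                                 d / r, params$force_cap_mult)
    }
  }
  list(internal = G, external = Fext, specific = Fspe,
       total = G + Fext + Fspe)
}

#' Advance the overdamped dynamics
#'
#' Integrates the first-order equations of motion with explicit Euler steps:
#' membrane particles move by `dt/lambda_med` times their total force
#' (internal + cytoskeleton + transmitted external + specific), the
#' intracellular particle by `dt/lambda_chi` times the reaction of its
#' cytoskeleton springs.  Adhesion links are refreshed every
#' `params$refresh_every` steps (pass `refresh = FALSE` to keep the current
#' links fixed).
#'
#' @param pop a `sem_population`.
#' @param params a [sim_params()].
#' @param n_steps number of steps.
#' @param applied optional constant per-particle load (n x 3 matrix).
#' @param refresh whether to periodically recompute adhesion links.
#' @return list with the advanced `pop` and the per-step elastic `energy`.
#' @export
advance <- function(pop, params = sim_params(), n_steps,
                    applied = NULL, refresh = TRUE) {
  Jsp <- .spring_J(pop, params)
  lambda <- .particle_lambda(pop, params)
  fap <- if (is.null(applied)) matrix(0, 0, 0) else applied
  lt <- if (is.null(pop$lumen)) integer(0) else as.integer(pop$lumen$targets)
  lc <- if (is.null(pop$lumen)) c(0, 0, 0) else pop$lumen$center
  lR <- if (is.null(pop$lumen)) 1 else pop$lumen$R_lum
  lJ <- if (is.null(pop$lumen)) 0 else pop$lumen$J
  energy <- numeric(0)
  chunk <- if (refresh) params$refresh_every else n_steps
  done <- 0L
  while (done < n_steps) {
    k <- min(chunk, n_steps - done)
    if (refresh) pop <- external_particle_neighbors(pop, params)
    res <- cpp_sem_steps(pop$pos,
                         pop$springs$i, pop$springs$j,
                         pop$springs$req, Jsp, params$rho, lambda,
                         pop$links$a, pop$links$b,
                         fap, lt, lc, lR, lJ,
                         as.integer(k), params$dt, params$force_cap_mult)
    pop$pos <- res$pos
    energy <- c(energy, res$energy)
    done <- done + k
  }
  list(pop = pop, energy = energy)
}
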
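#' In-silico stress-strain protocol for a single cell
#'
#' Estimates the emergent stiffness (Young modulus) of one epithelial cell.
#' A series of increasing equal-and-opposite axial loads is applied to the
#' apical and basal faces (the total force `F` split equally over the face
#' particles, directed along the polarity axis, tensile by default).  For
#' each load the overdamped dynamics are relaxed to equilibrium, the stress
#' `sigma = F / S` (with `S` the undeformed face area) and the strain
#' `epsilon = |L - L0| / L0` (with `L` the apico-basal height) are recorded,
#' and a line is fitted through the stress-strain points; its slope is the
#' Young modulus estimate `Y`.
#'
#' The force schedule scales linearly with `J` (default maximum
#' `0.5 * J`), which keeps the response in the small-strain regime and
#' makes the exact scaling `Y(cJ) = c Y(J)` hold at convergence.
#'
#' @param spec a [cell_shape_spec()].
#' @param params a [sim_params()]; `J_EPI` is the cell's interaction
#'   strength.
#' @param force_magnitudes increasing total force magnitudes starting at 0;
#'   default 10 values linearly spaced in `[0, 0.5 * J]`.
#' @param mode `"tensile"` (faces pulled apart) or `"compressive"`.
#' @param tol convergence: the relaxation stops when the elastic energy
#'   changes by less than `tol` per step over 100 consecutive steps.
#' @param max_steps relaxation budget per force level.
#' @return object of class `stress_strain_result`: list with `force`,
#'   `stress`, `strain`, `Y` (fitted slope), `intercept`, `R_value`
#'   (fit correlation), `converged`, `discontinuous` (TRUE when the
#'   strain response is not a well-behaved increasing curve, i.e. the
#'   parameter set does not behave like a physical material).
#' @export
stress_strain_protocol <- function(spec = cell_shape_spec(),
                                   params = sim_params(),
                                   force_magnitudes = NULL,
                                   mode = c("tensile", "compressive"),
                                   tol = 1e-8, max_steps = 1e5) {
  mode <- match.arg(mode)
  J <- params$J_EPI
  if (is.null(force_magnitudes))
    force_magnitudes <- seq(0, 0.5 * J, length.out = 10)
  stopifnot(force_magnitudes[1] == 0, !is.unsorted(force_magnitudes))
  cell <- build_epithelial_cell(spec, type = "EPI")
  pop0 <- new_population(list(cell))
  apical <- which(pop0$is_membrane & pop0$labels == "apical")
  basal <- which(pop0$is_membrane & pop0$labels == "basal")
  S <- face_area(cell, "apical")
  axis <- cell$frame[, 3]
  sgn <- if (mode == "tensile") 1 else -1
  height <- function(pop) {
    ha <- colMeans(pop$pos[apical, , drop = FALSE])
    hb <- colMeans(pop$pos[basal, , drop = FALSE])
    abs(sum((hb - ha) * axis))
  }
  L0 <- height(pop0)
  strain <- numeric(length(force_magnitudes))
  converged <- logical(length(force_magnitudes))
  for (k in seq_along(force_magnitudes)) {
    Fm <- force_magnitudes[k]
    if (Fm == 0) { strain[k] <- 0; converged[k] <- TRUE; next }
    load <- matrix(0, nrow(pop0$pos), 3)
    load[apical, ] <- matrix(-sgn * Fm / length(apical) * axis,
                             length(apical), 3, byrow = TRUE)
    load[basal, ] <- matrix(sgn * Fm / length(basal) * axis,
                            length(basal), 3, byrow = TRUE)
    pop <- pop0
    done <- 0L
    ok <- FALSE
    res <- NULL
    while (done < max_steps) {
      chunk <- 1000L
      res <- tryCatch(advance(pop, params, chunk, applied = load,
                              refresh = FALSE),
                      error = function(e) NULL)
      if (is.null(res)) break                    # numerical blow-up
      pop <- res$pop
      done <- done + chunk
      e <- res$energy
      if (all(abs(diff(e[(chunk - 100):chunk])) < tol)) { ok <- TRUE; break }
    }
    if (is.null(res) || !all(is.finite(pop$pos))) {
      strain[k] <- NA_real_; converged[k] <- FALSE
    } else {
      strain[k] <- abs(height(pop) - L0) / L0
      converged[k] <- ok
    }
  }
  stress <- force_magnitudes / S
  disc <- any(!converged) || anyNA(strain) ||
    any(diff(strain) <= 0 & diff(force_magnitudes) > 0)
  usable <- is.finite(strain)
  fit_Y <- fit_b <- rv <- NA_real_
  if (sum(usable) >= 3 && !disc) {
    fit <- lm(stress[usable] ~ strain[usable])
    fit_Y <- unname(coef(fit)[2])
    fit_b <- unname(coef(fit)[1])
    rv <- cor(strain[usable], stress[usable])
  }
  structure(list(force = force_magnitudes, stress = stress, strain = strain,
                 Y = fit_Y, intercept = fit_b, R_value = rv,
                 converged = converged, discontinuous = disc,
                 S = S, L0 = L0, mode = mode, spec = spec, params = params),
            class = "stress_strain_result")
}

#' @export
print.stress_strain_result <- function(x, ...) {
  if (x$discontinuous)
    cat("stress_strain_result: discontinuous response (no modulus defined)\n")
  else
    cat(sprintf("stress_strain_result: Y = %.4f (intercept %.4f, R = %.4f), %d loads, %s\n",
                x$Y, x$intercept, x$R_value, length(x$force), x$mode))
  invisible(x)
}

#' Young modulus as a function of interaction strength J
#'
#' Runs the stress-strain protocol for each value of `J`; the emergent
#' stiffness increases with the interaction strength between sub-cellular
#' particles.
#'
#' @param spec a [cell_shape_spec()].
#' @param J_values interaction strengths to probe.
#' @param params base [sim_params()].
#' @return data.frame with columns `J` and `Y`.
#' @export
sweep_young_vs_J <- function(spec = cell_shape_spec(), J_values,
                             params = sim_params()) {
  stopifnot(length(J_values) >= 1)
  Y <- vapply(J_values, function(J) {
    p <- params; p$J_EPI <- J
    stress_strain_protocol(spec, p)$Y
  }, 0)
  data.frame(J = J_values, Y = Y)
}

#' Young modulus as a function of the friction-coefficient ratio
#'
#' Fixes `lambda_med`, varies `lambda_chi`, and records the modulus as a
#' function of `lambda_chi / lambda_med`.  Above a critical ratio the
#' modulus is constant; below it the intracellular particle destabilises
#' the explicit integration, the cell structure is compromised and the
#' stress-strain curve is flagged discontinuous (no modulus defined).
#'
#' @param spec a [cell_shape_spec()].
#' @param ratio_values ratios `lambda_chi / lambda_med` to probe.
#' @param lambda_med fixed medium friction.
#' @param params base [sim_params()].
#' @param locate_critical when `TRUE`, bisect between the largest failing
#'   and smallest passing ratio to localise the critical ratio.
#' @param bisect_tol resolution of the bisection.
#' @return list with `table` (data.frame `ratio`, `Y`, `defined`) and
#'   `critical_ratio` (NA when not bracketed or not requested).
#' @export
sweep_friction_ratio <- function(spec = cell_shape_spec(), ratio_values,
                                 lambda_med = 2, params = sim_params(),
                                 locate_critical = TRUE, bisect_tol = 0.01) {
  probe <- function(ratio) {
    p <- params
    p$lambda_med <- lambda_med
    p$lambda_chi <- ratio * lambda_med
    stress_strain_protocol(spec, p)
  }
  res <- lapply(ratio_values, probe)
  tab <- data.frame(ratio = ratio_values,
                    Y = vapply(res, `[[`, 0, "Y"),
                    defined = !vapply(res, `[[`, TRUE, "discontinuous"))
  critical <- NA_real_
  if (locate_critical) {
    lo <- suppressWarnings(max(tab$ratio[!tab$defined]))
    hi <- suppressWarnings(min(tab$ratio[tab$defined]))
    if (is.finite(lo) && is.finite(hi) && lo < hi) {
      while (hi - lo > bisect_tol) {
        mid <- (lo + hi) / 2
        if (probe(mid)$discontinuous) lo <- mid else hi <- mid
      }
      critical <- (lo + hi) / 2
    }
  }
  list(table = tab, critical_ratio = critical)
}

#' Trophectoderm-stiffness sweep of the implantation scenario
#'
#' Runs the implantation scenario without lumenogenesis or detachment for
#' each trophectoderm interaction strength `J_TE` (epiblast strength held
#' fixed), records the final interface curvature `theta`, interface ratio
#' `Ir` and pushing distance `H`, and computes the normalised fitness `M`
#' against the sweep's own optima.
#'
#' @param jte_values trophectoderm interaction strengths.
#' @param j_epi fixed epiblast interaction strength.
#' @param params base [sim_params()] for the population runs.
#' @param scenario scenario template (defaults to the no-lumen preset).
#' @return data.frame with columns `J_TE`, `theta`, `Ir`, `H`, `M`.
#' @export
sweep_jte <- function(jte_values, j_epi = 2.5,
                      params = sim_params(),
                      scenario = implantation_scenario("implantation-no-lumen")) {
  stopifnot(length(jte_values) >= 2)
  one <- function(jte) {
    p <- params; p$J_TE <- jte; p$J_EPI <- j_epi
    run <- run_scenario(scenario, p)
    last <- run$metrics[nrow(run$metrics), ]
    c(theta = last$theta, Ir = last$ratio, H = last$pd_lowest)
  }
  m <- t(vapply(jte_values, one, c(theta = 0, Ir = 0, H = 0)))
  out <- data.frame(J_TE = jte_values, theta = m[, "theta"],
                    Ir = m[, "Ir"], H = m[, "H"])
  out$M <- fitness_metric(out$theta, out$Ir, out$H)
  out
}
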
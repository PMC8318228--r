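# Shared fixtures: tiny populations built in code.

# One isolated columnar cell as a population.
single_cell_pop <- function(spec = cell_shape_spec()) {
  new_population(list(build_epithelial_cell(spec)))
}

# Two abutting cells on neighbouring lattice sites, faces within adhesion
# range, with links established.  Cell 1 EPI at origin, cell 2 of `type_b`
# stacked above (apical face down towards cell 1's basal face).
two_cell_pop <- function(type_b = "EPI", gap = 0.1,
                         params = sim_params()) {
  spec <- cell_shape_spec(R = 0.5, h = 1)
  a <- build_epithelial_cell(spec, center = c(0, 0, 0),
                             polarity = c(0, 0, 1), type = "EPI")
  a$lattice <- c(0L, 0L, 0L)
  b <- build_epithelial_cell(spec, center = c(0, 0, spec$h + gap),
                             polarity = c(0, 0, 1), type = type_b)
  b$lattice <- c(0L, 0L, 1L)
  pop <- new_population(list(a, b))
  external_particle_neighbors(pop, params)
}

# Deterministically scrambled positions for perturbation tests.
perturb <- function(pop, scale = 0.05, seed = 42) {
  set.seed(seed)
  pop$pos <- pop$pos + matrix(stats::rnorm(length(pop$pos), sd = scale),
                              nrow(pop$pos), 3)
  pop
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
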
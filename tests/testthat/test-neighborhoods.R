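test_that("Moore neighbourhood counts match the lattice geometry", {
  full <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  pairs <- moore_cell_neighbors(full)
  center <- which(full[, 1] == 0 & full[, 2] == 0 & full[, 3] == 0)
  expect_equal(sum(pairs[, 1] == center | pairs[, 2] == center), 26)
  sheet <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = 0))
  ps <- moore_cell_neighbors(sheet)
  cs <- which(sheet[, 1] == 0 & sheet[, 2] == 0)
  expect_equal(sum(ps[, 1] == cs | ps[, 2] == cs), 8)
  expect_equal(nrow(moore_cell_neighbors(matrix(c(0, 0, 0), 1))), 0)
  expect_error(moore_cell_neighbors(rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})

test_that("gated link search agrees with the all-pairs brute-force oracle", {
  p <- sim_params(max_links = 3)   # exercise the quota logic too
  pop <- perturb(two_cell_pop(params = p), 0.05)
  g <- external_particle_neighbors(pop, p, method = "gated")
  b <- external_particle_neighbors(pop, p, method = "brute")
  key <- function(l) sort(paste(pmin(l$links$a, l$links$b),
                                pmax(l$links$a, l$links$b)))
  expect_identical(key(g), key(b))
})

test_that("links join distinct cells only, respect the cutoff and the quota", {
  p <- sim_params(max_links = 2)
  pop <- external_particle_neighbors(perturb(two_cell_pop(), 0.02), p)
  expect_gt(length(pop$links$a), 0)
  expect_true(all(pop$cell_of[pop$links$a] != pop$cell_of[pop$links$b]))
  d <- sqrt(rowSums((pop$pos[pop$links$a, , drop = FALSE] -
                     pop$pos[pop$links$b, , drop = FALSE])^2))
  expect_true(all(d < p$adhesion_cutoff))
  expect_true(all(table(c(pop$links$a, pop$links$b)) <= p$max_links))
})

test_that("cells beyond the cutoff acquire no links", {
  spec <- cell_shape_spec(R = 0.5, h = 1)
  a <- build_epithelial_cell(spec, center = c(0, 0, 0))
  a$lattice <- c(0L, 0L, 0L)
  b <- build_epithelial_cell(spec, center = c(0, 0, 3))
  b$lattice <- c(0L, 0L, 1L)
  pop <- external_particle_neighbors(new_population(list(a, b)))
  expect_equal(length(pop$links$a), 0)
})

test_that("abutting faces acquire links on shared-face particles", {
  pop <- two_cell_pop(gap = 0.1)
  # cell 1 basal face against cell 2 apical face: links should involve them
  lab_a <- pop$labels[pop$links$a]
  lab_b <- pop$labels[pop$links$b]
  expect_true(all(lab_a %in% c("basal", "apical") |
                  lab_b %in% c("basal", "apical")))
  expect_gt(length(pop$links$a), 4)
})

test_that("break_adhesion removes cross-type forces and never reactivates", {
  p <- sim_params()
  pop <- perturb(two_cell_pop(type_b = "TE"), 0.04)
  pop <- break_adhesion(pop, "TE", "EPI")
  expect_equal(length(pop$links$a), 0)
  # refresh does not bring the links back
  pop <- external_particle_neighbors(pop, p)
  expect_equal(length(pop$links$a), 0)
  expect_equal(max(abs(compute_forces(pop, p)$external)), 0)
  expect_error(break_adhesion(pop, "TE", "XX"), "unknown cell type")
  # breaking a pair with no links is a no-op
  lone <- single_cell_pop()
  expect_silent(break_adhesion(lone, "EPI", "EPI"))
})

test_that("with all cross links broken each tissue evolves as if simulated alone", {
  p <- sim_params()
  pop <- perturb(two_cell_pop(type_b = "TE"), 0.04)
  pop <- break_adhesion(pop, "TE", "EPI")
  joint <- advance(pop, p, 100)$pop
  # the EPI cell alone, from the same initial coordinates
  alone <- single_cell_pop(cell_shape_spec(R = 0.5, h = 1))
  n1 <- nrow(alone$pos)
  alone$pos <- pop$pos[seq_len(n1), , drop = FALSE]
  alone$springs$req <- pop$springs$req[pop$springs$cell == 1]
  ares <- advance(alone, p, 100)$pop
  expect_identical(joint$pos[seq_len(n1), ], ares$pos)
})

test_that("adhesion graph export lists every active link", {
  pop <- two_cell_pop()
  g <- adhesion_graph(pop, t = 7L)
  expect_equal(nrow(g), length(pop$links$a))
  expect_true(all(g$active))
  expect_true(all(g$t == 7L))
})
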
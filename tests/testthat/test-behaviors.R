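test_that("retargeting to the current shape changes nothing", {
  pop <- single_cell_pop(cell_shape_spec(R = 0.5, h = 1))
  req0 <- pop$springs$req
  pos0 <- pop$pos
  pop <- retarget_shape(pop, 1, cell_shape_spec(R = 0.5, h = 1))
  expect_equal(pop$springs$req, req0, tolerance = 1e-12)
  expect_identical(pop$pos, pos0)
  expect_equal(elastic_energy(pop), 0, tolerance = 1e-12)
})

test_that("cuboidal-to-columnar retargeting doubles axial equilibrium lengths, positions untouched", {
  pop <- single_cell_pop(cell_shape_spec(R = 0.5, h = 1))
  pos0 <- pop$pos
  # spring between vertically aligned ring particles (ring 1 and ring 2,
  # same azimuth): template rows 2 and 10
  s <- which(pop$springs$i == 2 & pop$springs$j == 10)
  req_before <- pop$springs$req[s]
  pop <- retarget_shape(pop, 1, cell_shape_spec(R = 0.5, h = 2))
  expect_equal(pop$springs$req[s], 2 * req_before, tolerance = 1e-12)
  expect_identical(pop$pos, pos0)
  expect_error(retarget_shape(pop, 1, cell_shape_spec(n_vertices = 42,
                                                      basis = "square")),
               "incompatible mesh family")
})

test_that("after retargeting, relaxation reaches the target height within 5%", {
  pop <- single_cell_pop(cell_shape_spec(R = 0.5, h = 1))
  pop <- retarget_shape(pop, 1, cell_shape_spec(R = 0.5, h = 2))
  pop <- advance(pop, sim_params(), 8000, refresh = FALSE)$pop
  ap <- colMeans(pop$pos[which(pop$labels == "apical"), ])
  ba <- colMeans(pop$pos[which(pop$labels == "basal"), ])
  expect_equal(sqrt(sum((ba - ap)^2)), 2, tolerance = 0.05)
})

test_that("apical constriction rescales apical springs by the target geometry", {
  spec <- cell_shape_spec(R = 0.5, h = 2)
  pop <- single_cell_pop(spec)
  req0 <- pop$springs$req
  # d = 0 leaves everything unchanged
  pop0 <- apical_constriction_targets(pop, 1, 0)
  expect_equal(pop0$springs$req, req0, tolerance = 1e-12)
  # d = R/2: apical ring chords scale by (R-d)/R = 1/2; the apico-lateral
  # spring matches the distance from the displaced apical vertex to the
  # unmoved ring-2 vertex (geometric oracle)
  pop1 <- apical_constriction_targets(pop, 1, spec$R / 2)
  chord <- which(pop1$springs$i == 2 & pop1$springs$j == 3)
  expect_equal(pop1$springs$req[chord], req0[chord] / 2, tolerance = 1e-12)
  apiclat <- which(pop1$springs$i == 2 & pop1$springs$j == 10)
  tmpl <- pop$cells[[1]]$template
  moved <- tmpl[2, ] * c(0.5, 0.5, 1)
  expect_equal(pop1$springs$req[apiclat],
               sqrt(sum((tmpl[10, ] - moved)^2)), tolerance = 1e-12)
  # basal springs untouched
  basal_chord <- which(pop1$springs$i == 26 & pop1$springs$j == 27)
  expect_equal(pop1$springs$req[basal_chord], req0[basal_chord],
               tolerance = 1e-12)
  # full constriction collapses the apical ring
  pop2 <- apical_constriction_targets(pop, 1, spec$R)
  expect_lt(pop2$springs$req[chord], 1e-9)
  # involution: re-applying d = 0 restores the original equilibrium set
  pop3 <- apical_constriction_targets(pop2, 1, 0)
  expect_equal(pop3$springs$req, req0, tolerance = 1e-12)
  expect_error(apical_constriction_targets(pop, 1, spec$R + 0.1),
               "0 <= d <= R")
})

test_that("step constriction profile marks interior cells only", {
  spec <- cell_shape_spec(R = 0.5, h = 1)
  mk <- function(n) {
    cells <- list()
    half <- (n - 1) / 2
    for (ix in -half:half) for (iy in -half:half) {
      cell <- build_epithelial_cell(spec, center = c(ix, iy, 0), type = "TE")
      cell$lattice <- c(as.integer(ix), as.integer(iy), 0L)
      cells[[length(cells) + 1]] <- cell
    }
    new_population(cells)
  }
  p3 <- positional_constriction_profile(mk(3), "TE")
  expect_equal(sum(p3$d == spec$R), 1)
  expect_equal(sum(p3$d == 0), 8)
  expect_true(all(p3$d %in% c(0, spec$R)))
  p5 <- positional_constriction_profile(mk(5), "TE")
  expect_equal(sum(p5$d == spec$R), 9)
  p1 <- positional_constriction_profile(mk(1), "TE")
  expect_equal(p1$d, spec$R)
  expect_error(positional_constriction_profile(mk(1), "EPI"), "no cells")
})

test_that("lumen repulsion is zero on the shell, outward inside, and matches the formula", {
  p <- sim_params()
  src <- list(center = c(0, 0, 0), R_lum = 0.25, J = 2.5)
  expect_equal(lumen_repulsion_force(src, c(0.25, 0, 0), p), c(0, 0, 0),
               tolerance = 1e-12)
  f <- lumen_repulsion_force(src, c(0.1, 0, 0), p)
  expect_gt(f[1], 0)                               # pushed away from the source
  expect_equal(sqrt(sum(f^2)),
               abs(2 * 2.5 * 1 * (exp(-0.3) - exp(-0.15))), tolerance = 1e-12)
  # beyond the shell the particle is drawn back towards it
  f2 <- lumen_repulsion_force(src, c(0.5, 0, 0), p)
  expect_lt(f2[1], 0)
})

test_that("open_lumen installs the source, breaks apical pairs and targets apical particles only", {
  p <- sim_params()
  pop <- build_rosette_epiblast(grid = 3, relax_steps = 200, params = p)
  pop <- external_particle_neighbors(pop, p)
  v0 <- lumen_volume(pop)
  expect_equal(v0, 0)                              # no lumen before opening
  pop <- open_lumen(pop, "EPI", params = p)
  expect_true(!is.null(pop$lumen))
  expect_true(all(pop$labels[pop$lumen$targets] == "apical"))
  f <- compute_forces(pop, p)
  act <- which(rowSums(abs(f$specific)) > 0)
  expect_true(all(act %in% pop$lumen$targets))
  # apical-apical pairs stay excluded from refreshed links
  pop <- external_particle_neighbors(pop, p)
  t <- logical(nrow(pop$pos)); t[pop$lumen$targets] <- TRUE
  expect_false(any(t[pop$links$a] & t[pop$links$b]))
  # hollowing: the cavity inflates over time
  v1 <- lumen_volume(pop)
  pop <- advance(pop, p, 800)$pop
  expect_gt(lumen_volume(pop), v1)
})
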
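semicircle <- function(n = 51, r = 1, center = c(0, 0)) {
  a <- seq(0, pi, length.out = n)
  cbind(x = center[1] + r * cos(a), z = center[2] + r * sin(a))
}

rot2 <- function(p, ang) {
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  p %*% R
}

test_that("interface curvature: collinear 180, semicircle 90, rigid-motion invariant", {
  line <- cbind(x = seq(0, 1, length.out = 7), z = rep(0.3, 7))
  expect_equal(interface_curvature(line), 180, tolerance = 1e-9)
  expect_equal(interface_curvature(semicircle()), 90, tolerance = 0.5)
  p <- semicircle(31, r = 2)
  expect_equal(interface_curvature(rot2(p, 0.7)), interface_curvature(p),
               tolerance = 1e-9)
  # reversing the traversal direction changes nothing
  expect_equal(interface_curvature(p[rev(seq_len(nrow(p))), ]),
               interface_curvature(p), tolerance = 1e-9)
  expect_error(interface_curvature(line[1:2, ]), "3 points")
})

test_that("interface ratio: straight 1, semicircle pi/2, scale invariant", {
  line <- cbind(x = c(0, 0.4, 1), z = c(0, 0, 0))
  expect_equal(unname(interface_ratio(line)["ratio"]), 1, tolerance = 1e-12)
  expect_equal(unname(interface_ratio(semicircle(201))["ratio"]), pi / 2,
               tolerance = 1e-3)
  p <- semicircle(31)
  expect_equal(interface_ratio(p * 3.7)[["ratio"]], interface_ratio(p)[["ratio"]],
               tolerance = 1e-12)
  expect_error(interface_ratio(rbind(c(0, 0), c(0, 0))), "degenerate")
})

test_that("curvature and ratio approach their flat limits together", {
  # progressively flattened arcs: theta -> 180 while L/D -> 1
  sag <- c(1, 0.5, 0.2, 0.05)
  th <- ld <- numeric(length(sag))
  for (k in seq_along(sag)) {
    a <- seq(-1, 1, length.out = 41)
    p <- cbind(x = a, z = sag[k] * (1 - a^2))
    th[k] <- interface_curvature(p)
    ld[k] <- interface_ratio(p)[["ratio"]]
  }
  expect_true(all(diff(th) > 0))
  expect_true(all(diff(ld) < 0))
  expect_gt(th[length(sag)], 170)
  expect_lt(ld[length(sag)], 1.005)
})

test_that("pushing distances are zero at reference and track rigid displacement", {
  pop <- two_cell_pop(type_b = "TE")
  ref <- reference_state(pop)
  expect_equal(unname(pushing_distance(pop, ref)), c(0, 0, 0))
  pop$pos[, 3] <- pop$pos[, 3] - 0.7
  expect_equal(unname(pushing_distance(pop, ref)), rep(0.7, 3),
               tolerance = 1e-12)
})

test_that("lumen volume reproduces the sphere and is zero without a lumen", {
  pop <- single_cell_pop()
  expect_equal(lumen_volume(pop), 0)
  # place the membrane particles on a sphere of radius r around the source
  r <- 0.4
  n <- sum(pop$is_membrane)
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  th <- pi * (1 + sqrt(5)) * i
  pop$pos[pop$is_membrane, ] <- r * cbind(cos(th) * sin(phi),
                                          sin(th) * sin(phi), cos(phi))
  pop$lumen <- list(center = c(0, 0, 0), R_lum = r, J = 2.5,
                    targets = which(pop$is_membrane))
  expect_equal(lumen_volume(pop), 4 / 3 * pi * r^3, tolerance = 1e-6)
})

test_that("interface extraction orders points by angle, independent of particle order", {
  pop <- two_cell_pop(type_b = "TE")
  pl <- interface_extract(pop, reach = 0.25)
  expect_gte(nrow(pl), 3)
  # abutting flat faces give a near-straight interface segment
  expect_gt(interface_curvature(pl), 180 - 25)
  expect_lt(interface_ratio(pl)[["ratio"]], 1.2)
})

test_that("fitness metric attains 0 and 1 at the sweep optima and stays inside [0,1]", {
  theta <- c(100, 120, 180, 140)
  Ir <- c(2.0, 1.5, 1.0, 1.2)
  H <- c(0.0, 0.2, 0.5, 0.3)
  M <- fitness_metric(theta, Ir, H)
  expect_equal(M[3], 0)     # attains every optimum
  expect_equal(M[1], 1)     # attains every pessimum
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(M[c(2, 4)] > 0 & M[c(2, 4)] < 1))
  expect_error(fitness_metric(c(1, 1), c(1, 2), c(1, 2)), "degenerate")
})
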
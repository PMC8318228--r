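test_that("morse force matches the scalar formula and sign convention", {
  u <- c(1, 0, 0)
  expect_equal(morse_force(2.5, 1, r = 0.5, r_eq = 0.5, u = u), c(0, 0, 0))
  # direct scalar evaluation at r = 1, r_eq = 0.5
  f <- morse_force(2.5, 1, r = 1, r_eq = 0.5, u = u, cap_mult = 1e6)
  expect_equal(sqrt(sum(f^2)), 2 * 2.5 * 1 * (exp(1) - exp(0.5)),
               tolerance = 1e-12)
  # stretched spring pulls towards the partner (+u), compressed pushes away
  expect_gt(morse_force(1, 1, 1.2, 1, u)[1], 0)
  expect_lt(morse_force(1, 1, 0.8, 1, u)[1], 0)
  expect_error(morse_force(1, 1, 0, 1, u), "positive")
})

test_that("a freshly built cell is at rest: zero forces, zero energy", {
  pop <- single_cell_pop()
  f <- compute_forces(pop)
  expect_equal(max(abs(f$total)), 0, tolerance = 1e-10)
  expect_equal(elastic_energy(pop), 0, tolerance = 1e-12)
})

test_that("internal + cytoskeleton forces conserve momentum and obey action-reaction", {
  pop <- perturb(single_cell_pop(), 0.05)
  f <- compute_forces(pop)
  # pairwise action-reaction makes the per-cell force sum vanish
  expect_equal(colSums(f$internal), c(0, 0, 0), tolerance = 1e-9)
  # the intracellular particle carries exactly minus the sum of the
  # cytoskeleton forces on the membrane particles (recomputed by hand)
  p <- sim_params()
  chi <- nrow(pop$pos)
  cyto <- matrix(0, 1, 3)
  for (i in seq_len(chi - 1)) {
    d <- pop$pos[chi, ] - pop$pos[i, ]
    r <- sqrt(sum(d^2))
    s <- which(pop$springs$i == i & pop$springs$j == chi)
    cyto <- cyto + morse_force(p$J_EPI, p$rho, r, pop$springs$req[s], d / r,
                               p$force_cap_mult)
  }
  expect_equal(as.numeric(f$internal[chi, ]), as.numeric(-cyto),
               tolerance = 1e-9)
})

test_that("uniformly inflating a resting cell makes all membrane forces point inward", {
  pop <- single_cell_pop()
  center <- colMeans(pop$pos)
  pop$pos <- sweep(sweep(pop$pos, 2, center, `-`) * 1.1, 2, center, `+`)
  f <- compute_forces(pop)
  outward <- sweep(pop$pos, 2, center, `-`)
  mem <- which(pop$is_membrane)
  proj <- rowSums(f$internal[mem, ] * outward[mem, ])
  expect_true(all(proj < 0))
})

test_that("forces are invariant under rigid translation of the population", {
  pop <- perturb(two_cell_pop(), 0.03)
  f1 <- compute_forces(pop)
  pop2 <- pop
  pop2$pos <- sweep(pop2$pos, 2, c(3.2, -1.7, 0.9), `+`)
  f2 <- compute_forces(pop2)
  expect_equal(f1$total, f2$total, tolerance = 1e-9)
})

test_that("external transmission gives linked partners each other's intrinsic force", {
  pop <- perturb(two_cell_pop(), 0.03)
  f <- compute_forces(pop)
  expect_gt(length(pop$links$a), 0)
  # every particle's external force equals the sum of its partners' internal
  # force sums, evaluated independently here
  cnt <- table(c(pop$links$a, pop$links$b))
  one <- as.integer(names(cnt)[cnt == 1])
  k <- which(pop$links$a == one[1] | pop$links$b == one[1])[1]
  i <- pop$links$a[k]; j <- pop$links$b[k]
  expect_equal(as.numeric(f$external[i, ]), as.numeric(f$internal[j, ]),
               tolerance = 1e-12)
  expect_equal(as.numeric(f$external[j, ]), as.numeric(f$internal[i, ]),
               tolerance = 1e-12)
})

test_that("isolated and resting configurations transmit zero external force", {
  lone <- single_cell_pop()
  expect_equal(max(abs(compute_forces(lone)$external)), 0)
  resting <- two_cell_pop()      # both cells at their resting state
  expect_equal(max(abs(compute_forces(resting)$external)), 0,
               tolerance = 1e-10)
})

test_that("compiled integrator reproduces the plain-R reference step for step", {
  p <- sim_params()
  pop <- perturb(two_cell_pop(), 0.03)
  popc <- pop
  for (k in 1:5) {
    f <- compute_forces(popc, p)
    lam <- ifelse(popc$is_membrane, p$lambda_med, p$lambda_chi)
    popc$pos <- popc$pos + p$dt * f$total / lam
  }
  res <- advance(pop, p, 5, refresh = FALSE)
  expect_equal(res$pop$pos, popc$pos, tolerance = 1e-12)
})

test_that("elastic energy: single stretched spring contributes its squared extension", {
  pop <- single_cell_pop()
  s <- 1L
  i <- pop$springs$i[s]
  # stretch one spring endpoint along the spring axis by delta
  delta <- 0.07
  j <- pop$springs$j[s]
  u <- pop$pos[j, ] - pop$pos[i, ]
  u <- u / sqrt(sum(u^2))
  pop2 <- pop
  pop2$springs$req[s] <- pop$springs$req[s] + delta
  expect_equal(elastic_energy(pop2), delta^2, tolerance = 1e-12)
  # per-cell decomposition sums to the total (full-sum oracle)
  popp <- perturb(two_cell_pop(), 0.05)
  expect_equal(sum(elastic_energy(popp, by = "cell")), elastic_energy(popp),
               tolerance = 1e-9)
  d <- popp$pos[popp$springs$j, ] - popp$pos[popp$springs$i, ]
  brute <- sum((popp$springs$req - sqrt(rowSums(d^2)))^2)
  expect_equal(elastic_energy(popp), brute, tolerance = 1e-12)
})

test_that("relaxation of a perturbed cell dissipates elastic energy", {
  pop <- perturb(single_cell_pop(), 0.08)
  res <- advance(pop, sim_params(), 2000, refresh = FALSE)
  e <- res$energy
  expect_lt(e[length(e)], 0.01 * e[1])
  # monotone non-increasing up to tiny integrator overshoot
  expect_true(all(diff(e) < 1e-8))
})

test_that("doubling the membrane friction halves the per-step displacement", {
  pop <- perturb(single_cell_pop(), 0.05)
  p1 <- sim_params()
  p2 <- sim_params(lambda_med = 2 * p1$lambda_med,
                   lambda_chi = 2 * p1$lambda_chi)
  d1 <- advance(pop, p1, 1, refresh = FALSE)$pop$pos - pop$pos
  d2 <- advance(pop, p2, 1, refresh = FALSE)$pop$pos - pop$pos
  expect_equal(d1, 2 * d2, tolerance = 1e-12)
})

test_that("trajectories are deterministic and byte-identical across reruns", {
  pop <- perturb(two_cell_pop(), 0.04)
  p <- sim_params()
  r1 <- advance(pop, p, 200)
  r2 <- advance(pop, p, 200)
  expect_identical(r1$pop$pos, r2$pop$pos)
  expect_identical(r1$energy, r2$energy)
})
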
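test_that("occupancy solver matches the independent bisection oracle", {
  # oracle value computed by bisection on the fixed-point residual
  th_oracle <- mvh_bisect_oracle(2.3, K_D = 2.3, omega = 23, n = 26)
  sol <- mvh_occupancy(2.3, std_binding())
  expect_equal(sol$theta, th_oracle, tolerance = 1e-8)
  # a second, less symmetric point
  th2 <- mvh_bisect_oracle(0.4, K_D = 1.7, omega = 8, n = 15)
  expect_equal(mvh_occupancy(0.4, binding_params(1.7, 8, 15))$theta, th2,
               tolerance = 1e-8)
})

test_that("occupancy solver obeys limits and self-checks", {
  bp <- std_binding()
  expect_identical(mvh_occupancy(0, bp)$theta, 0)
  # Langmuir reduction at n = 1, omega = 1
  bl <- binding_params(K_D = 5, omega = 1, n = 1)
  cg <- seq(0, 500, length.out = 41)
  expect_equal(mvh_occupancy(cg, bl)$theta, cg / (5 + cg), tolerance = 1e-10)
  # nondecreasing in concentration, saturating below 1
  cc <- c(0, 10^seq(-3, 3, by = 0.25))
  th <- mvh_occupancy(cc, bp)$theta
  expect_true(all(diff(th) >= 0))
  expect_true(all(th < 1))
  # residual self-check over a random parameter sweep
  set.seed(42)
  for (i in 1:20) {
    bpi <- binding_params(K_D = 10^runif(1, -1, 2), omega = 10^runif(1, 0, 2.5),
                          n = sample(1:30, 1))
    sol <- mvh_occupancy(10^runif(3, -2, 2), bpi)
    expect_true(all(sol$residual <= 1e-8))
  }
  # near-unity cooperativity falls back to the non-cooperative closed form
  th_a <- mvh_occupancy(3, binding_params(5, 1 + 1e-7, 10))$theta
  th_b <- mvh_occupancy(3, binding_params(5, 1, 10))$theta
  expect_equal(th_a, th_b, tolerance = 1e-6)
  expect_error(mvh_occupancy(-1, bp), "non-negative")
})

test_that("occupancy maps interpolate between free and saturated endpoints", {
  expect_equal(occupancy_map_P(0, 50, 10), 50)
  expect_equal(occupancy_map_P(1, 50, 10), 10)
  expect_equal(occupancy_map_P(0.5, 50, 10), 500 / 30, tolerance = 1e-12)
  th <- seq(0, 1, by = 0.05)
  expect_true(all(diff(occupancy_map_P(th, 50, 10)) < 0))
  expect_equal(occupancy_map_linear(0, 0.34, 0.40), 0.34)
  expect_equal(occupancy_map_linear(1, 0.34, 0.40), 0.40)
  expect_equal(occupancy_map_linear(0.25, 0.34, 0.40), 0.355, tolerance = 1e-12)
  expect_error(occupancy_map_P(1.5, 50, 10), "theta")
})

test_that("occupancy inversion from persistence length round-trips", {
  expect_equal(invert_occupancy_from_P(59, 59, 7.1), 0)
  expect_equal(invert_occupancy_from_P(7.1, 59, 7.1), 1)
  # the 39 nm observation maps to ~0.07 when the saturated value is ~7.08 nm
  P_L <- 7.0838
  th <- invert_occupancy_from_P(39, 59, P_L)
  expect_equal(th, 0.07, tolerance = 1e-3)
  expect_equal(occupancy_map_P(th, 59, P_L), 39, tolerance = 1e-9)
  expect_error(invert_occupancy_from_P(80, 59, 7.1), "range")
})

test_that("cluster size: dilute non-cooperative limit is a monomer", {
  bp <- binding_params(K_D = 10, omega = 1, n = 6)
  r <- mean_cluster_size(0.001, bp, "exact", lattice_sites = 300)
  expect_lt(r$mean_cluster_size, 1.05)
  expect_gte(r$mean_cluster_size, 1)
})

test_that("exact and Monte-Carlo cluster sizes agree on a 60-site lattice", {
  bp <- binding_params(K_D = 2.3, omega = 23, n = 4)
  ex <- mean_cluster_size(2.3, bp, "exact", lattice_sites = 60)
  mc <- suppressWarnings(
    mean_cluster_size(2.3, bp, "montecarlo", lattice_sites = 60,
                      seed = 21, sweeps = 4000, chains = 8))
  expect_lt(abs(mc$mean_cluster_size - ex$mean_cluster_size), 3 * mc$se)
})

test_that("clustering increases with cooperativity", {
  lo <- mean_cluster_size(1, binding_params(2.3, 23, 6), "exact", lattice_sites = 600)
  hi <- mean_cluster_size(1, binding_params(2.3, 1000, 6), "exact", lattice_sites = 600)
  expect_gt(hi$mean_cluster_size, 3 * lo$mean_cluster_size)
})

test_that("transfer-matrix occupancy approaches the isotherm on long lattices", {
  bp <- std_binding()
  r <- mean_cluster_size(0.07, bp, "exact", lattice_sites = 10000)
  expect_equal(r$theta, mvh_occupancy(0.07, bp)$theta, tolerance = 0.01)
})

test_that("Monte-Carlo occupancy on a ring matches the isotherm", {
  bp <- std_binding()
  for (cc in c(0.03, 0.15)) {
    mc <- suppressWarnings(
      mean_cluster_size(cc, bp, "montecarlo", lattice_sites = 1040,
                        seed = 7, sweeps = 400, chains = 4, boundary = "circular"))
    expect_lt(abs(mc$theta - mvh_occupancy(cc, bp)$theta), 3 * mc$theta_se)
  }
})

test_that("cluster-size size limits are enforced", {
  bp <- std_binding()
  expect_error(mean_cluster_size(1, bp, "exact", lattice_sites = 50000), "capped")
  expect_error(mean_cluster_size(1, bp, "montecarlo", lattice_sites = 100), "10 \\* n")
  expect_error(binding_params(2, 23, 2.5), "integer")
})
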
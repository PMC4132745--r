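test_that("noiseless titrations are inverted to the generator truth", {
  bp <- binding_params(K_D = 2, omega = 20, n = 26)
  sim <- simulate_titration(bp, std_endpoints(), std_conc_grid(), noise_frac = 0)
  for (obs in c("persistence", "contour", "overstretch")) {
    f <- fit_titration(sim[[obs]])
    expect_equal(f$K_D, 2, tolerance = 1e-3)
    expect_equal(f$omega, 20, tolerance = 1e-3)
    truth_sat <- c(persistence = 8, contour = 0.40, overstretch = 68)[[obs]]
    expect_equal(f$saturated_value, truth_sat, tolerance = 1e-3)
  }
})

test_that("the fitted model is anchored at the protein-free value and monotone", {
  bp <- binding_params(K_D = 2, omega = 20, n = 26)
  sim <- simulate_titration(bp, std_endpoints(), std_conc_grid(),
                            noise_frac = 0.05, seed = 8)
  fp <- suppressWarnings(fit_titration(sim$persistence))
  expect_identical(fp$model(0), fp$protein_free_value)
  cg <- 10^seq(-2, 2, length.out = 30)
  expect_true(all(diff(fp$model(cg)) <= 0))      # persistence falls with binding
  fo <- suppressWarnings(fit_titration(sim$overstretch))
  expect_true(all(diff(fo$model(cg)) >= 0))      # overstretch rises with binding
})

test_that("noisy titrations recover truth within two reported sigma", {
  bp <- binding_params(K_D = 2, omega = 20, n = 26)
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    sim <- simulate_titration(bp, std_endpoints(), std_conc_grid(),
                              noise_frac = 0.05, seed = 3000 + s)
    f <- suppressWarnings(fit_titration(sim$persistence))
    ok <- abs(f$K_D - 2) <= 2 * f$K_D_se && abs(f$omega - 20) <= 2 * f$omega_se
    hits <- hits + ok
  }
  expect_gte(hits, ceiling(0.8 * n_rep))   # expect ~90%+; allow sampling slack
})

test_that("weighted-mean combination matches the analytic formula and symmetry", {
  # combining the three per-observable affinity estimates
  kd <- combine_weighted(c(2.1, 1.9, 2.8), c(0.8, 0.7, 0.6))
  expect_equal(kd$value, 2.3, tolerance = 0.05)
  expect_equal(kd$uncertainty, 0.4, tolerance = 0.05)
  om <- combine_weighted(c(20, 18, 80), c(7, 5, 15))
  expect_equal(om$value, 23, tolerance = 0.5)
  expect_equal(om$uncertainty, 4, tolerance = 0.5)
  # permutation invariance
  perm <- combine_weighted(c(1.9, 2.8, 2.1), c(0.7, 0.6, 0.8))
  expect_equal(perm$value, kd$value, tolerance = 1e-12)
  # k identical inputs: mean x, uncertainty sigma/sqrt(k)
  rep4 <- combine_weighted(rep(3.2, 4), rep(0.6, 4))
  expect_equal(rep4$value, 3.2, tolerance = 1e-12)
  expect_equal(rep4$uncertainty, 0.6 / 2, tolerance = 1e-12)
  # combined value lies within the inputs, uncertainty below the smallest sigma
  expect_true(kd$value >= 1.9 && kd$value <= 2.8)
  expect_lte(kd$uncertainty, 0.6)
  expect_error(combine_weighted(numeric(0), numeric(0)), "no estimates")
  expect_error(combine_weighted(c(1, 2), c(0.5, 0)), "positive")
})

test_that("titration series constructor validates its contract", {
  expect_error(titration_series("persistence", c(1, 2, 3, 4), 1:4, rep(1, 4)),
               "c = 0")
  expect_error(titration_series("persistence", c(0, 1, 2, 3), 1:4, c(1, 1, -1, 1)),
               "positive")
  expect_error(titration_series("persistence", c(0, 1, 1, 1), 1:4, rep(1, 4)),
               "4 distinct")
})
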
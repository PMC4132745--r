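test_that("extensible WLC evaluates the closed form correctly", {
  p <- std_wlc()
  # hand-evaluated: 0.34 * (1 - 0.5*sqrt(4.11/(50*10)) + 10/1200)
  expect_equal(wlc_extension(10, p), 0.34 * (1 - 0.5 * sqrt(4.11 / 500) + 10 / 1200),
               tolerance = 1e-12)
  expect_equal(wlc_extension(10, p), 0.3274204, tolerance = 1e-6)
  # at F = kT/P with the enthalpic term negligible the bracket is exactly 1/2
  p_stiff <- wlc_params(50, 0.34, 1e12)
  expect_equal(wlc_extension(4.11 / 50, p_stiff), 0.5 * 0.34, tolerance = 1e-9)
  # linear in the contour length
  p2 <- wlc_params(50, 0.68, 1200)
  expect_equal(wlc_extension(c(1, 7, 22), p2), 2 * wlc_extension(c(1, 7, 22), p),
               tolerance = 1e-12)
})

test_that("WLC extension is monotone in force and persistence length", {
  p <- std_wlc()
  Fg <- exp(seq(log(0.1), log(29.9), length.out = 40))
  b <- wlc_extension(Fg, p)
  expect_true(all(diff(b) > 0))
  Pg <- seq(5, 80, by = 5)
  bP <- vapply(Pg, function(P) wlc_extension(2, wlc_params(P, 0.34, 1200)), numeric(1))
  expect_true(all(diff(bP) > 0))
})

test_that("WLC force inversion round-trips and rejects bad input", {
  p <- std_wlc()
  for (f in c(0.5, 5, 50)) {
    b <- suppressWarnings(wlc_extension(f, p, f_flag = Inf))
    expect_equal(wlc_force(b, p), f, tolerance = 1e-6)
  }
  Fg <- exp(seq(log(0.1), log(100), length.out = 25))
  b <- suppressWarnings(wlc_extension(Fg, p, f_flag = Inf))
  expect_equal(wlc_force(b, p), Fg, tolerance = 1e-6)
  expect_equal(wlc_force(0.3274204, p), 10, tolerance = 1e-4)
  # monotone grid in, strictly increasing force out
  bg <- seq(0.20, 0.34, by = 0.01)
  expect_true(all(diff(wlc_force(bg, p)) > 0))
  expect_error(wlc_force(-0.1, p), "positive")
  expect_error(wlc_force(1e9, p), "range")
  expect_error(wlc_extension(-2, p), "positive")
  expect_error(wlc_params(-50, 0.34, 1200), "positive")
})

test_that("tangent correlation handles exact geometries", {
  # straight polyline: no curvature anywhere
  tr <- cbind(seq(0, 500, by = 5), 0)
  ct <- tangent_correlation(tr, step = 5, max_L = 100)
  expect_true(all(abs(ct$mean_cos_theta - 1) < 1e-12))
  fit <- fit_persistence_2d(ct)
  expect_true(fit$diverged)
  # closed square traversed once, step = side: right angles, cos = 0 at L = side
  sq <- rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40), c(0, 0))
  cs <- tangent_correlation(sq, step = 40, max_L = 80)
  expect_equal(cs$mean_cos_theta[cs$L == 40], 0, tolerance = 1e-12)
})

test_that("tangent correlation is invariant under rigid motions", {
  ch <- simulate_chain_2d(p = 39, contour = 500, step = 2.5, seed = 11)$points
  a <- 0.83
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  c1 <- tangent_correlation(ch, 5, 100)
  c2 <- tangent_correlation(sweep(ch %*% R, 2, c(-120, 57)), 5, 100)
  expect_equal(c1$mean_cos_theta, c2$mean_cos_theta, tolerance = 1e-10)
})

test_that("persistence fit inverts noiseless decay exactly", {
  L <- seq(5, 150, by = 5)
  corr <- structure(data.frame(L = L, mean_cos_theta = exp(-L / 118),
                               counts = 1000, se = rep(1e-3, length(L))),
                    class = c("tangent_correlation", "data.frame"))
  fit <- fit_persistence_2d(corr)
  expect_equal(fit$p, 59, tolerance = 1e-6)
  expect_false(fit$diverged)
})

test_that("persistence length is recovered within 10% from chain ensembles", {
  for (p_true in c(20, 39, 59)) {
    hits <- 0L
    for (s in 1:5) {
      set.seed(1000 * p_true + s)
      ch <- lapply(1:100, function(i) simulate_chain_2d(p_true, 1000, 2.5))
      # analyse at the trace's own sampling interval: coarser resampling
      # smooths the tangents and inflates the fitted persistence length
      p_hat <- fit_persistence_2d(tangent_correlation(ch, 2.5, 150))$p
      hits <- hits + (abs(p_hat / p_true - 1) < 0.1)
    }
    expect_gte(hits, 4L)
  }
})

test_that("short traces are skipped with a warning, all-short input errors", {
  short <- cbind(c(0, 3), c(0, 0))
  ok <- cbind(seq(0, 300, 5), 0)
  expect_warning(tangent_correlation(list(short, ok), step = 5, max_L = 50), "skipped")
  expect_error(suppressWarnings(tangent_correlation(list(short), step = 5, max_L = 50)),
               "no usable traces")
})
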
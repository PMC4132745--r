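test_that("bend angles reproduce constructed geometries", {
  # straight trace: 0 degrees
  straight <- trace2d("s", cbind(seq(0, 100, 2), 0))
  expect_equal(bend_angle_at_site(straight, 26, arm_length = 10), 0, tolerance = 1e-9)
  # right-angle polyline: 90 degrees
  ra <- trace2d("r", rbind(cbind(seq(0, 50, 5), 0), cbind(50, seq(5, 50, 5))))
  expect_equal(bend_angle_at_site(ra, 11, arm_length = 10), 90, tolerance = 1e-9)
  # programmed 40-degree kink on an otherwise rigid chain
  tr <- simulate_chain_2d(p = 1e6, contour = 200, step = 2,
                          kinks = data.frame(at_nm = 100, angle_deg = 40), seed = 9)
  site <- tr$annotations$start_index[1]
  expect_lt(abs(bend_angle_at_site(tr, site, arm_length = 10) - 40), 2)
  # too close to an end
  expect_error(bend_angle_at_site(straight, 2, arm_length = 10), "arm length")
})

test_that("bend angle is invariant under rotation and reflection", {
  tr <- simulate_chain_2d(p = 1e6, contour = 200, step = 2,
                          kinks = data.frame(at_nm = 100, angle_deg = 55), seed = 14)
  site <- tr$annotations$start_index[1]
  a0 <- bend_angle_at_site(tr, site, 10)
  th <- 1.2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- trace2d("rot", sweep(tr$points %*% R, 2, c(50, -20)))
  expect_lt(abs(bend_angle_at_site(rot, site, 10) - a0), 0.1)
  mir <- trace2d("mir", cbind(tr$points[, 1], -tr$points[, 2]))
  expect_lt(abs(bend_angle_at_site(mir, site, 10) - a0), 0.1)
})

test_that("bi-Gaussian fit recovers a symmetric sample and rejects degenerate input", {
  set.seed(77)
  ang <- pmin(180, pmax(0, rnorm(1000, mean = 40, sd = 10)))
  bg <- fit_bigaussian(ang)
  expect_false(bg$rejected)
  expect_lt(abs(bg$sigma_left / bg$sigma_right - 1), 0.15)
  expect_lt(abs(bg$center - 40), 3)
  expect_lt(abs(bg$mean_angle - 40), 1.5)
  # two-component flavor runs on the same data
  bg2 <- fit_bigaussian(ang, flavor = "two_component")
  expect_false(bg2$rejected)
  # degenerate: all angles equal
  expect_warning(rej <- fit_bigaussian(rep(35, 40)), "degenerate")
  expect_true(rej$rejected)
  expect_equal(rej$mean_angle, 35)
  expect_error(fit_bigaussian(rep(10, 5)), "30 angles")
})

test_that("loop sizes convert contour length by the calibration", {
  # circle of circumference ~170 nm
  t_seq <- seq(0, 2 * pi, length.out = 200)
  r <- 170 / (2 * pi)
  circ <- cbind(r * cos(t_seq), r * sin(t_seq))
  tr <- trace2d("c", rbind(c(-60, 0), c(-40, 0), c(-30, 0), circ + c(rep(0, 200), rep(0, 200))),
                annotations = NULL)
  loop <- list(start_index = 4, end_index = 203)
  bp <- loop_size_bp(tr, loop)
  expect_equal(bp, 500, tolerance = 0.01)
  expect_equal(loop_size_bp(tr, loop, nm_per_bp = 0.30), 170 / 0.30, tolerance = 0.01)
  # linear scaling with circumference
  circ2 <- cbind(2 * r * cos(t_seq), 2 * r * sin(t_seq))
  tr2 <- trace2d("c2", rbind(c(-80, 0), c(-70, 0), c(-68, 0), circ2))
  expect_equal(loop_size_bp(tr2, loop), 1000, tolerance = 0.01)
  # open circuit is rejected
  open_arc <- trace2d("o", cbind(r * cos(t_seq[1:120]), r * sin(t_seq[1:120])))
  expect_error(loop_size_bp(open_arc, list(start_index = 1, end_index = 120)),
               "closed circuit")
})

test_that("bridge statistics count annotated molecules", {
  mk <- function(id, n_bridge) {
    ann <- if (n_bridge > 0)
      data.frame(kind = rep("bridge", n_bridge), start_index = 1, end_index = 2)
    else NULL
    trace2d(id, cbind(seq(0, 50, 5), 0), annotations = ann)
  }
  # 10 molecules, 7 bridged, 20 bridges in total
  counts <- c(4, 3, 3, 3, 3, 2, 2, 0, 0, 0)
  traces <- lapply(seq_along(counts), function(i) mk(paste0("m", i), counts[i]))
  bs <- bridge_summary(traces)
  expect_equal(bs$fraction_with_bridges, 0.7)
  expect_equal(bs$mean_bridges_per_molecule, 2.0)
  none <- lapply(1:4, function(i) mk(paste0("n", i), 0))
  bs0 <- bridge_summary(none)
  expect_equal(bs0$fraction_with_bridges, 0)
  expect_equal(bs0$mean_bridges_per_molecule, 0)
  expect_error(bridge_summary(list()), "empty")
  # seeded Bernoulli(0.7) presence over 174 molecules: inside the binomial 95% CI
  set.seed(174)
  pres <- rbinom(174, 1, 0.7)
  traces2 <- lapply(seq_along(pres), function(i) mk(paste0("b", i), pres[i]))
  frac <- bridge_summary(traces2)$fraction_with_bridges
  ci_half <- 1.96 * sqrt(0.7 * 0.3 / 174)
  expect_lt(abs(frac - 0.7), ci_half + 1e-9)
})

test_that("AFM-scale chain ensembles return the generator persistence length", {
  # 174 molecules of pBR322-like contour (4361 bp * 0.34 nm/bp ~ 1483 nm)
  set.seed(88)
  ch <- lapply(1:174, function(i) simulate_chain_2d(39, 1483, 2.5, n_bp = 4361))
  fit <- fit_persistence_2d(tangent_correlation(ch, 2.5, 150))
  expect_lt(abs(fit$p / 39 - 1), 0.1)
})

test_that("trace construction validates annotations", {
  pts <- cbind(seq(0, 100, 5), 0)
  expect_error(trace2d("x", pts[1:2, ]), "3 rows")
  expect_error(trace2d("x", rbind(pts, pts[nrow(pts), ])), "distinct")
  bad_loop <- data.frame(kind = "loop", start_index = 1, end_index = 10)
  expect_error(trace2d("x", pts, annotations = bad_loop), "closed circuit")
  expect_error(trace2d("x", pts, annotations = data.frame(kind = "blob", start_index = 1, end_index = 1)),
               "unknown annotation")
})
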
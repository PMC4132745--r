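test_that("noiseless force-extension curves invert to the generator parameters", {
  cur <- simulate_fec(std_wlc(), n_bp = 48500, noise_F = 0)
  fit <- fit_force_extension(cur)
  expect_equal(fit$params$P_ds, 50, tolerance = 1e-3)
  expect_equal(fit$params$B_ds, 0.34, tolerance = 1e-3)
  expect_equal(fit$params$S_ds, 1200, tolerance = 1e-3)
})

test_that("persistence length is recovered within 5% from noisy curves", {
  errs <- vapply(1:50, function(s) {
    cur <- simulate_fec(std_wlc(), noise_F = 0.3, seed = 5000 + s, n_points = 1000)
    abs(fit_force_extension(cur)$params$P_ds / 50 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_gte(mean(errs < 0.05), 0.9)
})

test_that("force-extension fit enforces its range preconditions", {
  cur <- simulate_fec(std_wlc(), noise_F = 0)
  low <- fec(cur$extension[cur$force < 3], cur$force[cur$force < 3], 48500)
  expect_error(fit_force_extension(low), "force range")
  few <- fec(cur$extension[1:5], cur$force[1:5], 48500)
  expect_error(fit_force_extension(few), "10 points")
})

test_that("overstretching force averages the plateau window", {
  cur <- simulate_fec(std_wlc(), F_ov = 62, noise_F = 0)
  ov <- overstretch_force(cur)
  expect_equal(ov$F_ov, 62, tolerance = 1e-9)
  ovn <- overstretch_force(simulate_fec(std_wlc(), F_ov = 62, noise_F = 1, seed = 3))
  expect_lt(abs(ovn$F_ov - 62), 3 * ovn$se)
  # truncated below the window
  trunc <- simulate_fec(std_wlc(), noise_F = 0)   # no plateau: max 1.0 contour
  expect_error(overstretch_force(trunc), "0.42")
})

test_that("jump detection finds injected ruptures and nothing else", {
  p <- std_wlc()
  # smooth curve with modest noise: no events
  expect_length(detect_loop_jumps(simulate_fec(p, noise_F = 0.25, seed = 1)), 0)
  # three injected releases, located within 2 samples
  loops <- data.frame(size_bp = c(500, 550, 650), rupture_pN = c(6, 10, 14))
  cur <- simulate_fec(p, loops = loops, noise_F = 0.3, seed = 12)
  truth <- attr(cur, "events")
  idx <- detect_loop_jumps(cur, min_delta_F = 1.0)
  expect_length(idx, 3)
  for (k in seq_len(nrow(truth)))
    expect_true(any(abs(idx - truth$index[k]) <= 2))
  # a sub-threshold release is not reported: a small loop gives a small drop
  tiny <- simulate_fec(p, loops = data.frame(size_bp = 120, rupture_pN = 8),
                       noise_F = 0, seed = 2)
  ev <- attr(tiny, "events")
  expect_lt(ev$delta_F, 1.0)
  expect_length(detect_loop_jumps(tiny, min_delta_F = 1.0), 0)
  # release curves are never scanned
  rel <- fec(rev(cur$extension) * -1 + max(cur$extension) * 2, cur$force, 48500,
             direction = "release")
  expect_error(detect_loop_jumps(rel), "extend")
})

test_that("loop sizing applies the contour-change conversion", {
  p <- std_wlc()
  loops <- data.frame(size_bp = 500, rupture_pN = 10)
  cur <- simulate_fec(p, loops = loops, noise_F = 0, seed = 4)
  res <- analyze_loops(cur, min_delta_F = 1.0)
  expect_equal(nrow(res), 1)
  expect_equal(res$loop_bp, 500, tolerance = 0.1)
  # loop_bp is delta_B * n_bp / 0.34 by construction
  expect_equal(res$loop_bp, res$delta_B * 48500 / 0.34, tolerance = 1e-12)
  expect_gt(res$B_after, res$B_before)
  # stability: adding 0.2 pN noise moves the sized loop by < 5%
  cur_n <- simulate_fec(p, loops = loops, noise_F = 0.2, seed = 4)
  res_n <- analyze_loops(cur_n, min_delta_F = 1.0)
  expect_lt(abs(res_n$loop_bp / res$loop_bp - 1), 0.05)
})

test_that("sequestered length is conserved across multi-loop curves", {
  p <- std_wlc()
  loops <- data.frame(size_bp = c(600, 500, 650), rupture_pN = c(6, 10, 14))
  tot_true <- tot_sized <- 0
  for (s in 1:5) {
    cur <- simulate_fec(p, loops = loops, noise_F = 0.3, seed = 700 + s)
    truth <- attr(cur, "events")
    res <- analyze_loops(cur, min_delta_F = 1.0)
    tot_true <- tot_true + sum(truth$loop_bp[truth$delta_F >= 1.0])
    tot_sized <- tot_sized + sum(res$loop_bp[res$sized])
  }
  expect_lt(abs(tot_sized / tot_true - 1), 0.1)
})

test_that("loop histograms bin sizes and censor sub-threshold drops", {
  ev <- data.frame(extension_at_jump = 1:6, F_before = c(8, 11, 12, 13, 14, 22),
                   F_after = 0, delta_F = c(0.5, rep(2, 5)),
                   B_before = 0, B_after = 0, delta_B = 0,
                   loop_bp = c(100, 450, 480, 520, 560, 900), sized = TRUE)
  h <- loop_histograms(ev, bp_bin = 200, force_bin = 5)
  expect_equal(h$n_censored, 1L)
  expect_equal(h$modal_size_bin, c(400, 600))
  expect_equal(h$modal_force_bin, c(10, 15))
  expect_equal(sum(h$size$count), 5L)
  expect_warning(loop_histograms(ev[0, , drop = FALSE]), "no events")
})

test_that("compaction kinetics are fitted and rejected appropriately", {
  sim <- simulate_compaction(k = 0.64, amplitude = 800, baseline = 15600, noise = 0)
  fit <- compaction_fit(sim$times, sim$extensions)
  expect_equal(fit$k, 0.64, tolerance = 1e-6)
  expect_equal(fit$tau, 1 / 0.64, tolerance = 1e-6)
  expect_equal(fit$tau * fit$k, 1)
  # noisy recovery within 15%
  ks <- vapply(1:30, function(s) {
    sm <- simulate_compaction(0.64, 800, 15600, noise = 40, seed = 900 + s)
    compaction_fit(sm$times, sm$extensions)$k
  }, numeric(1))
  expect_lt(abs(stats::median(ks) / 0.64 - 1), 0.15)
  # no trend in residuals on well-specified data (Durbin-Watson near 2)
  sm <- simulate_compaction(0.64, 800, 15600, noise = 40, seed = 901)
  ft <- compaction_fit(sm$times, sm$extensions)
  r <- sm$extensions - (ft$baseline + ft$amplitude * exp(-ft$k * sm$times))
  dw <- sum(diff(r)^2) / sum(r^2)
  expect_gt(dw, 1.5); expect_lt(dw, 2.5)
  # flat series is rejected with the sample mean as baseline
  flat <- simulate_compaction(0.64, 0, 15600, noise = 5, seed = 3)
  expect_warning(rej <- compaction_fit(flat$times, flat$extensions), "rejected|decay")
  expect_true(rej$rejected)
})

test_that("compaction force is the low-extension force difference", {
  p <- std_wlc()
  ext <- seq(1500, 16000, length.out = 400)
  f0 <- suppressWarnings(wlc_force(ext / 48500, p))
  naked <- fec(ext, f0, 48500, direction = "release")
  expect_equal(compaction_force(naked, naked)$delta_F_c, 0)
  offset <- fec(ext, f0 + 1.7, 48500, direction = "release")
  expect_equal(compaction_force(offset, naked)$delta_F_c, 1.7, tolerance = 1e-9)
  # noisy programmed offset recovered within 3 SE
  set.seed(31)
  noisy <- fec(ext, f0 + 2.0 + rnorm(length(ext), sd = 0.3), 48500,
               direction = "release")
  cf <- compaction_force(noisy, naked)
  expect_lt(abs(cf$delta_F_c - 2.0), 3 * cf$se)
  # disjoint extension ranges cannot be aligned
  far <- fec(ext + 1e6, f0, 48500, direction = "release")
  expect_error(compaction_force(far, naked), "overlap")
})
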
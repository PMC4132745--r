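#' Simulate an optical-tweezers force-extension curve
#'
#' Generates a stretch curve on an increasing extension grid from the
#' extensible WLC model, with optional protein-stabilized loops and an
#' overstretching plateau. While loops are intact their base pairs are
#' sequestered, so the force follows the WLC with an effective contour of
#' `n_bp - sequestered` base pairs; when the force first reaches a loop's
#' rupture force that loop's length is returned to the contour and the force
#' drops at fixed extension (the sawtooth signature). Gaussian force noise is
#' added last.
#'
#' @param params A [wlc_params()] for the underlying DNA.
#' @param n_bp Molecule size, bp (default 48500, bacteriophage-lambda DNA).
#' @param loops Data.frame with columns `size_bp` and `rupture_pN` (may be
#'   empty). Sizes must sum to less than `n_bp`.
#' @param ext_range Extension grid range as fractions of the B-form contour
#'   `n_bp * B_ds` (default c(0.35, 1.0), reaching ~33 pN for standard DNA
#'   parameters so that the 30 pN fitting window is covered).
#' @param n_points Grid size (default 2000).
#' @param noise_F Gaussian force noise SD, pN (default 0).
#' @param F_ov Overstretching plateau force, pN, or NULL for no plateau. When
#'   set, the grid is extended to 0.50 nm/bp and forces are capped at `F_ov`.
#' @param concentration,pulling_rate Metadata stored on the curve.
#' @param seed RNG seed (required when `noise_F > 0`).
#' @return A [fec()] object with attribute `events`: a data.frame of the true
#'   rupture events (grid index, extension, peak and post-release force, the
#'   emergent force drop `delta_F`, and `loop_bp`).
#' @export
simulate_fec <- function(params, n_bp = 48500, loops = NULL,
                         ext_range = c(0.35, 1.0), n_points = 2000L,
                         noise_F = 0, F_ov = NULL,
                         concentration = 0, pulling_rate = NA_real_, seed = NULL) {
  stopifnot(inherits(params, "wlc_params"))
  if (is.null(loops)) loops <- data.frame(size_bp = numeric(0), rupture_pN = numeric(0))
  if (nrow(loops) > 0) {
    stopifnot(all(c("size_bp", "rupture_pN") %in% names(loops)))
    if (sum(loops$size_bp) >= n_bp) stop("loop sizes must sum to less than n_bp", call. = FALSE)
    loops <- loops[order(loops$rupture_pN), , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  contour <- n_bp * params$B_ds
  # the overstretch window (0.42-0.48 nm/bp) lies beyond the B-form contour:
  # as a fraction of n_bp * B_ds it is 0.42/B_ds .. 0.48/B_ds (~1.2-1.4)
  hi_frac <- if (!is.null(F_ov)) 0.50 / params$B_ds else ext_range[2]
  ext <- seq(ext_range[1] * contour, max(ext_range[2], hi_frac) * contour,
             length.out = n_points)
  active <- rep(TRUE, nrow(loops))
  seq_bp <- sum(loops$size_bp)
  force <- numeric(n_points)
  events <- list()
  f_at <- function(x, sequestered) {
    b <- x / (n_bp - sequestered)
    wlc_force(b, params)
  }
  # ruptures must be reachable: check against the force at the grid start
  if (nrow(loops) > 0) {
    f0 <- f_at(ext[1], seq_bp)
    if (any(loops$rupture_pN <= f0))
      stop("loop rupture force below the force at the start of the grid", call. = FALSE)
  }
  for (i in seq_len(n_points)) {
    f <- f_at(ext[i], seq_bp)
    # record the peak, then release every loop whose rupture force is reached
    while (any(active) && f >= min(loops$rupture_pN[active])) {
      k <- which(active)[which.min(loops$rupture_pN[active])]
      active[k] <- FALSE
      seq_bp <- seq_bp - loops$size_bp[k]
      f_new <- f_at(ext[i], seq_bp)
      events[[length(events) + 1L]] <- data.frame(
        index = i, extension = ext[i], F_peak = f, F_after = f_new,
        delta_F = f - f_new, loop_bp = loops$size_bp[k])
      f <- f_new
    }
    force[i] <- f
  }
  # events: the recorded grid value at the event index is the PEAK force;
  # subsequent points carry the released branch
  if (length(events) > 0) {
    ev <- do.call(rbind, events)
    # collapse simultaneous releases at one grid point into one observable drop
    ev_obs <- do.call(rbind, lapply(split(ev, ev$index), function(d) {
      data.frame(index = d$index[1], extension = d$extension[1],
                 F_peak = max(d$F_peak), F_after = min(d$F_after),
                 delta_F = max(d$F_peak) - min(d$F_after),
                 loop_bp = sum(d$loop_bp))
    }))
    force[ev_obs$index] <- ev_obs$F_peak
  } else ev_obs <- data.frame(index = integer(0), extension = numeric(0),
                              F_peak = numeric(0), F_after = numeric(0),
                              delta_F = numeric(0), loop_bp = numeric(0))
  if (!is.null(F_ov)) force <- pmin(force, F_ov)
  if (noise_F > 0) force <- force + stats::rnorm(n_points, sd = noise_F)
  out <- fec(ext, force, n_bp = n_bp, concentration = concentration,
             pulling_rate = pulling_rate, direction = "extend")
  attr(out, "events") <- ev_obs
  out
}

#' Simulate titration series of the three mechanical observables
#'
#' Computes the occupancy at each concentration from the cooperative binding
#' isotherm, maps it to persistence length (harmonic map), contour length and
#' overstretching force (linear maps), and adds Gaussian noise with SD equal to
#' `noise_frac` times the free-to-saturated range of each observable.
#'
#' @param params A [binding_params()] (truth).
#' @param endpoints Named list of saturation endpoints: `P_D`, `P_L` (nm),
#'   `B_D`, `B_L` (nm/bp), `F_ov_D`, `F_ov_L` (pN).
#' @param c_nM Concentration grid, nM; 0 is added if absent.
#' @param noise_frac Noise SD as a fraction of each observable's range
#'   (default 0.05).
#' @param seed RNG seed.
#' @return Named list of three [titration_series()] ("persistence", "contour",
#'   "overstretch") with attribute `theta` (the true occupancies).
#' @export
simulate_titration <- function(params, endpoints, c_nM, noise_frac = 0.05, seed = NULL) {
  stopifnot(inherits(params, "binding_params"))
  need <- c("P_D", "P_L", "B_D", "B_L", "F_ov_D", "F_ov_L")
  stopifnot(all(need %in% names(endpoints)))
  if (!0 %in% c_nM) c_nM <- c(0, c_nM)
  c_nM <- sort(unique(c_nM))
  if (!is.null(seed)) set.seed(seed)
  th <- mvh_occupancy(c_nM, params)$theta
  mk <- function(obs, truth, rng) {
    sigma <- max(noise_frac * rng, 1e-12)
    y <- truth + if (noise_frac > 0) stats::rnorm(length(truth), sd = sigma) else 0
    titration_series(obs, c_nM, y, sigma = rep(sigma, length(y)))
  }
  out <- list(
    persistence = mk("persistence", occupancy_map_P(th, endpoints$P_D, endpoints$P_L),
                     abs(endpoints$P_D - endpoints$P_L)),
    contour = mk("contour", occupancy_map_linear(th, endpoints$B_D, endpoints$B_L),
                 abs(endpoints$B_L - endpoints$B_D)),
    overstretch = mk("overstretch", occupancy_map_linear(th, endpoints$F_ov_D, endpoints$F_ov_L),
                     abs(endpoints$F_ov_L - endpoints$F_ov_D)))
  attr(out, "theta") <- th
  out
}

#' Simulate a discrete 2D worm-like chain
#'
#' Successive tangent angles perform a Gaussian random walk with per-step
#' variance `step / p`, so the ensemble satisfies the planar WLC decay
#' `<cos theta(L)> = exp(-L / 2p)`. Optional programmed kinks add a fixed bend
#' at chosen arc positions (annotated as protein sites).
#'
#' @param p Persistence length, nm.
#' @param contour Total contour length, nm.
#' @param step Segment length, nm (default 2.5; must be much smaller than `p`).
#' @param kinks Optional data.frame with columns `at_nm` (arc position) and
#'   `angle_deg` (signed bend inserted there).
#' @param molecule_id Identifier (default "sim").
#' @param n_bp Stored molecule size, bp; default `contour / 0.34`.
#' @param seed RNG seed.
#' @return A [trace2d()]; kinks become `protein_site` annotations.
#' @export
simulate_chain_2d <- function(p, contour, step = 2.5, kinks = NULL,
                              molecule_id = "sim", n_bp = NULL, seed = NULL) {
  if (step >= p) stop("step must be smaller than the persistence length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_seg <- max(2L, round(contour / step))
  dtheta <- stats::rnorm(n_seg, sd = sqrt(step / p))
  dtheta[1] <- stats::runif(1, 0, 2 * pi)   # random initial orientation
  kink_idx <- integer(0)
  if (!is.null(kinks) && nrow(kinks) > 0) {
    kink_idx <- pmin(pmax(round(kinks$at_nm / step), 2L), n_seg)
    dtheta[kink_idx] <- dtheta[kink_idx] + kinks$angle_deg * pi / 180
  }
  ang <- cumsum(dtheta)
  pts <- rbind(c(0, 0), cbind(cumsum(step * cos(ang)), cumsum(step * sin(ang))))
  # the corner between segments k-1 and k sits at point k
  anno <- if (length(kink_idx) > 0)
    data.frame(kind = "protein_site", start_index = kink_idx, end_index = kink_idx)
  else NULL
  trace2d(molecule_id, pts, n_bp = if (is.null(n_bp)) contour / 0.34 else n_bp,
          annotations = anno)
}

#' Simulate a constant-force compaction record
#'
#' Single-exponential decay of the tether extension after protein exposure:
#' `x(t) = baseline + amplitude * exp(-k t)` plus Gaussian noise.
#'
#' @param k Compaction rate, 1/s. Positive.
#' @param amplitude Decay amplitude, nm.
#' @param baseline Final extension, nm.
#' @param t_max Record length, s (default `5 / k`).
#' @param dt Sampling interval, s (default 0.05).
#' @param noise Gaussian noise SD, nm (default 0).
#' @param seed RNG seed.
#' @return A list with `times` (s) and `extensions` (nm).
#' @export
simulate_compaction <- function(k, amplitude, baseline, t_max = 5 / k,
                                dt = 0.05, noise = 0, seed = NULL) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_max, by = dt)
  x <- baseline + amplitude * exp(-k * t)
  if (noise > 0) x <- x + stats::rnorm(length(t), sd = noise)
  list(times = t, extensions = x)
}

#' Grand-canonical Monte-Carlo sampling of the 1D binding lattice
#'
#' Equilibrium configurations of n-site ligands on a finite lattice with
#' statistical weight `c/K_D` per bound protein and `omega` per pair of exactly
#' adjacent footprints, sampled by Metropolis moves: insertion/deletion at a
#' uniformly random footprint position (symmetric), mixed 50/50 with
#' translations of a uniformly chosen bound protein to a uniformly chosen
#' position (also symmetric; translations rearrange clusters directly, which
#' the insertion/deletion moves alone do extremely slowly at high coverage).
#'
#' @param c_nM Free protein concentration, nM.
#' @param params A [binding_params()].
#' @param lattice_sites Lattice length, sites; at least `10 * n`.
#' @param seed RNG seed.
#' @param sweeps Number of recorded samples (one per thinning interval;
#'   default 2000).
#' @param thin Proposals between recorded samples (default one lattice sweep,
#'   `lattice_sites - n + 1` proposals).
#' @param burnin_sweeps Lattice sweeps discarded before recording (default 100).
#' @param start Initial configuration, "empty" or "packed" (fully covered);
#'   chains started from both extremes bracket the equilibrium.
#' @param boundary "linear" (hard ends; comparable to the finite-lattice
#'   transfer matrix) or "circular" (periodic; boundary effects vanish, so the
#'   occupancy converges to the infinite-lattice isotherm much faster in the
#'   lattice size).
#' @return A list with per-sample vectors `n_proteins` and `n_clusters`,
#'   `theta` (mean occupancy with standard error `theta_se` from batch means),
#'   and `final_starts` (bound positions of the last configuration).
#' @export
simulate_lattice <- function(c_nM, params, lattice_sites = NULL, seed = 1L,
                             sweeps = 2000L, thin = NULL, burnin_sweeps = 100L,
                             start = c("empty", "packed"),
                             boundary = c("linear", "circular")) {
  start <- match.arg(start)
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "binding_params"))
  n <- params$n
  M <- if (is.null(lattice_sites)) 20L * n else as.integer(lattice_sites)
  if (M < 10L * n) stop("lattice must have at least 10 * n sites", call. = FALSE)
  z <- c_nM / params$K_D
  omega <- params$omega
  circ <- boundary == "circular"
  n_pos <- if (circ) M else M - n + 1L
  if (is.null(thin)) thin <- n_pos
  set.seed(seed)
  occ <- logical(M)          # site covered by any footprint
  start_at <- logical(M)     # a footprint starts here
  plist <- integer(M)        # bound start positions (unordered), 1..N used
  pidx <- integer(M)         # start position -> index into plist
  N <- 0L
  nm1 <- n - 1L
  if (start == "packed") {   # overdispersed initial state: fully packed lattice
    for (s0 in seq(1L, M - n + 1L, by = n)) {
      N <- N + 1L; plist[N] <- s0; pidx[s0] <- N
      start_at[s0] <- TRUE; occ[s0:(s0 + nm1)] <- TRUE
    }
  }
  total <- (burnin_sweeps + sweeps) * thin
  record_at <- burnin_sweeps * thin + seq_len(sweeps) * thin
  n_prot <- n_clust <- integer(sweeps)
  rec <- 1L
  done <- 0L
  block <- 50000L
  while (done < total) {
    nb <- min(block, total - done)
    # pre-drawn randoms: move selector, position, protein selector, acceptance
    mv <- stats::runif(nb); ps <- sample.int(n_pos, nb, replace = TRUE)
    pr <- stats::runif(nb); ac <- stats::runif(nb)
    spn <- if (circ) function(s) {
      e <- s + nm1
      if (e <= M) s:e else c(s:M, 1:(e - M))
    } else function(s) s:(s + nm1)
    ctc <- if (circ) function(s) {
      l <- s - n; if (l < 1L) l <- l + M
      r <- s + n; if (r > M) r <- r - M
      start_at[l] + start_at[r]
    } else function(s) {
      (s > n && start_at[s - n]) + (s + n <= n_pos && start_at[s + n])
    }
    for (t in seq_len(nb)) {
      s <- ps[t]
      if (mv[t] < 0.5) {
        # insertion / deletion at position s (symmetric proposal)
        if (start_at[s]) {
          cc <- ctc(s)
          if (ac[t] * z * omega^cc < 1) {
            start_at[s] <- FALSE; occ[spn(s)] <- FALSE
            i <- pidx[s]; last <- plist[N]
            plist[i] <- last; pidx[last] <- i; pidx[s] <- 0L; N <- N - 1L
          }
        } else if (!any(occ[spn(s)])) {
          cc <- ctc(s)
          if (ac[t] < z * omega^cc) {
            start_at[s] <- TRUE; occ[spn(s)] <- TRUE
            N <- N + 1L; plist[N] <- s; pidx[s] <- N
          }
        }
      } else if (N > 0L) {
        # translation: uniformly chosen protein to uniformly chosen position
        # (symmetric; accelerates cluster rearrangement at high coverage)
        p0 <- plist[1L + as.integer(pr[t] * N)]
        if (s != p0) {
          span0 <- spn(p0)
          occ[span0] <- FALSE
          if (!any(occ[spn(s)])) {
            start_at[p0] <- FALSE
            c_old <- ctc(p0)
            c_new <- ctc(s)
            if (ac[t] < omega^(c_new - c_old)) {
              start_at[s] <- TRUE; occ[spn(s)] <- TRUE
              i <- pidx[p0]; plist[i] <- s; pidx[s] <- i; pidx[p0] <- 0L
            } else {
              start_at[p0] <- TRUE; occ[span0] <- TRUE
            }
          } else {
            occ[span0] <- TRUE
          }
        }
      }
      done <- done + 1L
      if (rec <= sweeps && done == record_at[rec]) {
        st <- plist[seq_len(N)]
        n_prot[rec] <- N
        if (N == 0L) n_clust[rec] <- 0L
        else {
          ln <- st - n
          if (circ) ln[ln < 1L] <- ln[ln < 1L] + M
          k <- sum(!(ln %in% st))
          n_clust[rec] <- if (k == 0L) 1L else k   # fully packed ring: one cluster
        }
        rec <- rec + 1L
      }
    }
  }
  theta <- mean(n_prot) * n / M
  nbatch <- 20L
  bm <- vapply(split(n_prot, cut(seq_len(sweeps), nbatch, labels = FALSE)),
               mean, numeric(1)) * n / M
  list(n_proteins = n_prot, n_clusters = n_clust,
       theta = theta, theta_se = stats::sd(bm) / sqrt(length(bm)),
       final_starts = sort(plist[seq_len(N)]), lattice_sites = M)
}
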
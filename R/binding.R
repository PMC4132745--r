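#' Cooperative lattice-binding parameters
#'
#' Parameters of the McGhee-von Hippel model for a large ligand covering `n`
#' lattice sites (base pairs) with nearest-neighbour cooperativity `omega`.
#'
#' @param K_D Dissociation constant, nM. Positive.
#' @param omega Cooperativity parameter, dimensionless. Positive; 1 means
#'   non-cooperative.
#' @param n Binding site size, bp (default 26).
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(K_D, omega, n = 26L) {
  if (!is.numeric(K_D) || length(K_D) != 1L || K_D <= 0) stop("K_D must be positive", call. = FALSE)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) stop("omega must be positive", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  structure(list(K_D = K_D, omega = omega, n = as.integer(n)), class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("McGhee-von Hippel: K_D = %.4g nM, omega = %.4g, n = %d bp\n",
              x$K_D, x$omega, x$n))
  invisible(x)
}

# Auxiliary root term R(Theta) of the cooperative isotherm
mvh_R <- function(theta, omega, n) {
  sqrt((1 - (n + 1) * theta / n)^2 + 4 * omega * theta * (1 - theta) / n)
}

#' Free concentration required for a given occupancy (closed form)
#'
#' The cooperative McGhee-von Hippel isotherm expresses the occupancy Theta
#' implicitly; solved for the free ligand concentration it becomes an explicit,
#' strictly increasing function c(Theta), which this helper evaluates. For
#' `omega` within 1e-6 of 1 the non-cooperative closed form is used (the
#' cooperative expression is 0/0 at omega = 1).
#'
#' @param theta Fractional site occupancy in [0, 1).
#' @param params A [binding_params()] object.
#' @return Free protein concentration, nM.
#' @export
mvh_c_of_theta <- function(theta, params) {
  stopifnot(inherits(params, "binding_params"))
  n <- params$n; omega <- params$omega; K_D <- params$K_D
  if (any(theta < 0 | theta >= 1)) stop("theta must lie in [0, 1)", call. = FALSE)
  th <- theta
  out <- numeric(length(th))
  pos <- th > 0
  th <- th[pos]
  if (abs(omega - 1) < 1e-6) {
    # non-cooperative closed form
    out[pos] <- th * K_D / (n * (1 - th)) *
      ((1 - (n - 1) * th / n) / (1 - th))^(n - 1)
  } else {
    R <- mvh_R(th, omega, n)
    br1 <- if (n == 1) rep(1, length(th)) else
      (((2 * omega - 1) * (1 - th) + th / n - R) / (2 * (omega - 1) * (1 - th)))^(n - 1)
    br2 <- ((1 - (n + 1) * th / n + R) / (2 * (1 - th)))^2
    out[pos] <- th * K_D / (n * (1 - th) * br1 * br2)
  }
  out
}

#' Solve the cooperative McGhee-von Hippel isotherm for the occupancy
#'
#' Computes the fractional site occupancy Theta at a free ligand concentration
#' `c_nM` by bracketed root finding on the strictly increasing closed form
#' c(Theta) (see [mvh_c_of_theta()]). Every solution is self-checked: the
#' relative residual of the fixed-point form Theta = RHS(Theta) must not exceed
#' `tol_resid`.
#'
#' @param c_nM Free protein concentration, nM (vectorised, >= 0).
#' @param params A [binding_params()] object.
#' @param tol Absolute tolerance on Theta for the root (default 1e-12).
#' @param tol_resid Maximum allowed relative residual of the isotherm
#'   (default 1e-8).
#' @return A data.frame of class `occupancy_solution` with columns `c` (nM),
#'   `theta`, `R` (the auxiliary root term) and `residual`.
#' @examples
#' mvh_occupancy(2.3, binding_params(K_D = 2.3, omega = 23, n = 26))
#' @export
mvh_occupancy <- function(c_nM, params, tol = 1e-12, tol_resid = 1e-8) {
  stopifnot(inherits(params, "binding_params"))
  if (any(!is.finite(c_nM)) || any(c_nM < 0))
    stop("concentration must be finite and non-negative", call. = FALSE)
  # c(theta) is strictly increasing and diverges at theta = 1; solve on a
  # logit grid by monotone interpolation, polish with Newton steps on log c,
  # and fall back to bracketed bisection for any point that misses tolerance.
  u <- seq(stats::qlogis(1e-12), stats::qlogis(1 - 1e-10), length.out = 400)
  tg <- stats::plogis(u)
  cg <- mvh_c_of_theta(tg, params)
  ok_g <- is.finite(cg) & cg > 0
  tg <- tg[ok_g]; cg <- cg[ok_g]
  theta <- numeric(length(c_nM))
  pos <- c_nM > 0
  if (any(pos)) {
    cc <- c_nM[pos]
    lo_c <- cg[1]; hi_c <- cg[length(cg)]
    th <- stats::plogis(stats::approx(log(cg), stats::qlogis(tg),
                                      xout = pmin(pmax(log(cc), log(lo_c)), log(hi_c)),
                                      ties = "ordered")$y)
    for (it in 1:6) {   # Newton on g(theta) = log c(theta) - log c
      h <- pmax(1e-9, 1e-6 * th * (1 - th))
      f0 <- log(mvh_c_of_theta(th, params)) - log(cc)
      f1 <- log(mvh_c_of_theta(pmin(th + h, 1 - 1e-13), params)) - log(cc)
      step <- f0 * h / (f1 - f0)
      step[!is.finite(step)] <- 0
      th <- pmin(pmax(th - step, 1e-14), 1 - 1e-11)
    }
    # bisection fallback where Newton did not converge
    bad <- abs(log(mvh_c_of_theta(th, params)) - log(cc)) > 1e-9
    if (any(bad)) {
      th[bad] <- vapply(cc[bad], function(c1) {
        hi <- tg[length(tg)]
        if (mvh_c_of_theta(hi, params) < c1) return(hi)  # numerically saturated
        stats::uniroot(function(x) mvh_c_of_theta(x, params) - c1,
                       interval = c(0, hi), tol = tol)$root
      }, numeric(1))
    }
    theta[pos] <- th
  }
  R <- mvh_R(theta, params$omega, params$n)
  resid <- mvh_residual(theta, c_nM, params)
  if (any(resid > tol_resid))
    stop(sprintf("isotherm self-check failed: max relative residual %.3g", max(resid)),
         call. = FALSE)
  structure(data.frame(c = c_nM, theta = theta, R = R, residual = resid),
            class = c("occupancy_solution", "data.frame"))
}

# Relative residual of the fixed-point form of the isotherm: |Theta - RHS|/max(Theta, eps)
mvh_residual <- function(theta, c_nM, params) {
  rhs <- theta
  ok <- theta > 0
  if (any(ok)) {
    cth <- mvh_c_of_theta(theta[ok], params)
    # RHS of the fixed-point equation scales as theta * (c / c(theta))
    rhs[ok] <- theta[ok] * c_nM[ok] / cth
  }
  abs(theta - rhs) / pmax(theta, 1e-30)
}

## ---- occupancy -> observable maps ------------------------------------------

#' Persistence length at fractional occupancy (harmonic interpolation)
#'
#' \deqn{P(\Theta) = P_L P_D / (P_L + \Theta (P_D - P_L))}
#' The inverse persistence lengths (bending compliances) add linearly with
#' occupancy, interpolating between the protein-free value `P_D` at Theta = 0
#' and the saturated value `P_L` at Theta = 1.
#'
#' @param theta Occupancy in [0, 1] (vectorised).
#' @param P_D Protein-free persistence length, nm.
#' @param P_L Protein-saturated persistence length, nm.
#' @return Apparent persistence length, nm.
#' @export
occupancy_map_P <- function(theta, P_D, P_L) {
  if (P_D <= 0 || P_L <= 0) stop("endpoint persistence lengths must be positive", call. = FALSE)
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]", call. = FALSE)
  den <- P_L + theta * (P_D - P_L)
  if (any(abs(den) < .Machine$double.eps)) stop("zero denominator in persistence map", call. = FALSE)
  P_L * P_D / den
}

#' Linear occupancy map for contour length and overstretching force
#'
#' \deqn{x(\Theta) = x_D + \Theta (x_L - x_D)}
#'
#' @param theta Occupancy in [0, 1] (vectorised).
#' @param x_D Protein-free value.
#' @param x_L Protein-saturated value.
#' @return Interpolated observable.
#' @export
occupancy_map_linear <- function(theta, x_D, x_L) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]", call. = FALSE)
  x_D + theta * (x_L - x_D)
}

#' Back-calculate the occupancy from an observed persistence length
#'
#' Algebraic inversion of the harmonic persistence map:
#' \deqn{\Theta = P_L (P_D - P_{obs}) / (P_{obs} (P_D - P_L))}
#'
#' @param P_obs Observed apparent persistence length, nm.
#' @param P_D Protein-free persistence length, nm.
#' @param P_L Protein-saturated persistence length, nm.
#' @return Fractional occupancy Theta.
#' @export
invert_occupancy_from_P <- function(P_obs, P_D, P_L) {
  if (P_D <= 0 || P_L <= 0 || P_obs <= 0) stop("persistence lengths must be positive", call. = FALSE)
  lo <- min(P_D, P_L); hi <- max(P_D, P_L)
  if (P_obs < lo - 1e-12 || P_obs > hi + 1e-12)
    stop(sprintf("P_obs = %.4g nm outside the endpoint range [%.4g, %.4g]", P_obs, lo, hi),
         call. = FALSE)
  P_L * (P_D - P_obs) / (P_obs * (P_D - P_L))
}

## ---- cluster statistics -----------------------------------------------------

# Transfer-matrix dynamic program over a finite lattice.
# State after site i: does a bound protein end exactly at i?
# Tracks (Z, sum_w * N_proteins, sum_w * N_clusters) per state.
cluster_dp <- function(M, n, z, omega) {
  # columns: Z, ZN, ZC ; rows: state end-free (1), end-occupied (2)
  # f[[i]] stored as 2x3 matrix; only previous n values needed
  hist <- vector("list", M + 1)
  hist[[1]] <- rbind(c(1, 0, 0), c(0, 0, 0))  # zero sites filled
  for (i in seq_len(M)) {
    prev <- hist[[i]]
    free_row <- prev[1, ] + prev[2, ]          # site i left free
    occ_row <- c(0, 0, 0)
    if (i - n >= 0) {
      base <- hist[[i - n + 1]]
      # protein occupies sites (i-n+1)..i
      # preceded by a free site (or lattice start): new cluster
      occ_row <- z * c(base[1, 1],
                       base[1, 2] + base[1, 1],
                       base[1, 3] + base[1, 1]) +
        # preceded immediately by a protein: extends cluster, contact weight omega
        z * omega * c(base[2, 1],
                      base[2, 2] + base[2, 1],
                      base[2, 3])
    }
    hist[[i + 1]] <- rbind(free_row, occ_row)
    # rescale to avoid overflow on long lattices
    sc <- max(abs(hist[[i + 1]][, 1]))
    if (sc > 1e200) for (j in seq(i + 1, 1)) hist[[j]] <- hist[[j]] / sc
  }
  fin <- hist[[M + 1]]
  tot <- unname(fin[1, ] + fin[2, ])
  list(Z = tot[1], mean_N = tot[2] / tot[1], mean_C = tot[3] / tot[1])
}

#' Mean bound-protein cluster size on a 1D lattice
#'
#' Mean number of proteins per maximal run of contiguously bound proteins
#' (footprints exactly adjacent, zero free sites between neighbours) in the
#' equilibrium McGhee-von Hippel ensemble at free concentration `c_nM`.
#' Computed as the ratio of the ensemble-average protein count to the
#' ensemble-average cluster count.
#'
#' `method = "exact"` uses a transfer-matrix dynamic program (statistical
#' weight c/K_D per bound protein, omega per bound-bound contact);
#' `method = "montecarlo"` uses seeded grand-canonical Metropolis sampling
#' (see [simulate_lattice()]) and also returns a Monte-Carlo standard error.
#'
#' @param c_nM Free protein concentration, nM.
#' @param params A [binding_params()] object.
#' @param method "exact" (transfer matrix) or "montecarlo".
#' @param lattice_sites Number of lattice sites. Defaults to three footprints
#'   (`3 * n`) for the exact method and `20 * n` for Monte Carlo. The exact
#'   method is capped at 20000 sites; Monte Carlo requires at least `10 * n`.
#'   The cluster size depends noticeably on lattice length: short lattices
#'   truncate the cluster-size distribution (an 80-site lattice holds at most
#'   three footprints of 26 bp), so finite-size values are smaller than the
#'   thermodynamic limit.
#' @param seed RNG seed for the Monte-Carlo method.
#' @param sweeps Monte-Carlo sweeps per chain after burn-in (default 2000).
#' @param chains Independent Monte-Carlo chains (default 8); the standard
#'   errors are taken across chains because the sampler decorrelates slowly at
#'   strongly clustered conditions.
#' @param boundary Lattice boundary for the Monte-Carlo method, "linear"
#'   (matches the finite transfer matrix) or "circular" (approximates the
#'   infinite-lattice isotherm); see [simulate_lattice()].
#' @return A list with `mean_cluster_size`, `theta` (mean occupancy),
#'   `mean_proteins`, `mean_clusters`, `method`, and for Monte Carlo `se` and
#'   `theta_se` (cross-chain standard errors) plus `rhat` (split-Rhat style
#'   equilibration diagnostic on the protein count; a warning is raised above
#'   1.2).
#' @examples
#' mean_cluster_size(2.3, binding_params(2.3, 23, 26), lattice_sites = 2000)
#' @export
mean_cluster_size <- function(c_nM, params, method = c("exact", "montecarlo"),
                              lattice_sites = NULL, seed = 1L, sweeps = 2000L,
                              chains = 8L, boundary = "linear") {
  stopifnot(inherits(params, "binding_params"))
  method <- match.arg(method)
  if (is.null(lattice_sites))
    lattice_sites <- if (method == "exact") 3L * params$n else 20L * params$n
  M <- as.integer(lattice_sites)
  n <- params$n
  z <- c_nM / params$K_D
  if (method == "exact") {
    if (M > 20000L) stop("exact method capped at 20000 lattice sites; use montecarlo", call. = FALSE)
    if (M < n) stop("lattice shorter than one footprint", call. = FALSE)
    dp <- cluster_dp(M, n, z, params$omega)
    if (dp$mean_C <= 0) {
      return(list(mean_cluster_size = NA_real_, theta = 0, mean_proteins = dp$mean_N,
                  mean_clusters = dp$mean_C, method = method))
    }
    list(mean_cluster_size = dp$mean_N / dp$mean_C,
         theta = dp$mean_N * n / M,
         mean_proteins = dp$mean_N, mean_clusters = dp$mean_C, method = method)
  } else {
    if (M < 10L * n) stop("montecarlo needs at least 10 * n lattice sites", call. = FALSE)
    # the sampler mixes slowly at strongly clustered conditions, so the error
    # is taken across independent chains, not from within-chain batches
    runs <- lapply(seq_len(chains), function(k)
      simulate_lattice(c_nM = c_nM, params = params, lattice_sites = M,
                       seed = seed + k - 1L, sweeps = sweeps, boundary = boundary,
                       start = if (k %% 2L == 0L) "packed" else "empty"))
    cs <- vapply(runs, function(r) {
      cl <- sum(r$n_clusters)
      if (cl > 0) sum(r$n_proteins) / cl else NA_real_
    }, numeric(1))
    th <- vapply(runs, function(r) mean(r$n_proteins) * n / M, numeric(1))
    # split-Rhat style equilibration check on the protein count
    cm <- vapply(runs, function(r) mean(r$n_proteins), numeric(1))
    cv <- vapply(runs, function(r) stats::var(r$n_proteins), numeric(1))
    W <- mean(cv)
    B <- sweeps * stats::var(cm)
    rhat <- if (W > 0) sqrt(((sweeps - 1) / sweeps * W + B / sweeps) / W) else 1
    if (is.finite(rhat) && rhat > 1.2)
      warning(sprintf("chains may not be equilibrated (Rhat = %.2f); increase sweeps", rhat),
              call. = FALSE)
    cs_ok <- cs[is.finite(cs)]
    list(mean_cluster_size = mean(cs_ok),
         theta = mean(th),
         theta_se = stats::sd(th) / sqrt(length(th)),
         mean_proteins = mean(vapply(runs, function(r) mean(r$n_proteins), numeric(1))),
         mean_clusters = mean(vapply(runs, function(r) mean(r$n_clusters), numeric(1))),
         se = if (length(cs_ok) > 1) stats::sd(cs_ok) / sqrt(length(cs_ok)) else NA_real_,
         rhat = rhat, method = method)
  }
}
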
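#' Thermal energy at room temperature
#'
#' Default thermal energy kT used throughout, 4.11 pN nm (T = 298 K).
#' @export
KT_ROOM <- 4.11

#' Mechanical parameters of the extensible worm-like chain
#'
#' Bundles the three mechanical parameters of the extensible WLC model of
#' double-stranded DNA together with the thermal energy.
#'
#' @param P_ds Persistence length, nm. Must be positive.
#' @param B_ds Contour length per base pair, nm/bp. Must be positive.
#' @param S_ds Elastic stretch modulus, pN. Must be positive.
#' @param kT Thermal energy, pN nm. Defaults to 4.11 (298 K).
#' @return An object of class `wlc_params`.
#' @examples
#' wlc_params(P_ds = 50, B_ds = 0.34, S_ds = 1200)
#' @export
wlc_params <- function(P_ds, B_ds, S_ds, kT = KT_ROOM) {
  for (nm in c("P_ds", "B_ds", "S_ds", "kT")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  structure(list(P_ds = P_ds, B_ds = B_ds, S_ds = S_ds, kT = kT),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("Extensible WLC: P_ds = %.4g nm, B_ds = %.6g nm/bp, S_ds = %.5g pN (kT = %.3g pN nm)\n",
              x$P_ds, x$B_ds, x$S_ds, x$kT))
  invisible(x)
}

#' Extensible WLC extension per base pair at a given force
#'
#' High-force interpolation of the extensible worm-like chain:
#' \deqn{b(F) = B_{ds} [ 1 - (1/2)\sqrt{kT/(P_{ds} F)} + F/S_{ds} ]}
#' returning the extension per base pair. Multiplying by the number of base
#' pairs gives the total tether extension. The model is quantitative roughly
#' between ~1 pN and 30 pN; a warning is issued above `f_flag`.
#'
#' @param F_pN Stretching force, pN. Vectorised; all values must be positive.
#' @param params A [wlc_params()] object.
#' @param f_flag Force above which a single warning flags out-of-range use
#'   (default 30 pN, the upper limit used in fitting).
#' @return Extension per base pair, nm/bp (same length as `F_pN`).
#' @examples
#' p <- wlc_params(50, 0.34, 1200)
#' wlc_extension(10, p)  # ~0.3274 nm/bp
#' @export
wlc_extension <- function(F_pN, params, f_flag = 30) {
  stopifnot(inherits(params, "wlc_params"))
  if (!is.numeric(F_pN) || any(!is.finite(F_pN)) || any(F_pN <= 0))
    stop("force must be positive and finite", call. = FALSE)
  if (any(F_pN > f_flag))
    warning(sprintf("evaluating WLC above %g pN; the interpolation is used for fits only below that force", f_flag), call. = FALSE)
  params$B_ds * (1 - 0.5 * sqrt(params$kT / (params$P_ds * F_pN)) + F_pN / params$S_ds)
}

#' Invert the extensible WLC: force at a given extension per base pair
#'
#' Numerical inversion of [wlc_extension()]. The extension per base pair is a
#' strictly increasing function of force on (0, Inf), so the inverse is unique.
#'
#' @param b_nm_bp Extension per base pair, nm/bp. Vectorised; must be positive.
#' @param params A [wlc_params()] object.
#' @param f_range Search bracket for the force, pN (default `c(1e-6, 1e5)`).
#' @param tol Relative tolerance of the root (default 1e-12).
#' @return Force, pN (same length as `b_nm_bp`).
#' @examples
#' p <- wlc_params(50, 0.34, 1200)
#' wlc_force(wlc_extension(10, p), p)  # 10
#' @export
wlc_force <- function(b_nm_bp, params, f_range = c(1e-6, 1e5), tol = 1e-12) {
  stopifnot(inherits(params, "wlc_params"))
  if (!is.numeric(b_nm_bp) || any(!is.finite(b_nm_bp)) || any(b_nm_bp <= 0))
    stop("extension per bp must be positive and finite", call. = FALSE)
  B <- params$B_ds; P <- params$P_ds; S <- params$S_ds; kT <- params$kT
  bfun <- function(f) B * (1 - 0.5 * sqrt(kT / (P * f)) + f / S)
  b_lo <- bfun(f_range[1]); b_hi <- bfun(f_range[2])
  if (any(b_nm_bp <= b_lo | b_nm_bp >= b_hi))
    stop(sprintf("extension outside invertible range (%.4g, %.4g) nm/bp", b_lo, b_hi),
         call. = FALSE)
  # initial guess: entropic branch inverse below the contour, enthalpic above
  x <- b_nm_bp / B
  f0 <- kT / (4 * P * pmax(1 - x, 1e-3)^2) + S * pmax(x - 1, 0)
  f <- pmin(pmax(f0, f_range[1] * 2), f_range[2] / 2)
  # Newton with analytic slope; b(F) is strictly increasing and smooth
  for (it in 1:60) {
    g <- bfun(f) - b_nm_bp
    dg <- B * (0.25 * sqrt(kT / P) * f^(-1.5) + 1 / S)
    step <- g / dg
    step <- pmin(pmax(step, -f * 0.9), f * 10)   # keep the iterate positive
    f <- f - step
    if (max(abs(step) / pmax(f, 1e-300)) < tol) break
  }
  f
}

## ---- 2D worm-like chain (AFM traces) --------------------------------------

#' Resample a 2D trace at uniform arc-length steps
#'
#' Arc-length parameterization with linear interpolation: returns points spaced
#' exactly `step` nm apart along the polyline contour.
#'
#' @param xy Two-column matrix of (x, y) coordinates in nm, ordered along the
#'   contour.
#' @param step Resampling step, nm.
#' @return Two-column matrix of resampled points (NULL if the contour is
#'   shorter than 2 steps).
#' @keywords internal
resample_trace <- function(xy, step) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 2, step > 0)
  seg <- sqrt(rowSums(diff(xy)^2))
  if (any(seg == 0)) {      # drop duplicated consecutive points
    keep <- c(TRUE, seg > 0)
    xy <- xy[keep, , drop = FALSE]
    if (nrow(xy) < 2) return(NULL)
    seg <- sqrt(rowSums(diff(xy)^2))
  }
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < 2 * step) return(NULL)
  s_new <- seq(0, total, by = step)
  cbind(stats::approx(s, xy[, 1], xout = s_new)$y,
        stats::approx(s, xy[, 2], xout = s_new)$y)
}

#' Tangent-correlation function of traced 2D molecules
#'
#' Measures the mean cosine of the angle between tangent directions separated
#' by contour distance L, pooled over all positions of all supplied traces.
#' Each trace is resampled at uniform arc-length `step`; the tangent of each
#' resampled segment is the direction between its endpoints (one-segment
#' tangents: wider stencils smooth the chain and bias the small-separation
#' correlations upward, which the no-amplitude exponential fit translates into
#' an inflated persistence length). Separations are multiples of `step` up to
#' `max_L`.
#'
#' @param traces A single two-column matrix or a list of two-column matrices of
#'   (x, y) points in nm; [trace2d()] objects are also accepted.
#' @param step Resampling step, nm (default 5).
#' @param max_L Maximum contour separation, nm (default 200).
#' @return A data.frame of class `tangent_correlation` with columns `L` (nm),
#'   `mean_cos_theta`, `counts` and `se` (standard error of the mean cosine).
#' @export
tangent_correlation <- function(traces, step = 5, max_L = 200) {
  if (is.matrix(traces) || is.data.frame(traces)) traces <- list(traces)
  traces <- lapply(traces, function(tr) if (inherits(tr, "trace2d")) tr$points else tr)
  n_lags <- floor(max_L / step)
  if (n_lags < 1) stop("max_L must be at least one step", call. = FALSE)
  # per-trace per-lag sums: positions pooled within a molecule are strongly
  # correlated, so uncertainties are taken across molecules
  tr_sums <- tr_counts <- tr_sumsq <- list()
  used <- 0L
  for (tr in traces) {
    rs <- resample_trace(tr, step)
    if (is.null(rs) || nrow(rs) < 3) {
      warning("trace shorter than 2 steps after resampling; skipped", call. = FALSE)
      next
    }
    used <- used + 1L
    # tangent angle of each resampled segment
    d <- diff(rs)
    ang <- atan2(d[, 2], d[, 1])
    m <- length(ang)
    s_k <- q_k <- c_k <- numeric(n_lags)
    for (k in seq_len(min(n_lags, m - 1))) {
      ct <- cos(ang[(1 + k):m] - ang[1:(m - k)])
      s_k[k] <- sum(ct); q_k[k] <- sum(ct^2); c_k[k] <- length(ct)
    }
    tr_sums[[used]] <- s_k; tr_sumsq[[used]] <- q_k; tr_counts[[used]] <- c_k
  }
  if (used == 0L) stop("no usable traces: all shorter than 2 steps", call. = FALSE)
  S <- do.call(rbind, tr_sums); Q <- do.call(rbind, tr_sumsq); C <- do.call(rbind, tr_counts)
  counts <- colSums(C)
  keep <- counts >= 1
  mu <- colSums(S)[keep] / counts[keep]
  se <- vapply(which(keep), function(k) {
    has <- C[, k] > 0
    if (sum(has) >= 2) {
      # count-weighted between-molecule standard error of the pooled mean
      mt <- S[has, k] / C[has, k]
      w <- C[has, k] / sum(C[has, k])
      m0 <- sum(w * mt)
      sqrt(sum(w^2 * (mt - m0)^2) * sum(has) / (sum(has) - 1))
    } else {
      # single molecule: fall back to the naive within-trace error
      v <- max(0, Q[has, k] / C[has, k] - (S[has, k] / C[has, k])^2)
      sqrt(v / C[has, k])
    }
  }, numeric(1))
  structure(data.frame(L = (seq_len(n_lags) * step)[keep],
                       mean_cos_theta = mu, counts = counts[keep], se = se),
            class = c("tangent_correlation", "data.frame"))
}

#' Fit the 2D WLC persistence length to a tangent-correlation curve
#'
#' Weighted least-squares fit of the planar worm-like-chain decay
#' \deqn{\langle\cos\theta\rangle = e^{-L/2p}}
#' to a [tangent_correlation()] result, performed on the mean cosines directly
#' (not log-transformed) with inverse-variance weights from the per-bin
#' standard errors.
#'
#' @param corr A `tangent_correlation` data.frame (columns `L`,
#'   `mean_cos_theta`, `counts`, optionally `se`).
#' @return A list with `p` (persistence length, nm), `se` (its standard error),
#'   `diverged` (TRUE when the data do not decay, e.g. perfectly straight
#'   traces, in which case `p` is `Inf`), and `n_bins`.
#' @export
fit_persistence_2d <- function(corr) {
  stopifnot(all(c("L", "mean_cos_theta") %in% names(corr)))
  corr <- corr[is.finite(corr$mean_cos_theta) & corr$L > 0, , drop = FALSE]
  if (nrow(corr) < 3) stop("need at least 3 separation bins", call. = FALSE)
  w <- if (!is.null(corr$se) && all(corr$se > 0)) 1 / corr$se^2 else rep(1, nrow(corr))
  # non-decaying input: no finite p
  if (all(corr$mean_cos_theta > 1 - 1e-12))
    return(list(p = Inf, se = NA_real_, diverged = TRUE, n_bins = nrow(corr)))
  # start from the log-slope of the decaying part
  pos <- corr$mean_cos_theta > 0.05
  p0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(corr$mean_cos_theta[pos]) ~ 0 + corr$L[pos]))[[1]]
    if (is.finite(sl) && sl < 0) -1 / (2 * sl) else max(corr$L) / 2
  } else max(corr$L) / 2
  fit <- minpack.lm::nls.lm(
    par = list(p = max(p0, 1e-3)),
    fn = function(par) sqrt(w) * (corr$mean_cos_theta - exp(-corr$L / (2 * par$p))),
    lower = 1e-6, upper = 1e9,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p_hat <- fit$par$p
  # covariance from the weighted Jacobian at the minimum
  se <- tryCatch({
    cv <- solve(fit$hessian)
    # with unit weights the residual variance scales the covariance
    scale <- if (is.null(corr$se) || any(corr$se <= 0))
      fit$deviance / max(1, nrow(corr) - 1) else 1
    sqrt(diag(cv) * scale)[[1]]
  }, error = function(e) NA_real_)
  list(p = p_hat, se = se, diverged = !is.finite(p_hat) || p_hat > 1e8,
       n_bins = nrow(corr))
}
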
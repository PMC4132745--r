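#' Construct a force-extension curve
#'
#' One optical-tweezers stretch (or release) of a single DNA tether: sampled
#' total extension (nm) and force (pN), with molecule metadata.
#'
#' @param extension Total tether extension, nm. Strictly increasing for
#'   `direction = "extend"`.
#' @param force Force, pN, same length.
#' @param n_bp Molecule size in base pairs (48500 for bacteriophage-lambda DNA).
#' @param concentration Protein concentration, nM (metadata; default 0).
#' @param pulling_rate Pulling rate, nm/s (metadata; default NA).
#' @param direction "extend" or "release".
#' @return An object of class `fec` (list with the fields above).
#' @export
fec <- function(extension, force, n_bp, concentration = 0,
                pulling_rate = NA_real_, direction = c("extend", "release")) {
  direction <- match.arg(direction)
  if (length(extension) != length(force) || length(force) < 2)
    stop("extension and force must have equal length >= 2", call. = FALSE)
  if (n_bp <= 0) stop("n_bp must be positive", call. = FALSE)
  if (direction == "extend" && any(diff(extension) <= 0))
    stop("extension must be strictly increasing for an extend curve", call. = FALSE)
  structure(list(extension = as.numeric(extension), force = as.numeric(force),
                 n_bp = n_bp, concentration = concentration,
                 pulling_rate = pulling_rate, direction = direction),
            class = "fec")
}

#' @export
print.fec <- function(x, ...) {
  cat(sprintf("Force-extension curve (%s): %d points, %g bp, %g nM protein, F in [%.3g, %.3g] pN\n",
              x$direction, length(x$force), x$n_bp, x$concentration,
              min(x$force), max(x$force)))
  invisible(x)
}

#' Fit a force-extension curve to the extensible WLC model
#'
#' Least-squares fit of the extensible WLC to the data up to `f_max` (default
#' 30 pN, above which the interpolation formula is no longer quantitative),
#' returning persistence length, contour length per bp and stretch modulus with
#' covariance-based standard errors. Residuals are taken in force (measured
#' force minus the model force at the recorded extension): tweezers noise lives
#' on the force channel, and fitting extension against a noisy force regressor
#' would bias the parameters through the model's curvature.
#'
#' @param curve A [fec()] object.
#' @param f_max Upper force cutoff for the fit, pN (default 30).
#' @param f_min Lower cutoff on the measured force, pN (default -Inf: no lower
#'   cut; residuals are in force, so noisy low-force samples carry little
#'   weight, whereas cutting on the noisy measured force would select
#'   positive-noise points and bias the fit).
#' @param kT Thermal energy, pN nm (default 4.11).
#' @param start Optional named list of start values (P_ds, B_ds, S_ds).
#' @return A list of class `wlc_fit`: `params` (a [wlc_params()]), `se` (named
#'   standard errors), `rss`, `n_points`.
#' @export
fit_force_extension <- function(curve, f_max = 30, f_min = -Inf, kT = KT_ROOM,
                                start = list(P_ds = 45, B_ds = 0.34, S_ds = 1000)) {
  stopifnot(inherits(curve, "fec"))
  sel <- curve$force >= f_min & curve$force <= f_max
  if (sum(sel) < 10) stop("need at least 10 points below the force cutoff", call. = FALSE)
  Fv <- curve$force[sel]
  if (max(Fv) < 5) stop("insufficient force range: curve must reach 5 pN below the cutoff", call. = FALSE)
  b <- curve$extension[sel] / curve$n_bp
  resid_fn <- function(par) {
    pars <- wlc_params(par$P_ds, par$B_ds, par$S_ds, kT = kT)
    ok <- tryCatch(wlc_force(b, pars), error = function(e) NULL)
    if (is.null(ok)) return(rep(1e6, length(Fv)))
    Fv - ok
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(1e-3, 1e-4, 1),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  cv <- tryCatch(solve(fit$hessian) * fit$deviance / max(1, length(b) - 3),
                 error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cv), 0))
  names(se) <- c("P_ds", "B_ds", "S_ds")
  structure(list(params = wlc_params(fit$par$P_ds, fit$par$B_ds, fit$par$S_ds, kT = kT),
                 se = se, rss = fit$deviance, n_points = length(b)),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("WLC fit (%d points): P_ds = %.4g +/- %.2g nm, B_ds = %.5g +/- %.2g nm/bp, S_ds = %.4g +/- %.2g pN\n",
              x$n_points, x$params$P_ds, x$se["P_ds"], x$params$B_ds, x$se["B_ds"],
              x$params$S_ds, x$se["S_ds"]))
  invisible(x)
}

#' Overstretching force of a curve
#'
#' Mean force (with standard error) over the extension window 0.42-0.48 nm/bp,
#' the cooperative overstretching plateau of duplex DNA.
#'
#' @param curve A [fec()] object.
#' @param b_lo,b_hi Extension-per-bp window bounds, nm/bp.
#' @return A list with `F_ov` (pN), `se` and `n_points`.
#' @export
overstretch_force <- function(curve, b_lo = 0.42, b_hi = 0.48) {
  stopifnot(inherits(curve, "fec"))
  b <- curve$extension / curve$n_bp
  sel <- b >= b_lo & b <= b_hi
  if (sum(sel) < 3)
    stop(sprintf("fewer than 3 samples with extension/bp in [%.2f, %.2f] nm/bp", b_lo, b_hi),
         call. = FALSE)
  f <- curve$force[sel]
  list(F_ov = mean(f), se = stats::sd(f) / sqrt(length(f)), n_points = length(f))
}

#' Detect loop-rupture force jumps on an extend curve
#'
#' Scans an extend curve for sudden force drops — the sawtooth signature of a
#' protein-stabilized DNA loop releasing sequestered contour length. At each
#' candidate position the local force level is estimated by a linear fit over
#' `window` samples on each side (with a `guard`-sample gap around the
#' transition) and both fits are extrapolated to the candidate: the gap between
#' them is the estimated force drop. Averaging over flanking windows keeps the
#' noise on the drop estimate well below the 1.0 pN counting threshold at
#' realistic force noise (~0.2 pN at sigma 0.3 pN with the default window),
#' while raw point-to-point ranges of that noise routinely exceed 1 pN. A
#' candidate also requires a rising trend (positive fitted slope) on both
#' sides. Contiguous candidate runs are collapsed to the position of the
#' largest estimated drop, so returned events are ordered and non-overlapping.
#'
#' @param curve A [fec()] object with `direction = "extend"`.
#' @param min_delta_F Minimum force drop to count, pN (default 1.0, the
#'   maximum force noise level in the presence of protein).
#' @param window Samples in each flanking linear fit (default 25).
#' @param guard Samples skipped after the candidate before the right window
#'   starts (default 1; the drop itself may span a couple of samples).
#' @return An integer vector of jump indices (last sample before each drop);
#'   empty for smooth curves.
#' @export
detect_loop_jumps <- function(curve, min_delta_F = 1.0, window = 25L, guard = 1L) {
  stopifnot(inherits(curve, "fec"))
  if (curve$direction != "extend")
    stop("loop jumps are only scanned on extend curves", call. = FALSE)
  x <- curve$extension; y <- curve$force
  m <- length(y)
  w <- as.integer(window); g <- as.integer(guard)
  if (m < 2L * w + g + 2L) return(integer(0))
  # rolling sums ending at each index (sides = 1 convolution)
  rs <- function(v) as.numeric(stats::filter(v, rep(1, w), sides = 1))
  Sy <- rs(y); Sx <- rs(x); Sxx <- rs(x * x); Sxy <- rs(x * y)
  slope <- (w * Sxy - Sx * Sy) / (w * Sxx - Sx^2)
  inter <- (Sy - slope * Sx) / w
  # candidate i: left window (i-w+1..i), right window (i+1+g..i+w+g)
  idx <- (w):(m - w - g - 1L)
  iR <- idx + w + g                      # right window's last sample
  x_mid <- (x[idx] + x[idx + 1L]) / 2
  predL <- inter[idx] + slope[idx] * x_mid
  predR <- inter[iR] + slope[iR] * x_mid
  drop <- predL - predR
  ok <- drop >= min_delta_F & slope[idx] > 0 & slope[iR] > 0
  ok[!is.finite(drop)] <- FALSE
  if (!any(ok)) return(integer(0))
  # collapse contiguous candidate runs (gaps <= w/2) to the strongest position
  cand <- idx[ok]; dcand <- drop[ok]
  grp <- cumsum(c(1, diff(cand) > w / 2))
  events <- vapply(split(seq_along(cand), grp), function(ii) {
    cand[ii][which.max(dcand[ii])]
  }, integer(1))
  unname(sort(events))
}

#' Size the DNA loop released at a force jump
#'
#' Fits the extensible WLC to the curve segments flanking a detected jump with
#' only the contour length per bp free (persistence length and stretch modulus
#' held fixed), and converts the contour-length change to a loop size in base
#' pairs: `loop_bp = delta_B * n_bp / 0.34`.
#'
#' The one-parameter fit is the exact weighted projection
#' B = sum(b g) / sum(g^2) with g(F) the unit-contour WLC shape.
#'
#' @param curve A [fec()] object.
#' @param jump_index Index of the local max before the drop (from
#'   [detect_loop_jumps()]).
#' @param fixed_P Persistence length held fixed, nm.
#' @param fixed_S Stretch modulus held fixed, pN.
#' @param seg_before,seg_after Index ranges of the flanking segments; default
#'   the 30 samples before the jump and samples 3-32 after it.
#' @param kT Thermal energy, pN nm.
#' @param nm_per_bp Crystallographic DNA rise used for the bp conversion
#'   (0.34 nm/bp).
#' @return A list of class `loop_event`: `extension_at_jump`, `F_before`,
#'   `F_after`, `delta_F`, `B_before`, `B_after`, `delta_B`, `loop_bp`,
#'   `sized` (FALSE when a flanking segment was too short; the event is kept
#'   but the size is NA).
#' @export
size_loop <- function(curve, jump_index, fixed_P, fixed_S,
                      seg_before = NULL, seg_after = NULL,
                      kT = KT_ROOM, nm_per_bp = 0.34) {
  stopifnot(inherits(curve, "fec"))
  m <- length(curve$force)
  f <- curve$force
  # local minimum after the jump
  j_min <- jump_index + which.min(f[(jump_index + 1):min(m, jump_index + 10L)])
  if (is.null(seg_before)) seg_before <- max(1L, jump_index - 30L):jump_index
  if (is.null(seg_after)) seg_after <- j_min:min(m, j_min + 29L)
  ev <- list(extension_at_jump = curve$extension[jump_index],
             F_before = f[jump_index], F_after = f[j_min],
             delta_F = f[jump_index] - f[j_min],
             B_before = NA_real_, B_after = NA_real_,
             delta_B = NA_real_, loop_bp = NA_real_, sized = FALSE)
  if (length(seg_before) < 5 || length(seg_after) < 5) {
    warning("flanking segment too short; loop size unavailable", call. = FALSE)
    return(structure(ev, class = "loop_event"))
  }
  fit_B <- function(idx) {
    Fv <- f[idx]
    ok <- Fv > 0
    Fv <- Fv[ok]
    b <- curve$extension[idx][ok] / curve$n_bp
    g <- 1 - 0.5 * sqrt(kT / (fixed_P * Fv)) + Fv / fixed_S
    sum(b * g) / sum(g^2)
  }
  ev$B_before <- fit_B(seg_before)
  ev$B_after <- fit_B(seg_after)
  ev$delta_B <- ev$B_after - ev$B_before
  ev$loop_bp <- ev$delta_B * curve$n_bp / nm_per_bp
  ev$sized <- TRUE
  structure(ev, class = "loop_event")
}

#' Detect and size all loop-rupture events of a curve
#'
#' Runs [detect_loop_jumps()] and [size_loop()] with flanking segments bounded
#' by neighbouring events, fixing P and S at values fitted to the final
#' (loop-free) portion of the same curve unless supplied.
#'
#' @param curve A [fec()] object (extend direction).
#' @param min_delta_F Detection threshold, pN (default 1.0).
#' @param fixed_P,fixed_S Fixed persistence length (nm) and stretch modulus
#'   (pN); fitted from the post-last-jump segment when NULL.
#' @param ... Passed to [detect_loop_jumps()].
#' @return A data.frame with one row per event (columns of `loop_event`).
#' @export
analyze_loops <- function(curve, min_delta_F = 1.0, fixed_P = NULL, fixed_S = NULL, ...) {
  idx <- detect_loop_jumps(curve, min_delta_F = min_delta_F, ...)
  if (length(idx) == 0)
    return(data.frame(extension_at_jump = numeric(0), F_before = numeric(0),
                      F_after = numeric(0), delta_F = numeric(0),
                      B_before = numeric(0), B_after = numeric(0),
                      delta_B = numeric(0), loop_bp = numeric(0), sized = logical(0)))
  if (is.null(fixed_P) || is.null(fixed_S)) {
    # fit the loop-free tail after the last jump
    m <- length(curve$force)
    last_min <- idx[length(idx)] + which.min(curve$force[(idx[length(idx)] + 1):min(m, idx[length(idx)] + 10L)])
    tail_idx <- (last_min + 2L):m
    tail_curve <- fec(curve$extension[tail_idx], curve$force[tail_idx], curve$n_bp,
                      curve$concentration, curve$pulling_rate, "extend")
    tail_fit <- fit_force_extension(tail_curve)
    if (is.null(fixed_P)) fixed_P <- tail_fit$params$P_ds
    if (is.null(fixed_S)) fixed_S <- tail_fit$params$S_ds
  }
  bounds <- c(0L, idx, length(curve$force) + 1L)
  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    m <- length(curve$force)
    j_min <- i + which.min(curve$force[(i + 1):min(m, i + 10L)])
    before <- max(bounds[k] + 6L, i - 30L):i
    nxt <- min(bounds[k + 2L] - 1L, j_min + 29L, m)
    after <- if (j_min <= nxt) j_min:nxt else integer(0)
    ev <- size_loop(curve, i, fixed_P, fixed_S, seg_before = before, seg_after = after)
    as.data.frame(unclass(ev))
  })
  do.call(rbind, rows)
}

#' Histograms of loop sizes and breaking forces
#'
#' @param events Data.frame of loop events (from [analyze_loops()]); events
#'   with `delta_F` below `censor_below` are excluded (and the exclusion
#'   reported), mirroring the 1.0 pN noise-censoring of the event counts.
#' @param bp_bin Loop-size bin width, bp (default 200).
#' @param force_bin Breaking-force bin width, pN (default 5).
#' @param censor_below Censoring threshold on the force drop, pN (default 1.0).
#' @return A list with `size` and `force` histogram data.frames (bin_lo,
#'   bin_hi, count), the modal bins, and `n_censored`.
#' @export
loop_histograms <- function(events, bp_bin = 200, force_bin = 5, censor_below = 1.0) {
  if (nrow(events) == 0) {
    warning("no events; empty histograms", call. = FALSE)
    return(list(size = data.frame(bin_lo = numeric(0), bin_hi = numeric(0), count = integer(0)),
                force = data.frame(bin_lo = numeric(0), bin_hi = numeric(0), count = integer(0)),
                modal_size_bin = c(NA_real_, NA_real_), modal_force_bin = c(NA_real_, NA_real_),
                n_censored = 0L))
  }
  keep <- events$delta_F >= censor_below
  n_censored <- sum(!keep)
  ev <- events[keep & events$sized, , drop = FALSE]
  hist1 <- function(x, w) {
    br <- seq(0, (floor(max(x) / w) + 1) * w, by = w)
    ct <- as.integer(table(cut(x, br, right = FALSE)))
    data.frame(bin_lo = br[-length(br)], bin_hi = br[-1], count = ct)
  }
  hs <- hist1(ev$loop_bp, bp_bin)
  hf <- hist1(ev$F_before, force_bin)
  modal <- function(h) if (nrow(h) == 0) c(NA_real_, NA_real_) else
    unlist(h[which.max(h$count), c("bin_lo", "bin_hi")], use.names = FALSE)
  list(size = hs, force = hf,
       modal_size_bin = modal(hs), modal_force_bin = modal(hf),
       n_censored = n_censored)
}

#' Fit constant-force compaction kinetics to a single exponential
#'
#' Fits extension-vs-time data recorded while the tether is held at constant
#' force and exposed to protein: x(t) = baseline + amplitude * exp(-k t).
#'
#' @param times Times, s.
#' @param extensions Extensions, nm.
#' @return A list of class `compaction_fit`: `k` (1/s), `k_se`, `tau` (s),
#'   `tau_se`, `amplitude` (nm), `baseline` (nm), `rejected` (TRUE for
#'   non-decaying input, in which case the other fields are NA), and
#'   `span_warning` (TRUE when the record spans fewer than 2 time constants).
#' @export
compaction_fit <- function(times, extensions) {
  stopifnot(length(times) == length(extensions))
  if (length(times) < 10) stop("need at least 10 samples", call. = FALSE)
  o <- order(times)
  t <- times[o]; x <- extensions[o]
  rng <- max(x) - min(x)
  # crude decay check: overall downward drift beyond noise scale
  first <- mean(x[seq_len(max(3, length(x) %/% 5))])
  last <- mean(x[seq(length(x) - max(3, length(x) %/% 5) + 1, length(x))])
  rej <- list(k = NA_real_, k_se = NA_real_, tau = NA_real_, tau_se = NA_real_,
              amplitude = NA_real_, baseline = mean(x), rejected = TRUE,
              span_warning = FALSE)
  if (rng == 0 || first <= last) {
    warning("series does not decay; exponential fit rejected", call. = FALSE)
    return(structure(rej, class = "compaction_fit"))
  }
  k0 <- 1 / (diff(range(t)) / 3)
  fit <- minpack.lm::nls.lm(
    par = list(baseline = min(x), amplitude = first - last, k = k0),
    fn = function(par) x - (par$baseline + par$amplitude * exp(-par$k * t)),
    lower = c(-Inf, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$par$amplitude <= 1e-12 * rng || fit$par$k <= 1e-9) {
    warning("fitted amplitude or rate collapsed to zero; fit rejected", call. = FALSE)
    return(structure(rej, class = "compaction_fit"))
  }
  cv <- tryCatch(solve(fit$hessian) * fit$deviance / max(1, length(x) - 3),
                 error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cv), 0))
  k <- fit$par$k
  span_warning <- diff(range(t)) < 2 / k
  if (span_warning)
    warning("record spans fewer than 2 time constants; rate poorly constrained", call. = FALSE)
  structure(list(k = k, k_se = se[3], tau = 1 / k, tau_se = se[3] / k^2,
                 amplitude = fit$par$amplitude, baseline = fit$par$baseline,
                 rejected = FALSE, span_warning = span_warning),
            class = "compaction_fit")
}

#' @export
print.compaction_fit <- function(x, ...) {
  if (x$rejected) cat("Compaction fit: rejected (non-decaying series)\n")
  else cat(sprintf("Compaction fit: k = %.3g +/- %.2g 1/s (tau = %.3g +/- %.2g s), amplitude %.4g nm, baseline %.4g nm\n",
                   x$k, x$k_se, x$tau, x$tau_se, x$amplitude, x$baseline))
  invisible(x)
}

#' Compaction force from paired release curves
#'
#' Mean force difference (protein minus naked) over the low-extension window,
#' i.e. extensions below `low_ext_fraction` of the naked contour length. The
#' curves are aligned on a common extension grid by linear interpolation.
#'
#' @param release_protein Release curve after protein exposure, a [fec()].
#' @param release_naked Protein-free release curve of the same tether.
#' @param low_ext_fraction Fraction of the naked contour length defining the
#'   low-extension window (default 0.2).
#' @param contour_nm Naked contour length, nm; default `n_bp * 0.34`.
#' @param n_grid Interpolation grid size (default 50).
#' @return A list with `delta_F_c` (pN), `se` and `n_points`.
#' @export
compaction_force <- function(release_protein, release_naked,
                             low_ext_fraction = 0.2, contour_nm = NULL,
                             n_grid = 50L) {
  stopifnot(inherits(release_protein, "fec"), inherits(release_naked, "fec"))
  if (is.null(contour_nm)) contour_nm <- release_naked$n_bp * 0.34
  x_max <- low_ext_fraction * contour_nm
  lo <- max(min(release_protein$extension), min(release_naked$extension))
  hi <- min(max(release_protein$extension), max(release_naked$extension), x_max)
  if (hi <= lo)
    stop("curves do not overlap in the low-extension window", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  fp <- stats::approx(release_protein$extension, release_protein$force, xout = grid)$y
  fn <- stats::approx(release_naked$extension, release_naked$force, xout = grid)$y
  d <- fp - fn
  list(delta_F_c = mean(d), se = stats::sd(d) / sqrt(length(d)), n_points = length(d))
}
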
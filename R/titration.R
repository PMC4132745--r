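#' Construct a titration series
#'
#' A concentration series of one mechanical observable (persistence length,
#' contour length per bp, or overstretching force) with per-point standard
#' errors, as measured from repeated force-extension fits at each protein
#' concentration.
#'
#' @param observable One of "persistence", "contour", "overstretch".
#' @param c_nM Protein concentrations, nM. Must contain 0 (the protein-free
#'   anchor) and at least 4 distinct values.
#' @param y Observable values (nm, nm/bp, or pN).
#' @param sigma Standard errors, same units as `y`. Positive.
#' @param N Replicate counts per point (default 1).
#' @return A data.frame of class `titration_series` with attribute
#'   `observable`.
#' @export
titration_series <- function(observable = c("persistence", "contour", "overstretch"),
                             c_nM, y, sigma, N = 1L) {
  observable <- match.arg(observable)
  stopifnot(length(c_nM) == length(y), length(y) == length(sigma))
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (length(unique(c_nM)) < 4) stop("need at least 4 distinct concentrations", call. = FALSE)
  if (!any(c_nM == 0)) stop("series must include a protein-free (c = 0) anchor", call. = FALSE)
  d <- data.frame(c_nM = c_nM, y = y, sigma = sigma, N = N)
  d <- d[order(d$c_nM), , drop = FALSE]
  structure(d, class = c("titration_series", "data.frame"), observable = observable)
}

# Model curve: occupancy at each concentration mapped to the observable
titration_model <- function(c_nM, K_D, omega, saturated, free_value, observable, n) {
  th <- mvh_occupancy(c_nM, binding_params(K_D, omega, n))$theta
  if (observable == "persistence") occupancy_map_P(th, P_D = free_value, P_L = saturated)
  else occupancy_map_linear(th, x_D = free_value, x_L = saturated)
}

#' Fit a titration series to the cooperative binding model
#'
#' Three-parameter chi-square fit of an observable-vs-concentration series to
#' the McGhee-von Hippel occupancy model: the dissociation constant `K_D`, the
#' cooperativity `omega` and the protein-saturated observable value are varied
#' while the binding site size `n` is held fixed and the protein-free value is
#' anchored at the c = 0 data. The occupancy is mapped to the observable by the
#' harmonic persistence map or the linear map depending on the observable.
#'
#' The chi-square surface is ridge-prone in (K_D, omega), so a 5 x 5 grid of
#' Levenberg-Marquardt starts over log10(K_D) in [-2, 3] and log10(omega) in
#' [0, 3] is used and the lowest chi-square solution returned. Uncertainties
#' come from the local covariance (inverse curvature) at the minimum.
#'
#' @param series A [titration_series()].
#' @param n Binding site size held fixed, bp (default 26).
#' @param protein_free_value The protein-free observable value; defaults to the
#'   inverse-variance weighted mean of the c = 0 points.
#' @param starts Optional matrix of (K_D, omega) start values; by default the
#'   5 x 5 log grid.
#' @return A list of class `titration_fit`: `K_D`, `K_D_se`, `omega`,
#'   `omega_se`, `saturated_value`, `saturated_se`, `chi2`, `dof`, `n_fixed`,
#'   `observable`, `protein_free_value`, `flat_omega` (TRUE when the
#'   chi-square surface is flat in omega, an identifiability warning), and
#'   `model` (function of concentration).
#' @export
fit_titration <- function(series, n = 26L, protein_free_value = NULL, starts = NULL) {
  stopifnot(inherits(series, "titration_series"))
  observable <- attr(series, "observable")
  anchor <- series$c_nM == 0
  if (is.null(protein_free_value)) {
    w0 <- 1 / series$sigma[anchor]^2
    protein_free_value <- sum(series$y[anchor] * w0) / sum(w0)
  }
  d <- series[!anchor, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 non-zero concentrations", call. = FALSE)
  # saturated-value start: the most extreme observed value
  sat0 <- if (observable == "persistence") min(d$y) else d$y[which.max(abs(d$y - protein_free_value))]
  if (is.null(starts)) {
    g <- expand.grid(lK = seq(-2, 3, length.out = 5), lw = seq(0, 3, length.out = 5))
    starts <- cbind(K_D = 10^g$lK, omega = 10^g$lw)
  }
  resid_fn <- function(par) {
    m <- tryCatch(
      titration_model(d$c_nM, par$K_D, par$omega, par$sat, protein_free_value, observable, n),
      error = function(e) rep(Inf, nrow(d)))
    r <- (d$y - m) / d$sigma
    r[!is.finite(r)] <- 1e6
    r
  }
  # pre-screen the start grid by chi2 at the start values (sat at its start)
  # and refine only the most promising starts; the surface is ridge-prone but
  # smooth, so 5 polished starts cover the grid's basins
  chi0 <- vapply(seq_len(nrow(starts)), function(i)
    sum(resid_fn(list(K_D = starts[i, 1], omega = starts[i, 2], sat = sat0))^2),
    numeric(1))
  starts <- starts[order(chi0)[seq_len(min(5L, nrow(starts)))], , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(K_D = starts[i, 1], omega = starts[i, 2], sat = sat0),
        fn = resid_fn,
        lower = c(1e-6, 1e-6, if (observable == "persistence") 1e-3 else -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("titration fit failed to converge from every start", call. = FALSE)
  p <- best$par
  cv <- tryCatch(solve(best$hessian), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cv), 0))
  # flat chi-square in omega: curvature indistinguishable from zero
  flat_omega <- !is.finite(se[2]) || se[2] > 100 * p$omega
  if (flat_omega) warning("chi-square surface is nearly flat in omega; cooperativity poorly identified", call. = FALSE)
  structure(list(
    K_D = unname(p$K_D), K_D_se = unname(se[1]),
    omega = unname(p$omega), omega_se = unname(se[2]),
    saturated_value = unname(p$sat), saturated_se = unname(se[3]),
    chi2 = best$deviance, dof = nrow(d) - 3L,
    n_fixed = as.integer(n), observable = observable,
    protein_free_value = protein_free_value,
    flat_omega = flat_omega,
    model = function(c_nM) titration_model(c_nM, p$K_D, p$omega, p$sat,
                                           protein_free_value, observable, n)
  ), class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit (%s, n = %d bp fixed):\n", x$observable, x$n_fixed))
  cat(sprintf("  K_D   = %.3g +/- %.2g nM\n", x$K_D, x$K_D_se))
  cat(sprintf("  omega = %.3g +/- %.2g\n", x$omega, x$omega_se))
  cat(sprintf("  saturated value = %.4g +/- %.2g\n", x$saturated_value, x$saturated_se))
  cat(sprintf("  chi2 = %.3g on %d dof\n", x$chi2, x$dof))
  invisible(x)
}

#' Inverse-variance weighted combination of independent estimates
#'
#' Combines independent estimates of the same parameter (e.g. K_D from the
#' persistence, contour and overstretching titrations) by the weighted mean
#' with weights 1/sigma^2; the uncertainty of the weighted mean is
#' 1/sqrt(sum 1/sigma^2).
#'
#' @param values Estimates.
#' @param sigmas Their standard errors (positive, same length).
#' @return A list with `value`, `uncertainty` and `inputs` (a data.frame).
#' @examples
#' combine_weighted(c(2.1, 1.9, 2.8), c(0.8, 0.7, 0.6))  # 2.3 +/- 0.4
#' @export
combine_weighted <- function(values, sigmas) {
  if (length(values) == 0) stop("no estimates to combine", call. = FALSE)
  stopifnot(length(values) == length(sigmas))
  if (any(sigmas <= 0)) stop("sigmas must be positive", call. = FALSE)
  w <- 1 / sigmas^2
  list(value = sum(values * w) / sum(w),
       uncertainty = 1 / sqrt(sum(w)),
       inputs = data.frame(value = values, sigma = sigmas))
}
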
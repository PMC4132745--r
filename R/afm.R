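#' Construct a traced 2D molecule
#'
#' An ordered planar polyline of one deposited molecule (already traced from
#' the AFM image), with optional annotations marking protein sites, loops and
#' bridges. Annotations are a data.frame with columns `kind` (one of
#' "protein_site", "loop", "bridge"), `start_index`, `end_index` (point
#' indices; for protein sites start == end; a loop's index range must form a
#' closed circuit, i.e. start and end points coincide within `closure_tol`).
#'
#' @param molecule_id Identifier.
#' @param points Two-column matrix/data.frame of (x, y) in nm, ordered along
#'   the contour; at least 3 points, consecutive points distinct.
#' @param n_bp Molecule size, bp (4361 for linearized pBR322; default NA).
#' @param annotations Optional annotation data.frame (see above).
#' @param closure_tol Closure tolerance for loop annotations, nm (default 5).
#' @return An object of class `trace2d`.
#' @export
trace2d <- function(molecule_id, points, n_bp = NA_real_, annotations = NULL,
                    closure_tol = 5) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2 || nrow(points) < 3)
    stop("points must be an (x, y) matrix with at least 3 rows", call. = FALSE)
  if (any(rowSums(diff(points)^2) == 0))
    stop("consecutive trace points must be distinct", call. = FALSE)
  if (!is.null(annotations)) {
    stopifnot(all(c("kind", "start_index", "end_index") %in% names(annotations)))
    bad <- !annotations$kind %in% c("protein_site", "loop", "bridge")
    if (any(bad)) stop("unknown annotation kind", call. = FALSE)
    loops <- annotations[annotations$kind == "loop", , drop = FALSE]
    for (i in seq_len(nrow(loops))) {
      a <- loops$start_index[i]; b <- loops$end_index[i]
      if (a < 1 || b > nrow(points) || b <= a)
        stop("loop annotation indices out of range", call. = FALSE)
      if (sqrt(sum((points[a, ] - points[b, ])^2)) > closure_tol)
        stop(sprintf("loop annotation %d is not a closed circuit (gap > %g nm)", i, closure_tol),
             call. = FALSE)
    }
  }
  structure(list(molecule_id = molecule_id, points = points, n_bp = n_bp,
                 annotations = annotations),
            class = "trace2d")
}

#' @export
print.trace2d <- function(x, ...) {
  na <- if (is.null(x$annotations)) 0L else nrow(x$annotations)
  cat(sprintf("Trace2D '%s': %d points, %s bp, %d annotations\n",
              as.character(x$molecule_id), nrow(x$points),
              ifelse(is.na(x$n_bp), "?", format(x$n_bp)), na))
  invisible(x)
}

# contour (arc-length) coordinate of each trace point
contour_coord <- function(points) c(0, cumsum(sqrt(rowSums(diff(points)^2))))

# total-least-squares direction of a point cloud, sign-aligned with traversal
segment_direction <- function(pts) {
  if (nrow(pts) == 2) {
    d <- pts[2, ] - pts[1, ]
    return(d / sqrt(sum(d^2)))
  }
  ctr <- colMeans(pts)
  v <- svd(sweep(pts, 2, ctr))$v[, 1]
  span <- pts[nrow(pts), ] - pts[1, ]
  if (sum(v * span) < 0) v <- -v
  v
}

#' Local DNA bend angle at an annotated site
#'
#' Angle between the incoming and outgoing tangent directions at a trace point,
#' each direction estimated by a total-least-squares line fit over `arm_length`
#' of contour on its side. 0 degrees = straight (collinear tangents); angles
#' are folded into [0, 180].
#'
#' @param trace A [trace2d()].
#' @param site_index Index of the site point.
#' @param arm_length Contour length of each tangent arm, nm (default 10).
#' @return Bend angle in degrees.
#' @export
bend_angle_at_site <- function(trace, site_index, arm_length = 10) {
  stopifnot(inherits(trace, "trace2d"))
  pts <- trace$points
  s <- contour_coord(pts)
  s0 <- s[site_index]
  if (s0 < arm_length || s[length(s)] - s0 < arm_length)
    stop("site closer than one arm length to a trace end", call. = FALSE)
  before <- which(s >= s0 - arm_length & s <= s0)
  after <- which(s >= s0 & s <= s0 + arm_length)
  if (length(before) < 2 || length(after) < 2)
    stop("too few points within the arm length; retrace or enlarge arm_length", call. = FALSE)
  d_in <- segment_direction(pts[before, , drop = FALSE])
  d_out <- segment_direction(pts[after, , drop = FALSE])
  cosang <- max(-1, min(1, sum(d_in * d_out)))
  acos(cosang) * 180 / pi
}

#' Fit a bi-Gaussian to a bend-angle distribution
#'
#' Fits a single-peak Gaussian with distinct left and right standard deviations
#' (the bi-Gaussian convention of the bend-angle literature) to the binned
#' angle histogram; a sum-of-two-Gaussians alternative is available with
#' `flavor = "two_component"`. Sample mean and SD of the raw angles are always
#' reported.
#'
#' @param angles Bend angles, degrees, in [0, 180]; at least 30 values.
#' @param bin_width Histogram bin width, degrees (default 10).
#' @param flavor "asymmetric" (default) or "two_component".
#' @return A list of class `bigaussian_fit`: `center` (degrees), `sigma_left`,
#'   `sigma_right` (for "asymmetric"), or `centers`/`sigmas`/`weights` (for
#'   "two_component"); `mean_angle`, `sd_angle` (sample statistics), `rejected`
#'   (TRUE for degenerate input, sample stats still returned).
#' @export
fit_bigaussian <- function(angles, bin_width = 10, flavor = c("asymmetric", "two_component")) {
  flavor <- match.arg(flavor)
  if (length(angles) < 30) stop("need at least 30 angles", call. = FALSE)
  if (any(angles < 0 | angles > 180)) stop("angles must lie in [0, 180] degrees", call. = FALSE)
  mean_angle <- mean(angles); sd_angle <- stats::sd(angles)
  base <- list(mean_angle = mean_angle, sd_angle = sd_angle, flavor = flavor)
  if (sd_angle < 1e-9) {
    warning("degenerate angle sample; fit rejected, sample stats returned", call. = FALSE)
    return(structure(c(base, list(center = mean_angle, sigma_left = NA_real_,
                                  sigma_right = NA_real_, rejected = TRUE)),
                     class = "bigaussian_fit"))
  }
  br <- seq(0, 180 + bin_width, by = bin_width)
  h <- graphics::hist(angles, breaks = br, plot = FALSE)
  x <- h$mids; y <- h$density
  keep <- y > 0 | (x > min(angles) & x < max(angles))
  x <- x[keep]; y <- h$density[keep]
  if (flavor == "asymmetric") {
    model <- function(par) {
      s <- ifelse(x < par$mu, par$sL, par$sR)
      par$A * exp(-(x - par$mu)^2 / (2 * s^2))
    }
    fit <- minpack.lm::nls.lm(
      par = list(A = max(y), mu = x[which.max(y)], sL = sd_angle, sR = sd_angle),
      fn = function(par) y - model(par),
      lower = c(1e-12, 0, 1e-3, 1e-3), upper = c(Inf, 180, 360, 360),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    structure(c(base, list(center = fit$par$mu, sigma_left = fit$par$sL,
                           sigma_right = fit$par$sR, amplitude = fit$par$A,
                           rejected = FALSE)),
              class = "bigaussian_fit")
  } else {
    q <- stats::quantile(angles, c(0.25, 0.75))
    fit <- minpack.lm::nls.lm(
      par = list(A1 = max(y), mu1 = q[[1]], s1 = sd_angle / 2,
                 A2 = max(y) / 2, mu2 = q[[2]], s2 = sd_angle / 2),
      fn = function(par) y - (par$A1 * exp(-(x - par$mu1)^2 / (2 * par$s1^2)) +
                                par$A2 * exp(-(x - par$mu2)^2 / (2 * par$s2^2))),
      lower = c(0, 0, 1e-3, 0, 0, 1e-3), upper = c(Inf, 180, 360, Inf, 180, 360),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    structure(c(base, list(centers = c(fit$par$mu1, fit$par$mu2),
                           sigmas = c(fit$par$s1, fit$par$s2),
                           amplitudes = c(fit$par$A1, fit$par$A2),
                           rejected = FALSE)),
              class = "bigaussian_fit")
  }
}

#' @export
print.bigaussian_fit <- function(x, ...) {
  cat(sprintf("Bend angles: mean %.3g deg, SD %.3g deg (n sample stats)\n", x$mean_angle, x$sd_angle))
  if (!x$rejected && x$flavor == "asymmetric")
    cat(sprintf("  bi-Gaussian: center %.3g deg, sigma_left %.3g, sigma_right %.3g\n",
                x$center, x$sigma_left, x$sigma_right))
  invisible(x)
}

#' Loop size in base pairs from a traced loop
#'
#' Contour length of the annotated closed circuit converted to base pairs. By
#' default the crystallographic rise (0.34 nm/bp) is used; a per-molecule
#' calibration (total contour length / n_bp) can be supplied instead.
#'
#' @param trace A [trace2d()].
#' @param loop_annotation A row (list) with `start_index` and `end_index`
#'   delimiting the loop circuit; the endpoints must coincide within
#'   `closure_tol`.
#' @param nm_per_bp Calibration, nm/bp (default 0.34).
#' @param closure_tol Closure tolerance, nm (default 5).
#' @return Loop size, bp.
#' @export
loop_size_bp <- function(trace, loop_annotation, nm_per_bp = 0.34, closure_tol = 5) {
  stopifnot(inherits(trace, "trace2d"))
  a <- loop_annotation$start_index; b <- loop_annotation$end_index
  pts <- trace$points[a:b, , drop = FALSE]
  gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  if (gap > closure_tol)
    stop(sprintf("loop is not a closed circuit: endpoint gap %.3g nm", gap), call. = FALSE)
  len <- sum(sqrt(rowSums(diff(pts)^2))) + gap
  len / nm_per_bp
}

#' Bridge statistics over a set of traced molecules
#'
#' Bridges (two DNA strands connected by one or more proteins) are annotated by
#' the tracer, not detected. Reports the fraction of molecules with at least
#' one bridge annotation and the mean bridge count per molecule.
#'
#' @param traces List of [trace2d()] objects.
#' @return A list with `fraction_with_bridges`, `mean_bridges_per_molecule`,
#'   `n_molecules`, `n_bridges`.
#' @export
bridge_summary <- function(traces) {
  if (length(traces) == 0) stop("empty trace list", call. = FALSE)
  counts <- vapply(traces, function(tr) {
    if (is.null(tr$annotations)) 0L else sum(tr$annotations$kind == "bridge")
  }, integer(1))
  list(fraction_with_bridges = mean(counts >= 1),
       mean_bridges_per_molecule = mean(counts),
       n_molecules = length(traces), n_bridges = sum(counts))
}
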
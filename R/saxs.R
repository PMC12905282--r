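#' Construct a 1-D scattering curve
#'
#' @param q momentum transfer in 1/Angstrom, strictly increasing, > 0.
#' @param I scattered intensity (arbitrary units).
#' @param sigma per-point uncertainty, same units as I (required wherever
#'   a chi-square is computed).
#' @param comments optional character vector of header comments.
#' @return object of class \code{scattering_curve}.
#' @export
scattering_curve <- function(q, I, sigma = NULL, comments = character(0)) {
  q <- as.numeric(q); I <- as.numeric(I)
  stopifnot(length(q) == length(I), all(is.finite(q)), all(q > 0),
            !is.unsorted(q, strictly = TRUE))
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  stopifnot(length(sigma) == length(q))
  structure(list(q = q, I = I, sigma = as.numeric(sigma),
                 comments = comments),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("Scattering curve: %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.scattering_curve <- function(x, log = "y", ...) {
  graphics::plot(x$q, x$I, type = "l", log = log,
                 xlab = "q (1/A)", ylab = "I(q)", ...)
  invisible(x)
}

#' Buffer subtraction with error propagation
#'
#' I = I_sample - I_buffer on a common q grid, uncertainties combined in
#' quadrature. With \code{interpolate = TRUE} the buffer is linearly
#' interpolated onto the sample grid.
#'
#' @param sample,buffer \code{\link{scattering_curve}} objects.
#' @param interpolate interpolate the buffer onto the sample grid.
#' @return a \code{\link{scattering_curve}}.
#' @export
buffer_subtract <- function(sample, buffer, interpolate = FALSE) {
  if (!isTRUE(all.equal(sample$q, buffer$q))) {
    if (!interpolate)
      stop("buffer_subtract: q grids differ (set interpolate = TRUE)")
    Ib <- stats::approx(buffer$q, buffer$I, xout = sample$q, rule = 2)$y
    sb <- stats::approx(buffer$q, buffer$sigma, xout = sample$q, rule = 2)$y
  } else {
    Ib <- buffer$I; sb <- buffer$sigma
  }
  scattering_curve(sample$q, sample$I - Ib,
                   sqrt(sample$sigma^2 + sb^2),
                   comments = sample$comments)
}

#' Guinier fit of the low-q region
#'
#' Fit of ln I versus q^2 on the largest low-q window satisfying
#' q * Rg <= \code{qmax_rg_limit}, iterated to self-consistency (the window
#' is recomputed from the fitted Rg until it stops changing). Returns
#' Rg = sqrt(-3 * slope) and I0 = exp(intercept).
#'
#' By default a q^4 term is included in the fit and discarded
#' (\code{method = "corrected"}): the Guinier law is only the leading term
#' of ln I, and over a finite window the next (q^4) term biases the fitted
#' slope — by about +2\% for a solid sphere and by several percent (low)
#' for extended chains at the conventional q Rg <= 1.3 window. Absorbing it
#' in a nuisance coefficient removes that truncation bias while leaving the
#' estimate identical on data that follow the pure Guinier law.
#' \code{method = "linear"} gives the plain two-parameter fit.
#'
#' @param curve a \code{\link{scattering_curve}}.
#' @param qmax_rg_limit upper limit on q * Rg in the fit window
#'   (default 1.3, the conventional globular-particle cut-off).
#' @param min_points minimum number of points in the window.
#' @param method \code{"corrected"} (default) or \code{"linear"}.
#' @return object of class \code{guinier_fit}: \code{Rg}, \code{I0},
#'   \code{q_min}, \code{q_max}, \code{qmax_rg}, \code{n_points},
#'   \code{r_squared} of the fit and the window index range.
#' @export
guinier_fit <- function(curve, qmax_rg_limit = 1.3, min_points = 5L,
                        method = c("corrected", "linear")) {
  method <- match.arg(method)
  keep <- which(curve$I > 0)
  if (length(keep) < min_points) stop("guinier_fit: too few positive points")
  i0 <- keep[1]
  q <- curve$q; I <- curve$I
  n <- length(q)
  ## ln-space weights by error propagation: var(ln I) = (sigma/I)^2
  w_all <- rep(1, n)
  if (all(is.finite(curve$sigma)) && all(curve$sigma > 0))
    w_all <- (I / curve$sigma)^2
  fit_window <- function(j1) {
    idx <- i0:j1
    x <- q[idx]^2; y <- log(I[idx]); w <- w_all[idx]
    X <- if (method == "corrected" && length(idx) >= min_points + 1L)
      cbind(1, x, x^2) else cbind(1, x)
    f <- stats::lm.wfit(X, y, w)
    co <- c(intercept = f$coefficients[[1]], slope = f$coefficients[[2]])
    ## noisy windows can push the three-term fit to a non-negative slope
    ## even when the plain Guinier slope is fine; fall back before failing
    if (ncol(X) == 3L && (!is.finite(co[2]) || co[2] >= 0)) {
      f <- stats::lm.wfit(cbind(1, x), y, w)
      co <- c(intercept = f$coefficients[[1]], slope = f$coefficients[[2]])
    }
    co
  }
  ## start from a small leading window, then iterate window <- f(Rg)
  j <- min(n, i0 + max(min_points, 15L) - 1L)
  last_j <- -1L; co <- NULL; guard <- 0L
  while (j != last_j && guard < 50L) {
    guard <- guard + 1L
    last_j <- j
    co <- fit_window(j)
    if (!is.finite(co["slope"]) || co["slope"] >= 0)
      stop("guinier_fit: non-negative low-q slope; Guinier analysis failed")
    Rg <- sqrt(-3 * co["slope"])
    j_new <- max(which(q * Rg <= qmax_rg_limit), i0)
    if (j_new - i0 + 1L < min_points)
      stop("guinier_fit: fewer than ", min_points,
           " points satisfy q*Rg <= ", qmax_rg_limit)
    j <- j_new
  }
  Rg <- sqrt(-3 * co[["slope"]])
  idx <- i0:j
  x <- q[idx]^2; y <- log(I[idx])
  X <- if (method == "corrected" && length(idx) >= min_points + 1L)
    cbind(1, x, x^2) else cbind(1, x)
  resid <- stats::lm.wfit(X, y, w_all[idx])$residuals
  ss_tot <- max(sum((y - mean(y))^2), .Machine$double.eps)
  r2 <- 1 - sum(resid^2) / ss_tot
  structure(list(Rg = Rg, I0 = exp(co[[1]]),
                 q_min = q[i0], q_max = q[j], qmax_rg = q[j] * Rg,
                 n_points = length(idx), r_squared = r2,
                 window = c(i0, j), limit = qmax_rg_limit, method = method),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f A, I0 = %.4g (%d points, qmax*Rg = %.3f, R2 = %.5f)\n",
              x$Rg, x$I0, x$n_points, x$qmax_rg, x$r_squared))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Returns (q Rg, (q Rg)^2 I(q)/I0), the shape diagnostic in which an ideal
#' compact globule peaks at (sqrt(3), 3/e) while flexible or extended chains
#' plateau above that height at large q Rg.
#'
#' @param curve a \code{\link{scattering_curve}}.
#' @param g its \code{\link{guinier_fit}} (supplies Rg and I0).
#' @return a data frame with columns \code{qRg} and \code{kratky}; the
#'   globular reference point is stored in attribute \code{reference}
#'   (c(sqrt(3), 3/exp(1))).
#' @export
dimensionless_kratky <- function(curve, g) {
  stopifnot(inherits(g, "guinier_fit"))
  out <- data.frame(qRg = curve$q * g$Rg,
                    kratky = (curve$q * g$Rg)^2 * curve$I / g$I0)
  attr(out, "reference") <- c(qRg = sqrt(3), kratky = 3 / exp(1))
  out
}

#' Correlation-volume molecular weight
#'
#' Vc = I0 / integral(q I(q) dq) from 0 to \code{integration_qmax}, with the
#' unmeasured segment below the first data point filled by the Guinier
#' extrapolation (analytic integral of q I0 exp(-q^2 Rg^2 / 3)). The
#' molecular weight follows the published correlation-volume power-law
#' calibration, with separate constant sets for protein and for
#' protein/nucleic-acid complexes (neither is claimed correct for
#' nucleoproteins; pick explicitly).
#'
#' @param curve a \code{\link{scattering_curve}}.
#' @param g its \code{\link{guinier_fit}}.
#' @param integration_qmax upper integration limit in 1/A; default
#'   min(0.3, 8/Rg).
#' @param calibration \code{"protein"} (coef 0.1231, exponent 1) or
#'   \code{"nucleic"} (coef 0.00934, exponent 0.808); mass in Da from
#'   Qr = Vc^2 / Rg via mass = (Qr / coef)^exponent.
#' @return list with \code{Vc} (A^2), \code{mw_kda}, \code{qmax} used and
#'   the calibration constants.
#' @export
correlation_volume_mw <- function(curve, g,
                                  integration_qmax = NULL,
                                  calibration = c("protein", "nucleic")) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(g, "guinier_fit"))
  if (is.null(integration_qmax)) integration_qmax <- min(0.3, 8 / g$Rg)
  if (max(curve$q) < integration_qmax * 0.999)
    stop("correlation_volume_mw: curve does not extend to the integration limit")
  sel <- curve$q <= integration_qmax
  q <- curve$q[sel]; I <- curve$I[sel]
  ## analytic Guinier fill-in over [0, q1]
  q1 <- q[1]
  fill <- g$I0 * 3 / (2 * g$Rg^2) * (1 - exp(-q1^2 * g$Rg^2 / 3))
  integral <- fill + sum(diff(q) * (q[-1] * I[-1] + q[-length(q)] * I[-length(I)]) / 2)
  if (integral <= 0) stop("correlation_volume_mw: non-positive q*I integral")
  Vc <- g$I0 / integral
  const <- switch(calibration,
                  protein = c(coef = 0.1231, exponent = 1.0),
                  nucleic = c(coef = 0.00934, exponent = 0.808))
  Qr <- Vc^2 / g$Rg
  mw_da <- (Qr / const[["coef"]])^const[["exponent"]]
  list(Vc = Vc, mw_kda = mw_da / 1e3, qmax = integration_qmax,
       calibration = calibration, constants = const)
}

#' Analytic least-squares scale between two curves
#'
#' The scale factor c minimising sum((Iexp - c Itheor)^2 / sigma^2):
#' c = sum(Iexp Itheor / sigma^2) / sum(Itheor^2 / sigma^2).
#'
#' @param exp,theor \code{\link{scattering_curve}} objects on the same q grid
#'   (sigma taken from \code{exp}).
#' @return the scale factor (dimensionless).
#' @export
optimal_scale <- function(exp, theor) {
  check_common_grid(exp, theor)
  s2 <- exp$sigma^2
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("optimal_scale: experimental sigma must be finite and positive")
  denom <- sum(theor$I^2 / s2)
  if (denom <= 0) stop("optimal_scale: theoretical curve is degenerate (all zero)")
  sum(exp$I * theor$I / s2) / denom
}

#' Reduced chi-square between experimental and model curves
#'
#' chi^2 = 1/(N-1) sum_j [(Iexp(qj) - c Itheor(qj)) / sigma(qj)]^2 with the
#' analytic scale factor c of \code{\link{optimal_scale}} (or a forced c).
#'
#' @param exp,theor \code{\link{scattering_curve}} objects on a common grid.
#' @param c_scale optional fixed scale factor; default: analytic optimum.
#' @return object of class \code{curve_comparison}: \code{chi2},
#'   \code{scale_c}, \code{n}.
#' @export
chi_square <- function(exp, theor, c_scale = NULL) {
  check_common_grid(exp, theor)
  n <- length(exp$q)
  if (n < 2L) stop("chi_square: need at least 2 points")
  if (is.null(c_scale)) c_scale <- optimal_scale(exp, theor)
  chi2 <- sum(((exp$I - c_scale * theor$I) / exp$sigma)^2) / (n - 1)
  structure(list(chi2 = chi2, scale_c = c_scale, n = n),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Curve comparison: chi2 = %.4g (c = %.4g, N = %d)\n",
              x$chi2, x$scale_c, x$n))
  invisible(x)
}

check_common_grid <- function(a, b) {
  if (length(a$q) != length(b$q) || !isTRUE(all.equal(a$q, b$q)))
    stop("curves are not on a common q grid")
  invisible(TRUE)
}

#' A SEC-SAXS frame series
#'
#' @param frames list of \code{\link{scattering_curve}} objects in elution
#'   order, all on the same q grid.
#' @return object of class \code{sec_saxs_series}.
#' @export
sec_saxs_series <- function(frames) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "scattering_curve")))
  for (f in frames[-1]) check_common_grid(frames[[1]], f)
  structure(list(frames = frames), class = "sec_saxs_series")
}

#' Select and average SEC-SAXS frames with stable Rg
#'
#' Computes a Guinier Rg for each frame, finds the longest contiguous run of
#' frames whose Rg values deviate less than \code{rg_tolerance} (relative)
#' from the run median, and returns the uncertainty-weighted average curve
#' over that run. Averaging frames with similar and stable Rg improves the
#' signal-to-noise ratio without mixing species.
#'
#' @param series a \code{\link{sec_saxs_series}}.
#' @param rg_tolerance maximum relative deviation of Rg from the run median
#'   (default 0.05).
#' @param min_run minimum acceptable run length (default 3; a single-frame
#'   series returns that frame).
#' @param guinier_method per-frame Guinier estimator; the plain linear fit
#'   is the default here because frame selection only compares Rg between
#'   frames — its small shared bias cancels, while the lower-variance
#'   estimate keeps noisy single frames from breaking a genuine plateau.
#' @return list with \code{curve} (the averaged \code{scattering_curve}),
#'   \code{mask} (logical per frame), \code{rg} (per-frame Rg, NA on Guinier
#'   failure).
#' @export
select_stable_frames <- function(series, rg_tolerance = 0.05, min_run = 3L,
                                 guinier_method = "linear") {
  stopifnot(inherits(series, "sec_saxs_series"))
  frames <- series$frames
  nf <- length(frames)
  rg <- vapply(frames, function(f) {
    g <- try(guinier_fit(f, method = guinier_method), silent = TRUE)
    if (inherits(g, "try-error")) NA_real_ else g$Rg
  }, numeric(1))
  if (all(is.na(rg))) stop("select_stable_frames: no frame admits a Guinier fit")
  if (nf == 1L) return(list(curve = frames[[1]],
                            mask = TRUE, rg = rg))
  ok_run <- function(i, j) {
    v <- rg[i:j]
    if (anyNA(v)) return(FALSE)
    m <- stats::median(v)
    all(abs(v - m) < rg_tolerance * m)
  }
  best <- c(0L, -1L)                      # start, length
  for (i in seq_len(nf)) {
    if (is.na(rg[i])) next
    for (j in i:nf) {
      if (is.na(rg[j]) || !ok_run(i, j)) break
      if (j - i + 1L > best[2]) best <- c(i, j - i + 1L)
    }
  }
  if (best[2] < min(min_run, nf))
    stop("select_stable_frames: no stable run of length >= ", min_run)
  mask <- rep(FALSE, nf)
  mask[best[1]:(best[1] + best[2] - 1L)] <- TRUE
  sel <- frames[mask]
  w <- vapply(sel, function(f) 1 / f$sigma^2, numeric(length(sel[[1]]$q)))
  I <- vapply(sel, function(f) f$I, numeric(length(sel[[1]]$q)))
  wsum <- rowSums(w)
  avg <- scattering_curve(sel[[1]]$q, rowSums(I * w) / wsum,
                          sqrt(1 / wsum))
  list(curve = avg, mask = mask, rg = rg)
}
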
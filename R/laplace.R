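# Laplace quadrature for inverse orbital-energy denominators.
#
# 1/D = int_0^inf exp(-t D) dt is discretized, after the substitution
# t = exp(s), by the trapezoidal rule on an s-grid: the integrand
# exp(-D e^s + s) decays double-exponentially on the right and exponentially
# on the left, so the trapezoidal sum converges geometrically and yields
# strictly positive points and weights.  The number of points is increased
# adaptively until the maximum relative error over the requested denominator
# range [delta_min, delta_max] (checked on a dense logarithmic scan) is below
# the tolerance.  A shift (the CCSD excitation energy for excited-state
# amplitude denominators) is subtracted from the range before fitting:
# 1/(D - shift) = sum_k w_k exp(shift t_k) exp(-t_k D).

#' Build a Laplace quadrature for 1/(D - shift)
#'
#' @param delta_min,delta_max denominator range in hartree (before shifting).
#' @param shift real shift (0 for ground state, omega-CCSD for excited).
#' @param tol target maximum relative error (default 1e-6).
#' @param n_points optional fixed number of points (otherwise adaptive).
#' @param max_points adaptive cap.
#' @return object of class \code{laplace_quadrature} with fields \code{t}
#'   (points), \code{w} (weights for the shifted denominator), \code{range},
#'   \code{shift}, \code{rel_error}.
#' @export
build_laplace_quadrature <- function(delta_min, delta_max, shift = 0,
                                     tol = 1e-6, n_points = NULL,
                                     max_points = 80L) {
  if (delta_max < delta_min) stop("delta_max < delta_min")
  lo <- delta_min - shift
  hi <- delta_max - shift
  if (lo <= 0)
    stop("near-singular denominator: shifted range [", format(lo), ", ",
         format(hi), "] crosses or touches zero (intruder-state-like)")
  if (abs(hi / lo - 1) < 1e-12) {
    # degenerate range: a single point reproduces 1/D exactly
    q <- structure(list(t = 0, w = 1 / lo, range = c(delta_min, delta_max),
                        shift = shift, rel_error = 0, n_points = 1L),
                   class = "laplace_quadrature")
    return(q)
  }
  scan <- exp(seq(log(lo), log(hi), length.out = 1000L))
  build_n <- function(n) {
    # s-range: left end where integrand ~ exp(s)/ (small t) is negligible
    # relative to 1/hi; right end where exp(-lo e^s) is negligible.
    s_min <- log(tol * 0.05 / hi)
    s_max <- log(-log(tol * 0.05) / lo * 1.5)
    s <- seq(s_min, s_max, length.out = n)
    h <- s[2] - s[1]
    t <- exp(s)
    w <- h * t
    approx <- outer(scan, t, function(D, tt) exp(-D * tt)) %*% w
    err <- max(abs(approx * scan - 1))
    list(t = t, w = w, err = err)
  }
  if (!is.null(n_points)) {
    q <- build_n(as.integer(n_points))
  } else {
    n <- 8L
    repeat {
      q <- build_n(n)
      if (q$err <= tol || n >= max_points) break
      n <- ceiling(n * 1.5)
    }
  }
  if (q$err > tol)
    stop("Laplace quadrature cannot reach tolerance ", format(tol),
         " on range [", format(lo), ", ", format(hi), "]; achieved ",
         format(q$err))
  structure(list(t = q$t, w = q$w * exp(q$t * shift),
                 range = c(delta_min, delta_max), shift = shift,
                 rel_error = q$err, n_points = length(q$t)),
            class = "laplace_quadrature")
}

#' @export
print.laplace_quadrature <- function(x, ...) {
  cat("laplace_quadrature:", x$n_points, "points, range [",
      format(x$range[1]), ",", format(x$range[2]), "] shift",
      format(x$shift), " max rel err", format(x$rel_error), "\n")
  invisible(x)
}

#' Evaluate the quadrature approximation of 1/(D - shift)
#' @param quad \code{laplace_quadrature}; @param D denominator values.
#' @export
laplace_eval <- function(quad, D) {
  if (quad$n_points == 1L && quad$t[1] == 0)
    return(rep(quad$w[1], length(D)))
  as.numeric(outer(D, quad$t, function(d, tt) exp(-d * tt)) %*% quad$w)
}

#' Verify a quadrature on the true denominator extremes of a run
#'
#' Asserts the configured tolerance on a dense scan of the actual range in
#' use; called at runtime by the providers.
#' @param quad quadrature; @param dmin,dmax true range; @param tol tolerance.
#' @keywords internal
laplace_assert <- function(quad, dmin, dmax, tol = 1e-6) {
  if (dmin < quad$range[1] - 1e-12 || dmax > quad$range[2] + 1e-12)
    stop("denominator range [", format(dmin), ", ", format(dmax),
         "] outside the quadrature's validated range")
  scan <- seq(dmin, dmax, length.out = 200L)
  err <- max(abs(laplace_eval(quad, scan) * (scan - quad$shift) - 1))
  if (err > tol)
    stop("Laplace quadrature error ", format(err),
         " exceeds tolerance on the run's denominator range")
  invisible(TRUE)
}
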
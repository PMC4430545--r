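#' Free-energy profile container
#'
#' A potential of mean force \eqn{F(\lambda)} on a strictly increasing
#' reaction-coordinate grid, referenced so that \eqn{F = 0} at
#' \code{reference_lambda}.
#'
#' @param lambda strictly increasing grid [A]
#' @param F free energies [kcal/mol], same length as \code{lambda}
#' @param reference_lambda grid value at which F is zeroed (default: first
#'   grid point)
#' @param n_traj optional number of trajectories behind the estimate
#' @return object of class \code{"pmf_curve"}
#' @export
pmf_curve <- function(lambda, F, reference_lambda = lambda[1L],
                      n_traj = NA_integer_) {
  lambda <- as.numeric(lambda)
  F <- as.numeric(F)
  if (length(lambda) != length(F)) stop("lambda and F lengths differ")
  if (length(lambda) > 1L && any(diff(lambda) <= 0)) {
    stop("lambda grid must be strictly increasing")
  }
  iref <- which.min(abs(lambda - reference_lambda))
  if (abs(lambda[iref] - reference_lambda) > 1e-9) {
    stop("reference_lambda is not a grid point")
  }
  structure(list(lambda = lambda, F = F - F[iref],
                 reference_lambda = lambda[iref],
                 n_traj = as.integer(n_traj)),
            class = "pmf_curve")
}

#' @export
print.pmf_curve <- function(x, ...) {
  cat(sprintf("<pmf_curve> %d points, lambda [%g, %g] A, dF = %.4f kcal/mol\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              x$F[length(x$F)] - x$F[1L]))
  invisible(x)
}

#' Exact constrained free energy by quadrature (oracle)
#'
#' Computes the reference PMF of a one-dimensional potential under the
#' harmonic steering guide,
#' \deqn{F(\lambda) = -k_B T \ln \int e^{-[U(x) + k(x-\lambda)^2/2]/k_B T}\,dx,}
#' by composite trapezoidal quadrature on a fixed grid, re-referenced to
#' \code{reference_lambda}.  This is the independent oracle against which
#' the nonequilibrium estimators are checked; it is exact up to quadrature
#' error, which is verified internally by grid refinement.
#'
#' The integration range is \code{[x_lo - 10 sigma, x_hi + 10 sigma]} where
#' \code{x_lo}/\code{x_hi} bound the guide positions and the potential
#' minima, and \code{sigma} is the thermal width of the stiffest quadratic
#' term; this captures all non-negligible Boltzmann weight.
#'
#' @param potential a 1D [make_potential()] model (free, harmonic or
#'   double-well family)
#' @param k guide spring constant [kcal/mol/A^2]
#' @param lambda_grid guide positions at which to evaluate F
#' @param temperature temperature [K]
#' @param n_quad number of quadrature points (default 8193)
#' @param check_convergence if TRUE (default), recompute at twice the
#'   resolution and fail if any grid point moves by more than \code{tol}
#' @param tol convergence tolerance [kcal/mol]
#' @param reference_lambda grid point where F = 0
#' @return a [pmf_curve()]
#' @export
reference_pmf <- function(potential, k, lambda_grid, temperature,
                          n_quad = 8193L, check_convergence = TRUE,
                          tol = 1e-6, reference_lambda = lambda_grid[1L]) {
  stopifnot(inherits(potential, "potential_model"))
  if (potential$dimension != 1L) {
    stop("reference_pmf requires a one-dimensional potential")
  }
  if (k <= 0) stop("guide spring constant k must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  lambda_grid <- as.numeric(lambda_grid)

  Fq <- .quadrature_F(potential, k, lambda_grid, temperature, n_quad)
  if (check_convergence) {
    F2 <- .quadrature_F(potential, k, lambda_grid, temperature,
                        2L * (n_quad - 1L) + 1L)
    dF <- (Fq - Fq[1L]) - (F2 - F2[1L])
    if (max(abs(dF)) > tol) {
      stop(sprintf(paste0("quadrature not converged: max |dF| = %.3g ",
                          "kcal/mol at n_quad = %d vs %d; increase n_quad"),
                   max(abs(dF)), n_quad, 2L * (n_quad - 1L) + 1L))
    }
  }
  pmf_curve(lambda_grid, Fq, reference_lambda = reference_lambda)
}

.quadrature_F <- function(potential, k, lambda_grid, temperature, n_quad) {
  kT <- kB * temperature
  # stiffest quadratic term sets the thermal width sigma
  p <- potential$spec$params
  stiff <- k
  if (potential$kind == "harmonic") stiff <- max(stiff, p$a)
  if (potential$kind %in% c("double_well", "tilted_double_well")) {
    stiff <- max(stiff, 8 * p$h / p$w^2)
  }
  sigma <- sqrt(kT / stiff)
  centres <- lambda_grid
  if (potential$kind %in% c("double_well", "tilted_double_well")) {
    centres <- c(centres, -p$w, p$w)
  }
  if (potential$kind == "harmonic") centres <- c(centres, 0)
  lo <- min(centres) - 10 * sigma
  hi <- max(centres) + 10 * sigma
  xg <- seq(lo, hi, length.out = n_quad)
  U <- vapply(xg, function(x) cpp_pot_energy(potential$kind_code,
                                             potential$params_vec, x),
              numeric(1))
  h <- xg[2L] - xg[1L]
  wts <- rep(h, n_quad)
  wts[c(1L, n_quad)] <- h / 2
  vapply(lambda_grid, function(l) {
    lp <- -(U + 0.5 * k * (xg - l)^2) / kT + log(wts)
    m <- max(lp)
    -kT * (m + log(sum(exp(lp - m))))
  }, numeric(1))
}
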
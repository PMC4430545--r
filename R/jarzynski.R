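#' Nonequilibrium work ensemble
#'
#' Per-trajectory external work sampled on a common reaction-coordinate
#' grid.  Row \code{i} of \code{W} is trajectory \code{i}; column \code{g}
#' is grid point \code{g}.  Work is zero at the first grid point for every
#' trajectory.
#'
#' @param lambda monotone increasing grid [A]
#' @param W numeric matrix of accumulated work [kcal/mol], one row per
#'   trajectory
#' @param temperature temperature [K]
#' @return object of class \code{"work_ensemble"}
#' @export
work_ensemble <- function(lambda, W, temperature) {
  lambda <- as.numeric(lambda)
  W <- as.matrix(W)
  if (ncol(W) != length(lambda)) stop("W must have one column per grid point")
  if (nrow(W) < 1L) stop("work ensemble is empty")
  if (any(!is.finite(W))) stop("non-finite work values")
  if (length(lambda) > 1L && any(diff(lambda) <= 0)) {
    stop("lambda grid must be strictly increasing")
  }
  if (any(W[, 1L] != 0)) stop("work must be exactly 0 at the first grid point")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(lambda = lambda, W = unname(W), temperature = temperature),
            class = "work_ensemble")
}

#' @export
print.work_ensemble <- function(x, ...) {
  cat(sprintf("<work_ensemble> %d trajectories x %d grid points, T = %g K\n",
              nrow(x$W), ncol(x$W), x$temperature))
  invisible(x)
}

#' Jarzynski free-energy estimate from work samples
#'
#' Computes \eqn{F = -k_B T \ln \frac{1}{N}\sum_i e^{-W_i / k_B T}} columnwise
#' via a log-sum-exp formulation that is stable for works far exceeding
#' \eqn{k_B T}.
#'
#' @param W numeric vector (one grid point) or matrix (trajectories x grid)
#'   of work values [kcal/mol]
#' @param temperature temperature [K]
#' @return numeric vector of free energies, one per grid point
#' @export
je_estimate <- function(W, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  W <- if (is.matrix(W)) W else matrix(W, ncol = 1L)
  if (any(!is.finite(W))) stop("non-finite work values")
  kT <- kB * temperature
  apply(W, 2L, function(w) -kT * logmeanexp(-w / kT))
}

#' Pointwise Jarzynski PMF of a work ensemble
#'
#' @param ensemble a [work_ensemble()]
#' @return a [pmf_curve()] on the ensemble grid; \eqn{F = 0} at the first
#'   grid point (guaranteed because all works start at zero)
#' @export
jarzynski_pmf <- function(ensemble) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  F <- je_estimate(ensemble$W, ensemble$temperature)
  pmf_curve(ensemble$lambda, F, reference_lambda = ensemble$lambda[1L],
            n_traj = nrow(ensemble$W))
}

#' JE-criterion trajectory selection
#'
#' Returns the index of the trajectory whose final work most closely matches
#' the stage's final Jarzynski free energy; this trajectory's coordinates
#' and velocities seed the next pulling stage in naive adaptive steering.
#' Ties are broken by the lowest index.
#'
#' @param end_works final work per trajectory [kcal/mol]
#' @param F_end stage free energy at the stage end [kcal/mol]
#' @return integer index into \code{end_works}
#' @export
je_select <- function(end_works, F_end) {
  if (length(end_works) < 1L) stop("empty work list")
  if (any(!is.finite(end_works)) || !is.finite(F_end)) {
    stop("non-finite inputs to je_select")
  }
  which.min(abs(end_works - F_end))
}

#' Jackknife standard error of the Jarzynski estimate
#'
#' Leave-one-out jackknife over trajectories; a convenience for
#' "within n standard errors" checks, not an estimator claim.
#'
#' @inheritParams je_select
#' @param temperature temperature [K]
#' @return standard error [kcal/mol]
#' @export
je_jackknife_se <- function(end_works, temperature) {
  n <- length(end_works)
  if (n < 2L) return(NA_real_)
  loo <- vapply(seq_len(n),
                function(i) je_estimate(end_works[-i], temperature),
                numeric(1))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}
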
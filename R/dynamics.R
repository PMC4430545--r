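#' Langevin thermostat and integration parameters
#'
#' @param temperature bath temperature [K]; 0 gives deterministic dynamics
#' @param friction Langevin damping coefficient gamma [1/ps] (default 5, the
#'   conventional peptide-simulation value)
#' @param timestep integration step [ps] (default 0.002, i.e. 2 fs)
#' @param masses mass per degree of freedom [amu]; scalar recycled
#' @return object of class \code{"langevin_params"}
#' @export
langevin_params <- function(temperature = 300, friction = 5,
                            timestep = 0.002, masses = 1) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction < 0) stop("friction must be >= 0")
  if (timestep <= 0) stop("timestep must be > 0")
  if (any(masses <= 0)) stop("masses must be > 0")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, masses = as.numeric(masses)),
            class = "langevin_params")
}

#' Steering protocol for a moving harmonic guide
#'
#' The guide potential is \eqn{k (\xi(x) - \lambda(t))^2 / 2} with
#' \eqn{\lambda(t) = \lambda_{start} + v t} in pull mode, or \eqn{\lambda}
#' fixed in hold mode.  The reaction coordinate \eqn{\xi} is the potential's
#' default (identity for 1D systems, first-to-last bead distance for the
#' bead chain) unless overridden.
#'
#' @param k spring constant [kcal/mol/A^2]; default 7.2, the conventional
#'   stiff-spring pulling constant
#' @param lambda_start,lambda_end guide endpoints [A]
#' @param velocity pulling velocity [A/ns] (converted to A/ps internally)
#' @param mode \code{"pull"} or \code{"hold"}
#' @param reaction_coord optional list \code{list(type, ai, aj)} overriding
#'   the potential's default coordinate (type 0 = identity, 1 = bead pair
#'   distance with 0-based indices \code{ai}, \code{aj})
#' @return object of class \code{"steering_protocol"}
#' @export
steering_protocol <- function(k = 7.2, lambda_start, lambda_end,
                              velocity, mode = c("pull", "hold"),
                              reaction_coord = NULL) {
  mode <- match.arg(mode)
  if (k <= 0) stop("spring constant k must be > 0")
  if (mode == "pull") {
    if (missing(velocity) || velocity <= 0) {
      stop("pull mode requires velocity > 0 [A/ns]")
    }
    if (lambda_end <= lambda_start) {
      stop("lambda must increase from lambda_start to lambda_end")
    }
  } else {
    if (missing(velocity)) velocity <- 0
    if (missing(lambda_end)) lambda_end <- lambda_start
  }
  structure(list(k = k, lambda_start = lambda_start, lambda_end = lambda_end,
                 velocity = velocity, mode = mode,
                 reaction_coord = reaction_coord),
            class = "steering_protocol")
}

.rc_of <- function(potential, steering = NULL) {
  if (!is.null(steering) && !is.null(steering$reaction_coord)) {
    steering$reaction_coord
  } else {
    potential$rc
  }
}

#' System state
#'
#' @param positions coordinate vector [A]
#' @param velocities velocity vector [A/ps]; defaults to rest
#' @param time elapsed time [ps]
#' @return object of class \code{"system_state"}
#' @export
system_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.numeric(positions)
  if (is.null(velocities)) velocities <- numeric(length(positions))
  velocities <- as.numeric(velocities)
  if (length(velocities) != length(positions)) {
    stop("positions and velocities lengths differ")
  }
  structure(list(positions = positions, velocities = velocities,
                 time = time),
            class = "system_state")
}

.expand_masses <- function(params, dim) {
  m <- params$masses
  if (length(m) == 1L) m <- rep(m, dim)
  if (length(m) != dim) stop("masses length does not match dimension")
  m
}

#' One Langevin (BAOAB) integration step
#'
#' Advances the state by one timestep under \eqn{U(x)} plus, when a guide is
#' supplied, the harmonic steering potential at \eqn{\lambda(t)} evaluated
#' from the state's clock.  Deterministic given the R random number
#' generator state.
#'
#' @param state a [system_state()]
#' @param potential a [make_potential()] model
#' @param guide optional [steering_protocol()]
#' @param params a [langevin_params()]
#' @return the updated [system_state()]
#' @export
langevin_step <- function(state, potential, guide = NULL, params) {
  dim <- potential$dimension
  stopifnot(length(state$positions) == dim)
  m <- .expand_masses(params, dim)
  guide_on <- !is.null(guide)
  lambda <- 0
  rc <- .rc_of(potential, guide)
  if (guide_on) {
    lambda <- if (guide$mode == "pull") {
      min(guide$lambda_start + guide$velocity / 1000 * state$time,
          guide$lambda_end)
    } else {
      guide$lambda_start
    }
  }
  res <- cpp_hold_segment(potential$kind_code, potential$params_vec,
                          state$positions, state$velocities, m,
                          kB * params$temperature, params$friction,
                          params$timestep, 1, guide_on,
                          if (guide_on) guide$k else 0, lambda,
                          rc$type, rc$ai, rc$aj, integer(0), 0L)
  system_state(res$x, res$v, state$time + params$timestep)
}

#' Steered pulling segment with work accounting
#'
#' Integrates while the guide moves from \code{lambda_start} to
#' \code{lambda_end} at the protocol velocity, accumulating the external
#' work \eqn{dW = k(\lambda - \xi)\, v\, dt} by the trapezoidal rule.  Work
#' and the instantaneous reaction coordinate are reported on
#' \code{record_grid} (default: every \code{record_spacing} A of lambda,
#' endpoints included).  In hold mode the guide does not move and the work
#' is exactly zero.
#'
#' @inheritParams langevin_step
#' @param steering a [steering_protocol()]
#' @param record_grid lambda values at which to sample the work; must lie in
#'   \code{[lambda_start, lambda_end]} and include both endpoints
#' @param record_spacing grid spacing used when \code{record_grid} is NULL
#'   [A] (default 0.1)
#' @param duration hold-mode integration time [ps]
#' @return list with elements \code{trace} (data.frame: time, lambda, xi,
#'   work), \code{state} (final [system_state()]), and \code{work_end}
#' @export
steered_segment <- function(state, potential, steering, params,
                            record_grid = NULL, record_spacing = 0.1,
                            duration = NULL) {
  dim <- potential$dimension
  stopifnot(length(state$positions) == dim)
  m <- .expand_masses(params, dim)
  rc <- .rc_of(potential, steering)

  if (steering$mode == "hold") {
    if (is.null(duration)) stop("hold mode requires a duration [ps]")
    nsteps <- ceiling(duration / params$timestep)
    res <- cpp_hold_segment(potential$kind_code, potential$params_vec,
                            state$positions, state$velocities, m,
                            kB * params$temperature, params$friction,
                            params$timestep, nsteps, TRUE, steering$k,
                            steering$lambda_start, rc$type, rc$ai, rc$aj,
                            integer(0), 0L)
    trace <- data.frame(time = c(state$time, state$time + res$t_elapsed),
                        lambda = steering$lambda_start,
                        xi = c(reaction_coordinate(potential,
                                                   state$positions), res$xi),
                        work = c(0, 0))
    return(list(trace = trace,
                state = system_state(res$x, res$v,
                                     state$time + res$t_elapsed),
                work_end = 0))
  }

  l0 <- steering$lambda_start
  l1 <- steering$lambda_end
  if (is.null(record_grid)) {
    record_grid <- lambda_record_grid(l0, l1, record_spacing)
  }
  record_grid <- as.numeric(record_grid)
  if (abs(record_grid[1L] - l0) > 1e-9 ||
      abs(record_grid[length(record_grid)] - l1) > 1e-9) {
    stop("record_grid must include both lambda endpoints")
  }
  vps <- steering$velocity / 1000  # A/ns -> A/ps
  res <- cpp_pull_segment(potential$kind_code, potential$params_vec,
                          state$positions, state$velocities, m,
                          kB * params$temperature, params$friction,
                          params$timestep, steering$k, l0, l1, vps,
                          record_grid, rc$type, rc$ai, rc$aj)
  trace <- data.frame(time = state$time + (record_grid - l0) / vps,
                      lambda = record_grid, xi = res$xi, work = res$W)
  list(trace = trace,
       state = system_state(res$x, res$v, state$time + res$t_elapsed),
       work_end = res$work_end)
}

#' Lambda recording grid between two endpoints
#'
#' Evenly spaced at approximately \code{spacing}, always including both
#' endpoints exactly.
#'
#' @param l0,l1 endpoints [A]
#' @param spacing target spacing [A]
#' @return numeric grid
#' @export
lambda_record_grid <- function(l0, l1, spacing = 0.1) {
  n <- max(2L, as.integer(round((l1 - l0) / spacing)) + 1L)
  seq(l0, l1, length.out = n)
}

#' Constrained relaxation segment (exactly zero work)
#'
#' Relaxes the system at fixed extension between pulling stages.  Two
#' realizations are provided: \code{"freeze"} pins the pulled coordinate's
#' atoms at their current positions and removes the guide (the endpoints of
#' the chain are fixed, all other degrees of freedom thermalize);
#' \code{"hold"} keeps the guide spring active at a fixed lambda.  The guide
#' does not move in either case, so the external work is exactly zero.
#'
#' @inheritParams steered_segment
#' @param t_relax relaxation duration [ps]
#' @param method \code{"freeze"} (default) or \code{"hold"}
#' @param lambda hold-mode guide position; defaults to the current reaction
#'   coordinate value
#' @return list with \code{state} and \code{work} (identically 0)
#' @export
relax_segment <- function(state, potential, steering, params, t_relax,
                          method = c("freeze", "hold"), lambda = NULL) {
  method <- match.arg(method)
  if (t_relax < 0) stop("t_relax must be >= 0")
  dim <- potential$dimension
  m <- .expand_masses(params, dim)
  rc <- .rc_of(potential, steering)
  nsteps <- ceiling(t_relax / params$timestep)
  if (nsteps == 0L) return(list(state = state, work = 0))
  if (method == "freeze") {
    frozen <- if (rc$type == 0L) {
      1L
    } else {
      c(3L * rc$ai + 1:3, 3L * rc$aj + 1:3)
    }
    res <- cpp_hold_segment(potential$kind_code, potential$params_vec,
                            state$positions, state$velocities, m,
                            kB * params$temperature, params$friction,
                            params$timestep, nsteps, FALSE, 0, 0,
                            rc$type, rc$ai, rc$aj, as.integer(frozen), 0L)
  } else {
    if (is.null(lambda)) {
      lambda <- cpp_rc_value(rc$type, rc$ai, rc$aj, state$positions)
    }
    res <- cpp_hold_segment(potential$kind_code, potential$params_vec,
                            state$positions, state$velocities, m,
                            kB * params$temperature, params$friction,
                            params$timestep, nsteps, TRUE, steering$k,
                            lambda, rc$type, rc$ai, rc$aj, integer(0), 0L)
  }
  list(state = system_state(res$x, res$v, state$time + res$t_elapsed),
       work = res$work)
}

#' Equilibrate a state at fixed guide position
#'
#' Convenience wrapper: hold-mode integration for \code{t_equil} with the
#' guide at \code{lambda} (default: the protocol's lambda_start).
#'
#' @inheritParams relax_segment
#' @param t_equil equilibration time [ps]
#' @return the equilibrated [system_state()]
#' @export
equilibrate_state <- function(state, potential, steering, params, t_equil,
                              lambda = steering$lambda_start) {
  if (t_equil <= 0) return(state)
  hold <- steering_protocol(k = steering$k, lambda_start = lambda,
                            mode = "hold",
                            reaction_coord = steering$reaction_coord)
  steered_segment(state, potential, hold, params, duration = t_equil)$state
}
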
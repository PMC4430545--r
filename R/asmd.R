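#' Stage plan for staged pulling
#'
#' Describes how the reaction coordinate is broken into contiguous pulling
#' segments, how many trajectories run per stage (tps), and the inter-stage
#' relaxation used in full-relaxation mode.  Defaults mirror the
#' conventional helical-peptide stretching protocol: ten 2 A segments
#' spanning 13 to 33 A with 100 ps of constrained relaxation.
#'
#' @param lambda_start,lambda_end global pulling range [A]
#' @param n_stages number of equal segments
#' @param tps trajectories per stage (>= 1)
#' @param velocity optional pulling velocity [A/ns]; when NULL the steering
#'   protocol's velocity is used
#' @param t_relax constrained-relaxation duration between stages [ps]
#'   (full-relaxation mode only)
#' @param master_seed master seed from which all per-(stage, trajectory,
#'   phase) random streams derive
#' @param record_spacing lambda recording grid spacing [A]
#' @param relax_method \code{"freeze"} (pin the pulled atoms, guide removed)
#'   or \code{"hold"} (guide held at fixed lambda); both do exactly zero work
#' @param resample_velocities if TRUE, redraw Maxwell-Boltzmann velocities
#'   after the naive-mode contraction instead of cloning the selected
#'   trajectory's velocities (default FALSE: clone)
#' @param t_equil optional equilibration of the provided initial state
#'   before stage 1 [ps]
#' @param segments optional explicit 2-column matrix of (start, end) pairs,
#'   overriding \code{lambda_start}/\code{lambda_end}/\code{n_stages}
#' @return object of class \code{"stage_plan"}
#' @export
stage_plan <- function(lambda_start = 13, lambda_end = 33, n_stages = 10,
                       tps = 100, velocity = NULL, t_relax = 100,
                       master_seed = 1, record_spacing = 0.1,
                       relax_method = c("freeze", "hold"),
                       resample_velocities = FALSE, t_equil = 0,
                       segments = NULL) {
  relax_method <- match.arg(relax_method)
  if (is.null(segments)) {
    if (lambda_end <= lambda_start) stop("lambda_end must exceed lambda_start")
    edges <- seq(lambda_start, lambda_end, length.out = n_stages + 1L)
    segments <- cbind(edges[-length(edges)], edges[-1L])
  } else {
    segments <- as.matrix(segments)
    if (ncol(segments) != 2L) stop("segments must have two columns")
    if (any(segments[, 2L] <= segments[, 1L])) {
      stop("each segment must be increasing in lambda")
    }
    if (nrow(segments) > 1L &&
        any(abs(segments[-1L, 1L] -
                segments[-nrow(segments), 2L]) > 1e-9)) {
      stop("segments must be contiguous")
    }
  }
  tps <- as.integer(tps)
  if (tps < 1L) stop("tps must be >= 1")
  if (t_relax < 0) stop("t_relax must be >= 0")
  structure(list(segments = unname(segments), tps = tps,
                 velocity = velocity, t_relax = t_relax,
                 master_seed = as.integer(master_seed),
                 record_spacing = record_spacing,
                 relax_method = relax_method,
                 resample_velocities = isTRUE(resample_velocities),
                 t_equil = t_equil),
            class = "stage_plan")
}

#' Deterministic per-(stage, trajectory, phase) stream seed
#'
#' Maps the master seed and a (stage, trajectory, phase) triple to a 31-bit
#' seed by iterated Lehmer mixing, so that every trajectory is pulled "with
#' different random number sequences" while the whole run reproduces
#' bit-identically from the master seed.  Phases: 0 equilibration, 1 pull,
#' 2 relaxation, 3 velocity resampling.
#'
#' @param master master seed (integer)
#' @param stage,traj,phase non-negative integers identifying the stream
#' @return an integer seed in [0, 2^31 - 2]
#' @export
stream_seed <- function(master, stage, traj, phase) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (v in c(stage, traj, phase)) {
    h <- (h * 48271 + as.numeric(v) + 1) %% m
  }
  as.integer(h)
}

.maxwell_velocities <- function(params, dim) {
  m <- .expand_masses(params, dim)
  rnorm(dim, sd = sqrt(kB * params$temperature * 418.4 / m))
}

.stage_steering <- function(steering, l0, l1, velocity) {
  steering_protocol(k = steering$k, lambda_start = l0, lambda_end = l1,
                    velocity = velocity, mode = "pull",
                    reaction_coord = steering$reaction_coord)
}

# Run one pulling stage: tps steered segments from the given start states.
.run_stage <- function(potential, steering, params, plan, stage_idx,
                       starts, grid, velocity) {
  seg <- plan$segments[stage_idx, ]
  sp <- .stage_steering(steering, seg[1L], seg[2L], velocity)
  tps <- plan$tps
  W <- matrix(0, nrow = tps, ncol = length(grid))
  finals <- vector("list", tps)
  for (i in seq_len(tps)) {
    set.seed(stream_seed(plan$master_seed, stage_idx, i, 1L))
    st <- if (length(starts) == 1L) starts[[1L]] else starts[[i]]
    out <- steered_segment(st, potential, sp, params, record_grid = grid)
    W[i, ] <- out$trace$work
    finals[[i]] <- out$state
  }
  ens <- work_ensemble(grid, W, params$temperature)
  list(ensemble = ens, pmf = jarzynski_pmf(ens), finals = finals)
}

.stage_result <- function(stage, ensemble, pmf, finals, selected = NA_integer_,
                          carry_in = NULL, mode = "naive") {
  nF <- length(pmf$F)
  log <- data.frame(stage = stage, n = nrow(ensemble$W),
                    mean_W_end = mean(ensemble$W[, ncol(ensemble$W)]),
                    F_end = pmf$F[nF],
                    selected = if (is.na(selected)) NA_integer_ else selected)
  structure(list(stage = stage, ensemble = ensemble, pmf = pmf,
                 finals = finals, selected = selected, carry_in = carry_in,
                 mode = mode, log = log),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("<stage_result> stage %d (%s): N=%d, F_end=%.4f kcal/mol\n",
              x$stage, x$mode, nrow(x$ensemble$W),
              x$pmf$F[length(x$pmf$F)]))
  invisible(x)
}

.prepare_first_state <- function(system, steering, params, plan) {
  st <- system$state
  if (plan$t_equil > 0) {
    set.seed(stream_seed(plan$master_seed, 0L, 0L, 0L))
    st <- equilibrate_state(st, system$potential, steering, params,
                            plan$t_equil)
  }
  st
}

#' Plain steered molecular dynamics over one segment
#'
#' Runs \code{tps} independent steered trajectories over the plan's single
#' segment, all from the same initial state, with per-trajectory random
#' streams, and estimates the PMF by the Jarzynski average.  Identical to a
#' one-segment naive adaptive run by construction.
#'
#' @param system list with elements \code{potential} (a [make_potential()]
#'   model) and \code{state} (the shared initial [system_state()])
#' @param steering a [steering_protocol()] carrying k, velocity and the
#'   reaction-coordinate choice
#' @param plan a [stage_plan()] with exactly one segment
#' @param params a [langevin_params()]
#' @return a \code{stage_result}: work ensemble, stage PMF, final states,
#'   JE-selected index
#' @export
run_smd <- function(system, steering, plan, params) {
  if (nrow(plan$segments) != 1L) {
    stop("run_smd requires a plan with exactly one segment")
  }
  run_naive_asmd(system, steering, plan, params)$stages[[1L]]
}

#' Naive adaptive steered molecular dynamics
#'
#' Per stage: pull \code{tps} trajectories from a common start, estimate the
#' stage PMF by the Jarzynski average, select the trajectory whose final
#' work is closest to the stage's final free energy (the JE criterion), and
#' clone that trajectory's coordinates and velocities as the common start of
#' the next stage (fresh random streams).  The global PMF is the stage PMFs
#' chained with cumulative offsets, continuous at stage boundaries by
#' construction.
#'
#' @inheritParams run_smd
#' @param plan a [stage_plan()]
#' @param verbose print one log line per stage
#' @return list with \code{stages} (list of \code{stage_result}),
#'   \code{pmf} (assembled [pmf_curve()]), and \code{log} (per-stage
#'   data.frame)
#' @export
run_naive_asmd <- function(system, steering, plan, params, verbose = FALSE) {
  potential <- system$potential
  velocity <- if (is.null(plan$velocity)) steering$velocity else plan$velocity
  n_stages <- nrow(plan$segments)
  start <- .prepare_first_state(system, steering, params, plan)
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    seg <- plan$segments[s, ]
    grid <- lambda_record_grid(seg[1L], seg[2L], plan$record_spacing)
    st <- .run_stage(potential, steering, params, plan, s, list(start),
                     grid, velocity)
    F_end <- st$pmf$F[length(st$pmf$F)]
    end_works <- st$ensemble$W[, ncol(st$ensemble$W)]
    sel <- je_select(end_works, F_end)
    start <- st$finals[[sel]]
    if (plan$resample_velocities) {
      set.seed(stream_seed(plan$master_seed, s, sel, 3L))
      start$velocities <- .maxwell_velocities(params, potential$dimension)
    }
    stages[[s]] <- .stage_result(s, st$ensemble, st$pmf, st$finals,
                                 selected = sel, mode = "naive")
    if (verbose) {
      message(sprintf("stage %d: N=%d <W>=%.4f F_end=%.4f selected=%d",
                      s, plan$tps, mean(end_works), F_end, sel))
    }
  }
  list(stages = stages, pmf = assemble_pmf(stages),
       log = do.call(rbind, lapply(stages, `[[`, "log")))
}

#' Full-relaxation adaptive steered molecular dynamics
#'
#' Per stage: pull all \code{tps} trajectories, then relax each one
#' independently for \code{t_relax} with the pulled coordinate constrained
#' (exactly zero external work, asserted), and let each trajectory continue
#' itself into the next stage -- no contraction, no selection.  Because the
#' relaxation does no work, the Jarzynski average is unaffected; the global
#' PMF is computed from the per-trajectory work carried across stages.
#'
#' @inheritParams run_naive_asmd
#' @return list with \code{stages}, \code{pmf}, \code{log}, and
#'   \code{relax_works} (matrix of relaxation works, identically zero)
#' @export
run_fr_asmd <- function(system, steering, plan, params, verbose = FALSE) {
  potential <- system$potential
  velocity <- if (is.null(plan$velocity)) steering$velocity else plan$velocity
  n_stages <- nrow(plan$segments)
  tps <- plan$tps
  start0 <- .prepare_first_state(system, steering, params, plan)
  starts <- list(start0)
  carry <- numeric(tps)
  stages <- vector("list", n_stages)
  relax_works <- matrix(0, nrow = n_stages, ncol = tps)
  for (s in seq_len(n_stages)) {
    seg <- plan$segments[s, ]
    grid <- lambda_record_grid(seg[1L], seg[2L], plan$record_spacing)
    st <- .run_stage(potential, steering, params, plan, s, starts,
                     grid, velocity)
    stages[[s]] <- .stage_result(s, st$ensemble, st$pmf, st$finals,
                                 carry_in = carry, mode = "fr")
    carry <- carry + st$ensemble$W[, ncol(st$ensemble$W)]
    if (s < n_stages && plan$t_relax > 0) {
      hold_sp <- steering_protocol(k = steering$k,
                                   lambda_start = seg[2L], mode = "hold",
                                   reaction_coord = steering$reaction_coord)
      starts <- vector("list", tps)
      for (i in seq_len(tps)) {
        set.seed(stream_seed(plan$master_seed, s, i, 2L))
        rl <- relax_segment(st$finals[[i]], potential, hold_sp, params,
                            plan$t_relax, method = plan$relax_method,
                            lambda = seg[2L])
        stopifnot(identical(rl$work, 0))
        relax_works[s, i] <- rl$work
        starts[[i]] <- rl$state
      }
    } else {
      starts <- st$finals
    }
    if (verbose) {
      message(sprintf("stage %d: N=%d <W_carry>=%.4f", s, tps, mean(carry)))
    }
  }
  list(stages = stages, pmf = assemble_pmf(stages),
       log = do.call(rbind, lapply(stages, `[[`, "log")),
       relax_works = relax_works)
}

#' Assemble a global PMF from stage results
#'
#' For contracted (naive) runs, each stage PMF is offset by the cumulative
#' final free energy of the preceding stages; the global curve is continuous
#' at every boundary by construction and zero at the global start.  For
#' carried (full-relaxation) runs, the per-trajectory cumulative works are
#' reconstructed across stages and the Jarzynski average is evaluated
#' globally, which reduces exactly to single-stage Jarzynski estimation on
#' the concatenated path.
#'
#' @param stage_results list of \code{stage_result} objects, contiguous in
#'   lambda
#' @param method \code{"auto"} (from the stage results' mode),
#'   \code{"contracted"}, or \code{"carried"}
#' @return a [pmf_curve()]
#' @export
assemble_pmf <- function(stage_results,
                         method = c("auto", "contracted", "carried")) {
  method <- match.arg(method)
  if (length(stage_results) == 0L) stop("no stages to assemble")
  if (method == "auto") {
    method <- if (identical(stage_results[[1L]]$mode, "fr")) "carried"
              else "contracted"
  }
  grids <- lapply(stage_results, function(s) s$ensemble$lambda)
  for (s in seq_along(stage_results)[-1L]) {
    if (abs(grids[[s]][1L] - grids[[s - 1L]][length(grids[[s - 1L]])]) >
        1e-9) {
      stop("stages are not contiguous in lambda")
    }
  }
  if (method == "contracted") {
    lambda <- grids[[1L]]
    F <- stage_results[[1L]]$pmf$F
    offset <- F[length(F)]
    if (length(stage_results) > 1L) {
      for (s in seq_along(stage_results)[-1L]) {
        Fs <- stage_results[[s]]$pmf$F
        lambda <- c(lambda, grids[[s]][-1L])
        F <- c(F, offset + Fs[-1L])
        offset <- offset + Fs[length(Fs)]
      }
    }
    n_traj <- nrow(stage_results[[1L]]$ensemble$W)
    return(pmf_curve(lambda, F, reference_lambda = lambda[1L],
                     n_traj = n_traj))
  }
  # carried: rebuild cumulative per-trajectory works on the global grid
  tps <- nrow(stage_results[[1L]]$ensemble$W)
  Temp <- stage_results[[1L]]$ensemble$temperature
  carry <- numeric(tps)
  lambda <- NULL
  Wg <- NULL
  for (s in seq_along(stage_results)) {
    ens <- stage_results[[s]]$ensemble
    if (nrow(ens$W) != tps) stop("carried assembly requires constant tps")
    keep <- if (s == 1L) seq_along(ens$lambda) else -1L
    lambda <- c(lambda, ens$lambda[keep])
    Wg <- cbind(Wg, carry + ens$W[, keep, drop = FALSE])
    carry <- carry + ens$W[, ncol(ens$W)]
  }
  F <- je_estimate(Wg, Temp)
  pmf_curve(lambda, F, reference_lambda = lambda[1L], n_traj = tps)
}
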
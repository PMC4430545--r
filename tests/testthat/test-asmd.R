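test_that("stage plan defaults mirror the standard stretching protocol", {
  plan <- stage_plan()
  expect_equal(nrow(plan$segments), 10)
  expect_equal(plan$segments[1, 1], 13)
  expect_equal(plan$segments[10, 2], 33)
  expect_equal(unique(round(plan$segments[, 2] - plan$segments[, 1], 12)), 2)
  expect_equal(plan$t_relax, 100)
  expect_error(stage_plan(tps = 0), "tps")
  expect_error(stage_plan(segments = rbind(c(0, 1), c(1.5, 2))),
               "contiguous")
})

test_that("stream seeds are valid, deterministic and phase-separated", {
  s <- expand.grid(stage = 0:5, traj = 0:30, phase = 0:3)
  seeds <- mapply(stream_seed, 42, s$stage, s$traj, s$phase)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
  expect_identical(stream_seed(42, 3, 7, 1), stream_seed(42, 3, 7, 1))
  expect_false(stream_seed(42, 3, 7, 1) == stream_seed(43, 3, 7, 1))
})

test_that("one-segment naive staging is bit-identical to plain SMD", {
  sys <- harmonic_system()
  st <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 2,
                          velocity = 100)
  plan <- stage_plan(lambda_start = 0, lambda_end = 2, n_stages = 1,
                     tps = 8, master_seed = 3, t_equil = 2)
  a <- run_smd(sys, st, plan, toy_params())
  b <- run_naive_asmd(sys, st, plan, toy_params())$stages[[1]]
  expect_identical(a$ensemble$W, b$ensemble$W)
  expect_identical(a$pmf$F, b$pmf$F)
  expect_identical(a$selected, b$selected)
  expect_error(run_smd(sys, st, stage_plan(0, 2, n_stages = 2, tps = 2),
                       toy_params()), "one segment")
})

test_that("full runs reproduce bit-identically from the master seed", {
  sys <- harmonic_system()
  st <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 1,
                          velocity = 200)
  plan <- stage_plan(lambda_start = 0, lambda_end = 1, n_stages = 2,
                     tps = 5, master_seed = 9, t_relax = 0.5)
  p <- toy_params()
  n1 <- run_naive_asmd(sys, st, plan, p)
  n2 <- run_naive_asmd(sys, st, plan, p)
  expect_identical(n1$pmf, n2$pmf)
  expect_identical(lapply(n1$stages, `[[`, "ensemble"),
                   lapply(n2$stages, `[[`, "ensemble"))
  f1 <- run_fr_asmd(sys, st, plan, p)
  f2 <- run_fr_asmd(sys, st, plan, p)
  expect_identical(f1$pmf, f2$pmf)
})

test_that("naive contraction clones one final state into the next stage", {
  sys <- harmonic_system()
  st <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 1,
                          velocity = 200)
  plan <- stage_plan(lambda_start = 0, lambda_end = 1, n_stages = 2,
                     tps = 6, master_seed = 21)
  res <- run_naive_asmd(sys, st, plan, toy_params())
  for (sr in res$stages) {
    # selection satisfies the argmin property against a brute-force scan
    W_end <- sr$ensemble$W[, ncol(sr$ensemble$W)]
    F_end <- sr$pmf$F[length(sr$pmf$F)]
    expect_equal(sr$selected, which.min(abs(W_end - F_end)))
    expect_identical(sr$pmf$F[1], 0)
    # within-stage end-work spread is finite
    expect_true(is.finite(var(W_end)))
  }
  # stage-2 trajectories all branch from the stage-1 selected state:
  # rerun stage 2 manually from that state and compare the first trajectory
  sel_state <- res$stages[[1]]$finals[[res$stages[[1]]$selected]]
  sp2 <- steering_protocol(k = 1, lambda_start = 0.5, lambda_end = 1,
                           velocity = 200)
  set.seed(stream_seed(21, 2, 1, 1))
  manual <- steered_segment(sel_state, sys$potential, sp2, toy_params(),
                            record_grid = res$stages[[2]]$ensemble$lambda)
  expect_identical(manual$trace$work, res$stages[[2]]$ensemble$W[1, ])
})

test_that("assembled PMF is continuous, zero-based, and additive", {
  # synthetic stage results with known end values {2, 3} -> global end 5
  lam1 <- seq(0, 1, by = 0.5); lam2 <- seq(1, 2, by = 0.5)
  mk <- function(lam, Fend, stage) {
    W <- matrix(rep(seq(0, Fend, length.out = length(lam)), each = 3),
                nrow = 3)
    ens <- work_ensemble(lam, W, 300)
    adaptivepull:::.stage_result(stage, ens, jarzynski_pmf(ens),
                                 finals = NULL, mode = "naive")
  }
  g <- assemble_pmf(list(mk(lam1, 2, 1), mk(lam2, 3, 2)))
  expect_equal(g$F[length(g$F)], 5)
  expect_equal(g$F[1], 0)
  expect_equal(g$lambda, seq(0, 2, by = 0.5))
  # single stage: identity
  one <- assemble_pmf(list(mk(lam1, 2, 1)))
  expect_equal(one$F, c(0, 1, 2))
  expect_error(assemble_pmf(list(mk(lam1, 2, 1), mk(lam2 + 1, 3, 2))),
               "contiguous")
})

test_that("carried assembly equals one-shot JE on the summed works", {
  sys <- harmonic_system()
  st <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 1,
                          velocity = 400)
  plan <- stage_plan(lambda_start = 0, lambda_end = 1, n_stages = 4,
                     tps = 10, master_seed = 6, t_relax = 0)
  res <- run_fr_asmd(sys, st, plan, toy_params())
  # rebuild the cumulative work matrix independently
  carry <- numeric(plan$tps)
  Wall <- NULL; lam <- NULL
  for (s in seq_along(res$stages)) {
    ens <- res$stages[[s]]$ensemble
    keep <- if (s == 1) seq_along(ens$lambda) else -1
    Wall <- cbind(Wall, carry + ens$W[, keep, drop = FALSE])
    lam <- c(lam, ens$lambda[keep])
    carry <- carry + ens$W[, ncol(ens$W)]
  }
  direct <- je_estimate(Wall, 300)
  expect_equal(res$pmf$F, direct - direct[1], tolerance = 1e-12)
  expect_equal(res$pmf$lambda, lam)
  # global continuity at each boundary is exact by shared grid points
  expect_equal(anyDuplicated(res$pmf$lambda), 0)
})

test_that("FR relaxation segments contribute literally zero work", {
  sys <- harmonic_system()
  st <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 1,
                          velocity = 400)
  plan <- stage_plan(lambda_start = 0, lambda_end = 1, n_stages = 3,
                     tps = 4, master_seed = 2, t_relax = 0.5)
  res <- run_fr_asmd(sys, st, plan, toy_params())
  expect_identical(res$relax_works,
                   matrix(0, nrow = 3, ncol = 4))
})
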
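test_that("gamma = 0, T = 0 integration conserves energy (symplectic limit)", {
  # velocity-Verlet limit of BAOAB; shadow-energy oscillation stays tiny
  res <- adaptivepull:::cpp_hold_segment(
    1L, 1, 0.5, 0.3, 1, 0, 0, 5e-5, 1e4, FALSE, 0, 0, 0L, 0L, 0L,
    integer(0), 10L)
  e <- res$energy
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-6)
})

test_that("zero potential, T = 0, zero velocity leaves the state untouched", {
  pot <- make_potential(potential_spec("free"))
  params <- toy_params(temperature = 0)
  st <- system_state(1.23, 0)
  out <- langevin_step(st, pot, guide = NULL, params)
  expect_identical(out$positions, st$positions)
  expect_identical(out$velocities, st$velocities)
  expect_equal(out$time, params$timestep)
})

test_that("equilibrium sampling satisfies equipartition", {
  # hold-mode run under U = a x^2/2 plus guide k at lambda = 0:
  # var(x) -> kB T / (a + k)
  a <- 2; k <- 1
  pot <- make_potential(potential_spec("harmonic", a = a))
  hold <- steering_protocol(k = k, lambda_start = 0, mode = "hold")
  params <- toy_params()
  set.seed(42)
  s <- system_state(0)
  xs <- numeric(2000)
  for (i in seq_along(xs)) {
    r <- steered_segment(s, pot, hold, params, duration = 0.25)
    s <- r$state
    xs[i] <- s$positions[1]
  }
  theory <- kT300 / (a + k)
  se <- theory * sqrt(2 / length(xs))  # iid-normal variance SE (samples
  expect_lt(abs(var(xs) - theory), 3 * 1.5 * se)  # ~decorrelated; 1.5x slack
})

test_that("hold mode does exactly zero work", {
  pot <- make_potential(potential_spec("harmonic", a = 1))
  hold <- steering_protocol(k = 5, lambda_start = 0.7, mode = "hold")
  set.seed(1)
  r <- steered_segment(system_state(0), pot, hold, toy_params(),
                       duration = 5)
  expect_identical(r$work_end, 0)
  expect_identical(r$trace$work, c(0, 0))
})

test_that("frozen system accumulates the closed-form work", {
  # effectively infinite mass: xi stays at xi0, so
  # W = (k/2) [(L - xi0)^2 - (lambda_start - xi0)^2]; the integrand is
  # linear in lambda so trapezoidal accumulation is exact
  k <- 3; xi0 <- 0.4; L <- 2
  pot <- make_potential(potential_spec("free"))
  sp <- steering_protocol(k = k, lambda_start = 0, lambda_end = L,
                          velocity = 100)
  params <- langevin_params(temperature = 0, friction = 0,
                            timestep = 0.002, masses = 1e16)
  r <- steered_segment(system_state(xi0), pot, sp, params)
  closed <- (k / 2) * ((L - xi0)^2 - (0 - xi0)^2)
  expect_equal(r$work_end, closed, tolerance = 1e-10)
  expect_equal(r$state$positions[1], xi0, tolerance = 1e-10)
})

test_that("a particle riding the guide exactly does zero work", {
  # free potential, gamma = 0, T = 0, v0 = vpull, x0 = lambda_start:
  # xi(t) = lambda(t) for all t, so the integrand k (lambda - xi) v vanishes
  vpull <- 0.05  # A/ps
  pot <- make_potential(potential_spec("free"))
  sp <- steering_protocol(k = 4, lambda_start = 0, lambda_end = 1,
                          velocity = vpull * 1000)
  params <- langevin_params(temperature = 0, friction = 0,
                            timestep = 0.002, masses = 1)
  r <- steered_segment(system_state(0, vpull), pot, sp, params)
  expect_equal(r$work_end, 0, tolerance = 1e-12)
  expect_equal(max(abs(r$trace$work)), 0, tolerance = 1e-12)
})

test_that("same RNG stream gives bit-identical trajectories and work", {
  pot <- make_potential(potential_spec("double_well", h = 2, w = 1))
  sp <- steering_protocol(k = 7.2, lambda_start = -1, lambda_end = 1,
                          velocity = 500)
  params <- toy_params(masses = 10)
  set.seed(314)
  r1 <- steered_segment(system_state(-1), pot, sp, params)
  set.seed(314)
  r2 <- steered_segment(system_state(-1), pot, sp, params)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$state, r2$state)
  set.seed(315)
  r3 <- steered_segment(system_state(-1), pot, sp, params)
  expect_false(identical(r1$trace$work, r3$trace$work))
})

test_that("work error of a deterministic pull scales as O(dt^2)", {
  pot <- make_potential(potential_spec("harmonic", a = 1))
  wend <- function(dt) {
    params <- langevin_params(temperature = 0, friction = 5, timestep = dt,
                              masses = 1)
    sp <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 2,
                            velocity = 100)
    steered_segment(system_state(0), pot, sp, params)$work_end
  }
  w1 <- wend(0.004); w2 <- wend(0.002); w3 <- wend(0.001)
  ratio <- (w1 - w2) / (w2 - w3)
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})

test_that("velocity is interpreted in A/ns", {
  pot <- make_potential(potential_spec("free"))
  sp <- steering_protocol(k = 1, lambda_start = 0, lambda_end = 2,
                          velocity = 100)  # 0.1 A/ps -> 20 ps of pulling
  r <- steered_segment(system_state(0), pot, sp,
                       toy_params(temperature = 0))
  expect_equal(r$state$time, 20)
})

test_that("constrained relaxation pins the pulled coordinate and does no work", {
  # bead chain: endpoints frozen, interior thermalizes
  pot <- make_potential(potential_spec("bead_spring_helix", n_beads = 5))
  x0 <- as.numeric(t(cbind(seq(0, 6, length.out = 5), 0, 0)))
  sp <- steering_protocol(k = 7.2, lambda_start = 6, mode = "hold")
  params <- toy_params(masses = 10)
  set.seed(5)
  r <- relax_segment(system_state(x0), pot, sp, params, t_relax = 1,
                     method = "freeze")
  expect_identical(r$work, 0)
  expect_equal(r$state$positions[1:3], x0[1:3])       # first bead fixed
  expect_equal(r$state$positions[13:15], x0[13:15])   # last bead fixed
  expect_false(all(r$state$positions[4:12] == x0[4:12]))  # interior moved
  # hold-mode variant also does exactly zero work
  set.seed(5)
  r2 <- relax_segment(system_state(x0), pot, sp, params, t_relax = 1,
                      method = "hold")
  expect_identical(r2$work, 0)
})

test_that("non-finite dynamics are reported as integration errors", {
  # grossly unstable setup: stiff spring, light mass, huge timestep makes
  # the amplitude grow by ~4e10 per step until it overflows
  pot <- make_potential(potential_spec("harmonic", a = 1))
  sp <- steering_protocol(k = 100, lambda_start = 0, lambda_end = 2,
                          velocity = 10)
  params <- langevin_params(temperature = 0, friction = 0, timestep = 1,
                            masses = 1e-12)
  expect_error(steered_segment(system_state(0.1), pot, sp, params),
               "non-finite|diverged")
})
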
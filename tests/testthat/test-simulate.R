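test_that("implicit environment solve handles explicit, contractive and fixture cases", {
  # G2, H2 independent of e2: one-pass explicit evaluation
  m <- unstructured_model(growth = function(x, e, th) 0,
                          env_implicit_intrinsic = function(e, th) 2 * e$e1,
                          dim_e1 = 1L, dim_e2 = 1L, model_id = "explicit")
  expect_identical(solve_env_implicit(m, numeric(0), list(), 1.5, numeric(0)),
                   3)
  # contrived affine contraction e2 = 0.5 e2 + 1 has fixed point 2
  mc <- unstructured_model(growth = function(x, e, th) 0,
                           env_implicit_intrinsic = function(e, th)
                             0.5 * e$e2 + 1,
                           dim_e2 = 1L, e2_explicit = FALSE,
                           model_id = "contraction")
  expect_equal(solve_env_implicit(mc, numeric(0), list(), numeric(0),
                                  numeric(0), guess = 0), 2, tolerance = 1e-8)
  # foraging-prey total of the prey-predator fixture: n = 1, x = 0.3, p = 2
  expect_equal(solve_env_implicit(prey_predator_model(), 1, list(0.3), 2,
                                  numeric(0)), 1 / 1.6, tolerance = 1e-12)
})

test_that("the extinction set is invariant: an absent strategy stays absent", {
  cfg <- sim_config(t_end = 20, dt = 0.01, seed = 2L, record_stride = 10L)
  tr <- simulate_polymorphic(chemostat_model(), list(fig4_x, fig4_y),
                             list(n = c(0.3, 0), e1 = 1, theta = 0), cfg)
  expect_identical(max(tr$n[, 2]), 0)
  expect_true(all(tr$n >= 0))
})

test_that("deterministic chemostat converges to its known equilibrium", {
  md <- chemostat_model(list(rho2 = 0), stochastic = FALSE)
  cfg <- sim_config(t_end = 400, dt = 0.01, seed = 1L, record_stride = 100L)
  tr <- simulate_polymorphic(md, list(fig4_x), list(n = 0.2, e1 = 1), cfg)
  # R* = (delta + D)/(gamma beta), n* = D (rho1 - R*)/(beta R*)
  expect_equal(tail(tr$e1[, 1], 1), 0.121875, tolerance = 1e-4)
  expect_equal(tail(tr$n[, 1], 1), 0.3602564, tolerance = 1e-3)
})

test_that("Ornstein-Uhlenbeck driver reproduces its stationary moments", {
  tr <- ou_traj()
  m1 <- birkhoff_average(tr, function(s) s$theta[1])
  m2 <- birkhoff_average(tr, function(s) s$theta[1]^2)
  expect_lt(abs(m1$mean - 0), 3 * m1$se)
  expect_lt(abs(m2$mean - 0.5), 3 * m2$se)   # b^2/(2a) = 0.5
})

test_that("the Euler scheme shows first-order endpoint convergence", {
  md <- chemostat_model(list(rho2 = 0), stochastic = FALSE)
  ref <- fluctinvade:::det_integrate(md, list(fig4_x), c(0.2, 1), c(0, 20))
  refv <- as.numeric(ref[nrow(ref), -1])
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    cfg <- sim_config(t_end = 20, dt = dt, seed = 1L,
                      record_stride = round(20 / dt))
    tr <- simulate_polymorphic(md, list(fig4_x), list(n = 0.2, e1 = 1), cfg)
    max(abs(c(tail(tr$n, 1), tail(tr$e1, 1)) - refv))
  }, 0)
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 1.7 & ratios < 2.3))
})

test_that("identical configurations reproduce trajectories bitwise", {
  cfg <- sim_config(t_end = 5, dt = 0.01, seed = 3L, record_stride = 10L)
  t1 <- simulate_polymorphic(chemostat_model(), list(fig4_x),
                             list(n = 0.3, e1 = 1), cfg)
  t2 <- simulate_polymorphic(chemostat_model(), list(fig4_x),
                             list(n = 0.3, e1 = 1), cfg)
  expect_identical(t1$n, t2$n)
  expect_identical(t1$theta, t2$theta)
})

test_that("structured simulation keeps class distributions on the simplex", {
  cfg <- sim_config(t_end = 30, dt = 0.002, seed = 7L, record_stride = 20L)
  tr <- simulate_structured(sirs_model(), list(8.7),
                            list(n = list(c(0.8, 0.4)), e1 = 1.6, theta = 0),
                            cfg)
  expect_true(all(abs(rowSums(tr$v) - 1) <= 1e-8))
  expect_lt(tr$simplex_drift, 1e-10)
})

test_that("raw and decomposed structured forms agree to the order of the scheme", {
  sm0 <- sirs_model(list(b = 0))   # deterministic skeleton for clean scaling
  init <- list(n = list(c(0.8, 0.4)), e1 = 1.6, theta = 0)
  errs <- vapply(c(0.004, 0.002, 0.001), function(dt) {
    cfg <- sim_config(t_end = 20, dt = dt, seed = 7L,
                      record_stride = round(0.02 / dt))
    ta <- simulate_structured(sm0, list(8.7), init, cfg,
                              form = "decomposition")
    tb <- simulate_structured(sm0, list(8.7), init, cfg, form = "raw")
    max(abs(ta$n - tb$n))
  }, 0)
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 1.6 & ratios < 2.5))
  # and under a shared stochastic path the two forms stay close at fixed dt
  cfg <- sim_config(t_end = 20, dt = 0.002, seed = 7L, record_stride = 10L)
  init2 <- list(n = list(c(0.8, 0.4)), e1 = 1.6, theta = 0)
  ta <- simulate_structured(sirs_model(), list(8.7), init2, cfg,
                            form = "decomposition")
  tb <- simulate_structured(sirs_model(), list(8.7), init2, cfg, form = "raw")
  expect_lt(max(abs(ta$n - tb$n)), 0.01)
})

test_that("two identical structured strategies keep their relative size", {
  # neutral dimorphism: with equal strategies the relative population size
  # returns to (near) its initial value once the class structures align
  cfg <- sim_config(t_end = 120, dt = 0.002, seed = 9L, record_stride = 50L)
  init <- list(n = list(c(0.5, 0.25), c(0.36, 0.175)), e1 = 1.6, theta = 0)
  tr <- simulate_structured(sirs_model(), list(8.7, 8.7), init, cfg)
  P <- tr$n[, 2] / rowSums(tr$n)
  expect_lt(abs(tail(P, 1) - P[1]), 0.02)
})

test_that("trajectories round-trip through CSV with their manifest", {
  cfg <- sim_config(t_end = 5, dt = 0.01, seed = 3L, record_stride = 10L)
  tr <- simulate_polymorphic(chemostat_model(), list(fig4_x),
                             list(n = 0.3, e1 = 1), cfg)
  path <- file.path(tempdir(), "traj_roundtrip.csv")
  write_trajectory(tr, path)
  rt <- read_trajectory(path)
  expect_equal(rt$n, tr$n, ignore_attr = TRUE)
  expect_equal(rt$theta, tr$theta, ignore_attr = TRUE)
  expect_identical(rt$config$seed, tr$config$seed)
  df <- utils::read.csv(path)
  expect_true(all(c("t", "n_1", "e1_1", "theta_1") %in% names(df)))
})
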
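test_that("with zero separation the relative frequency is exactly conserved", {
  m <- chemostat_model()
  cfg <- sim_config(t_end = 20, dt = 0.01, seed = 5L, record_stride = 20L)
  tr <- simulate_dimorphic(m, fig4_x, c(0, 0, 0), c(-1, 5, -0.5), eps = 0,
                           list(N = 0.4, P = 0.37, e1 = 1, theta = 0), cfg)
  expect_identical(unique(tr$n[, "P"]), 0.37)
})

test_that("the (N, P) system matches direct two-strategy simulation under shared noise", {
  # stochastic chemostat: the discrepancy between the two formulations
  # shrinks with the step size
  m <- chemostat_model()
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    cfg <- sim_config(t_end = 50, dt = dt, seed = 11L,
                      record_stride = round(0.1 / dt))
    tp <- simulate_polymorphic(m, list(fig4_x, fig4_y),
                               list(n = c(0.2, 0.2), e1 = 1), cfg)
    td <- simulate_dimorphic(m, fig4_x, c(0, 0, 0), fig4_y - fig4_x, eps = 1,
                             list(N = 0.4, P = 0.5, e1 = 1), cfg)
    Np <- rowSums(tp$n)
    max(abs(Np - td$n[, "N"]), abs(tp$n[, 2] / Np - td$n[, "P"]))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("the equivalence holds on the competition and prey-predator fixtures", {
  # Lotka-Volterra (stochastic), one step size
  lv <- lotka_volterra_model(strategies = list(0.48, 0.51))
  cfg <- sim_config(t_end = 30, dt = 0.005, seed = 13L, record_stride = 20L)
  tp <- simulate_polymorphic(lv, list(0.48, 0.51),
                             list(n = c(0.25, 0.25)), cfg)
  td <- simulate_dimorphic(lv, 0.48, 0, 1, eps = 0.03,
                           list(N = 0.5, P = 0.5), cfg)
  Np <- rowSums(tp$n)
  expect_lt(max(abs(Np - td$n[, "N"])), 5e-3)
  expect_lt(max(abs(tp$n[, 2] / Np - td$n[, "P"])), 5e-3)
  # prey-predator (deterministic): first-order convergence in dt
  pp <- pp_model()
  errs <- vapply(c(0.004, 0.002), function(dt) {
    cfg <- sim_config(t_end = 30, dt = dt, seed = 1L,
                      record_stride = round(0.02 / dt))
    tp <- simulate_polymorphic(pp, list(0.27, 0.3),
                               list(n = c(0.3, 0.3), e1 = 0.5), cfg)
    td <- simulate_dimorphic(pp, 0.27, 0, 1, eps = 0.03,
                             list(N = 0.6, P = 0.5, e1 = 0.5), cfg)
    max(abs(rowSums(tp$n) - td$n[, "N"]))
  }, 0)
  expect_gt(errs[1] / errs[2], 1.6)
})

test_that("P stays within [0, 1] and clamps are counted", {
  m <- chemostat_model()
  cfg <- sim_config(t_end = 400, dt = 0.02, seed = 21L, record_stride = 20L)
  tr <- simulate_dimorphic(m, fig4_x, c(0, 0, 0),
                           (fig4_y - fig4_x) / 0.01, eps = 0.01,
                           list(N = 0.4, P = 0.5, e1 = 1, theta = 0), cfg)
  expect_true(all(tr$n[, "P"] >= 0 & tr$n[, "P"] <= 1))
  expect_true(is.finite(tr$clip_count))
})

test_that("the invader's frequency climbs to fixation for the reference pair", {
  rep_ <- chemo_slowfast(1L, c(0.05, 0.02, 0.01))
  expect_identical(rep_$p_star, 1)
  expect_true(all(rep_$pass))
  # closer strategies track the averaged flow at least as well
  expect_true(all(diff(rep_$sup_dev) <= 1e-6))
})

test_that("with zero separation the report records the exact initial deviation", {
  m <- chemostat_model()
  cls <- classify_pair(m, fig4_x, fig4_y)
  rep_ <- compare_to_averaged(m, fig4_x, c(0, 0, 0),
                              (fig4_y - fig4_x) / 0.01,
                              eps_grid = c(0), delta = 0.1,
                              config_template = sim_config(t_end = 1,
                                                           dt = 0.02,
                                                           seed = 1L),
                              classification = cls, p0 = 0.3,
                              init_fast = list(N = 0.4, e1 = 1, theta = 0))
  expect_identical(rep_$sup_dev, 0.7)
  expect_error(
    compare_to_averaged(m, fig4_x, c(0, 0, 0), c(1, 0, 0), c(0.01), 0.1,
                        sim_config(t_end = 1, dt = 0.02, seed = 1L),
                        classify_outcome(1e-12, 1e-12,
                                         list(drive1 = 0, quad = 0,
                                              mixed = 0))),
    "undetermined")
})

test_that("a branching pair settles at the predicted interior frequency", {
  lv <- lotka_volterra_model(strategies = list(0.48, 0.51))
  p <- example_params("lotka_volterra")
  S12 <- lv_closed_form_fitness(p, 0.48, 0.51)
  S21 <- lv_closed_form_fitness(p, 0.51, 0.48)
  ex <- second_order_coefficients(lv, 0.5)
  eps <- 0.02; xi1 <- -1; xi2 <- 0.5
  dxi <- xi2 - xi1
  cls <- classify_outcome(S12, S21,
                          list(drive1 = 0,
                               quad = eps^2 * dxi * (ex$C22 + ex$C11) * dxi,
                               mixed = eps^2 * (xi2 + xi1) *
                                 (ex$C22 + ex$C21) * dxi,
                               eps = eps))
  expect_identical(cls$outcome, "coexistence")
  rep_ <- compare_to_averaged(lv, 0.5, xi1, xi2, eps_grid = c(eps),
                              delta = 0.1,
                              config_template = sim_config(t_end = 1,
                                                           dt = 0.01,
                                                           seed = 2L),
                              classification = cls, p0 = 0.25,
                              init_fast = list(N = 0.5, e1 = numeric(0),
                                               theta = 0))
  expect_true(all(rep_$pass))
})
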
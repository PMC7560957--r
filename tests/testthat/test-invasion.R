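test_that("selective neutrality holds for every fixture and method", {
  # closed forms are exactly neutral
  p_lv <- example_params("lotka_volterra")
  p_s <- example_params("sirs")
  expect_identical(chemostat_closed_form_fitness(example_params("chemostat"),
                                                 fig4_x, fig4_x), 0)
  expect_equal(lv_closed_form_fitness(p_lv, 0.48, 0.48), 0)
  expect_equal(sirs_small_noise_fitness(p_s, 8.7, 8.7), 0)
  # ergodic neutrality within 3 SE on the simulated chemostat resident
  f <- invasion_fitness(chemostat_model(), chemostat_resident_traj(), fig4_x,
                        method = "ergodic")
  expect_lt(abs(f$value), 3 * f$se)
  # ergodic neutrality on the structured SIRS resident
  rc <- sirs_resident_check()
  fs <- invasion_fitness(sirs_model(), rc$trajectory, 8.7, method = "ergodic")
  expect_lt(abs(fs$value), 3 * fs$se)
  # periodic neutrality on the prey-predator limit cycle
  fp <- invasion_fitness(pp_model(), pp_attractor(0.27), 0.27,
                         method = "periodic")
  expect_lt(abs(fp$value), 1e-6)
})

test_that("chemostat ergodic fitness agrees with the closed form", {
  m <- chemostat_model()
  f <- invasion_fitness(m, chemostat_resident_traj(), fig4_y,
                        method = "ergodic")
  expect_lt(abs(f$value - 0.0161516), 3 * f$se)
  expect_gt(f$se, 0)
})

test_that("the chemostat selection gradient matches its analytic value", {
  g <- selection_gradient(chemostat_model(), fig4_x, method = "closed_form")
  # (gamma E[R], beta E[R], -1) with E[R] = 0.121875
  expect_equal(g, c(0.0975, 0.24375, -1), tolerance = 1e-6)
})

test_that("a linear fitness surface yields its gradient exactly", {
  g0 <- c(0.7, -1.3)
  am <- analytic_model(function(a, b) sum(g0 * (b - a)), strategy_dim = 2L)
  g <- selection_gradient(am, c(0.1, 0.2))
  expect_equal(g, g0, tolerance = 1e-9)
})

test_that("curvature extraction recovers a quadratic surface exactly", {
  c11 <- 0.5; c22 <- 1.5; c21 <- -(c11 + c22) / 2   # conservation-consistent
  am <- analytic_model(function(a, b) c22 * b^2 + c11 * a^2 + 2 * c21 * a * b)
  ex <- second_order_coefficients(am, 0.2)
  expect_equal(as.numeric(ex$C11), c11, tolerance = 1e-6)
  expect_equal(as.numeric(ex$C22), c22, tolerance = 1e-6)
  expect_equal(as.numeric(ex$C21), c21, tolerance = 1e-6)
  expect_lt(ex$conservation_defect, 1e-8)
})

test_that("the conservation law C11+C22+C12+C21 = 0 holds on all closed forms", {
  fixtures <- list(
    list(chemostat_model(), fig4_x),
    list(lotka_volterra_model(), 0.3),
    list(lotka_volterra_model(params = list(cvec = c(1, -2, 0, -2, 1, 0.5))),
         0.5),
    list(sirs_model(), 8.7))
  for (fx in fixtures) {
    ex <- second_order_coefficients(fx[[1]], fx[[2]], method = "closed_form")
    scale <- max(abs(ex$C11), abs(ex$C22), abs(ex$C21), 1e-3)
    expect_lt(ex$conservation_defect, 1e-4 * scale + 1e-6)
  }
})

test_that("competition-kernel singular strategies sit on the substitution line", {
  # with the second kernel parameter set, both singular strategies satisfy
  # C11 + C22 = 0 with C11, C22 individually nonzero
  lvb <- lotka_volterra_model(params = list(cvec = c(1, -2, 0, -2, 1, 0.5)))
  fs <- find_singular_strategy(lvb, c(-1.2, 1.2))
  roots <- sort(unlist(fs$roots))
  expect_length(roots, 2L)
  expect_equal(roots, c(-0.5, 0.5), tolerance = 1e-4)
  for (r in roots) {
    ex <- second_order_coefficients(lvb, r)
    expect_lt(abs(as.numeric(ex$C11 + ex$C22)), 1e-5)
    expect_gt(abs(as.numeric(ex$C11)), 0.1)
    expect_gt(abs(as.numeric(ex$C22)), 0.1)
    # the gradient vanishes at a singular strategy
    expect_lt(abs(selection_gradient(lvb, r)), 1e-4)
  }
})

test_that("the second-order expansion has third-order error in the separation", {
  m <- chemostat_model()
  ex <- second_order_coefficients(m, fig4_x, h = 1e-4)
  xi1 <- c(-1, 5, -0.5); xi2 <- c(1, -2, 0.3)
  err <- vapply(c(0.02, 0.01, 0.005), function(eps) {
    pred <- expand_fitness_second_order(ex, xi1, xi2, eps)
    tru <- c(m$closed_form_fitness(fig4_x + eps * xi1, fig4_x + eps * xi2),
             m$closed_form_fitness(fig4_x + eps * xi2, fig4_x + eps * xi1))
    max(abs(pred - tru))
  }, 0)
  ratios <- err[-3] / err[-1]
  expect_true(all(ratios > 6 & ratios < 10))
  # a quadratic surface is reproduced exactly
  am <- analytic_model(function(a, b) 1.5 * b^2 + 0.5 * a^2 - 2 * a * b)
  exq <- second_order_coefficients(am, 0)
  pr <- expand_fitness_second_order(exq, -1, 0.5, 0.1)
  expect_equal(unname(pr[1]), am$closed_form_fitness(-0.1, 0.05),
               tolerance = 1e-6)
  # identical strategies predict zero both ways (to rounding)
  expect_equal(unname(expand_fitness_second_order(exq, 0.3, 0.3, 0.1)),
               c(0, 0), tolerance = 1e-14)
})

test_that("pairwise fitnesses are antisymmetric to first order in the separation", {
  m <- chemostat_model()
  xi1 <- c(-1, 5, -0.5); xi2 <- c(1, -2, 0.3)
  sums <- vapply(c(0.02, 0.01, 0.005), function(eps) {
    m$closed_form_fitness(fig4_x + eps * xi1, fig4_x + eps * xi2) +
      m$closed_form_fitness(fig4_x + eps * xi2, fig4_x + eps * xi1)
  }, 0)
  ratios <- sums[-3] / sums[-1]
  expect_true(all(ratios > 3 & ratios < 5))   # O(eps^2) residual
})

test_that("singular-strategy search finds roots, reports misses and respects sign changes", {
  # gradient x - 0.4 has the root 0.4
  am <- analytic_model(function(a, b) (b - a) * (a - 0.4))
  fs <- find_singular_strategy(am, c(0, 1))
  expect_equal(unlist(fs$roots), 0.4, tolerance = 1e-6)
  # chemostat: the death-rate component of the gradient is identically -1
  fs2 <- find_singular_strategy(chemostat_model(),
                                matrix(c(1, 0.5, 0.05, 3, 1, 0.2), 2,
                                       byrow = TRUE))
  expect_length(fs2$roots, 0L)
  expect_match(fs2$diagnostics, "residual")
})

test_that("the prey-predator gradient changes sign between the mutual-invasion pair", {
  s <- fluctinvade:::fitness_surface(pp_model(), "periodic")
  g_lo <- fluctinvade:::selection_gradient_(s, 0.3764, 0.004)
  g_hi <- fluctinvade:::selection_gradient_(s, 0.4314, 0.004)
  expect_gt(g_lo, 0)
  expect_lt(g_hi, 0)
})

test_that("common random numbers shrink the gradient-estimate variance", {
  m <- chemostat_model()
  h <- fluctinvade:::default_h(fig4_x)
  seeds <- 1:5
  crn <- vapply(seeds, function(s) {
    cfg <- sim_config(t_end = 150, dt = 0.01, seed = s, record_stride = 5L)
    selection_gradient(m, fig4_x, method = "ergodic", config = cfg)[2]
  }, 0)
  indep <- vapply(seeds, function(s) {
    xp <- fig4_x; xp[2] <- xp[2] + h
    xm <- fig4_x; xm[2] <- xm[2] - h
    cp <- sim_config(t_end = 150, dt = 0.01, seed = 1000L + s,
                     record_stride = 5L)
    cm <- sim_config(t_end = 150, dt = 0.01, seed = 2000L + s,
                     record_stride = 5L)
    (invasion_fitness(m, fig4_x, xp, method = "ergodic", config = cp)$value -
       invasion_fitness(m, fig4_x, xm, method = "ergodic",
                        config = cm)$value) / (2 * h)
  }, 0)
  expect_gt(stats::var(indep) / stats::var(crn), 10)
})

test_that("fitness methods validate their inputs", {
  expect_error(invasion_fitness(prey_predator_model(), fig4_x, fig4_y,
                                method = "closed_form"),
               "closed-form")
  # periodic method on an equilibrium resident is a method error
  expect_error(invasion_fitness(pp_model(), 1.0, 0.9, method = "periodic"),
               "no periodic attractor")
})
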
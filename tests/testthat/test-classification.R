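test_that("both averaged systems vanish exactly at the boundary frequencies", {
  g <- c(0.3, -0.2)
  expect_identical(averaged_rhs_order1(0, g, c(1, 0), c(0, 1)), 0)
  expect_identical(averaged_rhs_order1(1, g, c(1, 0), c(0, 1)), 0)
  ex <- second_order_coefficients(
    analytic_model(function(a, b) 1.5 * b^2 + 0.5 * a^2 - 2 * a * b), 0)
  expect_identical(averaged_rhs_order2(0, ex, -1, 1), 0)
  expect_identical(averaged_rhs_order2(1, ex, -1, 1), 0)
  # plain arithmetic: P(1-P) * drive at P = 0.5
  expect_equal(averaged_rhs_order1(0.5, 0.2, 0, 1), 0.05)
})

test_that("the order-1 averaged flow is the logistic closed form", {
  g <- 0.8; xi1 <- -0.5; xi2 <- 1
  path <- solve_averaged_P("order1", g, xi1, xi2, p0 = 0.2, t_end = 10,
                           n_out = 101L)
  # independent numeric solve as oracle
  num <- deSolve::lsoda(0.2, path$t, function(t, y, p)
    list(averaged_rhs_order1(y, g, xi1, xi2)), NULL,
    rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(path$P - num[, 2])), 1e-8)
  expect_true(all(diff(path$P) > 0))   # monotone toward 1 for positive drive
  expect_identical(unique(solve_averaged_P("order1", g, xi1, xi2, 0, 5)$P), 0)
})

test_that("symmetric deviations put the order-2 interior equilibrium at one half", {
  ex <- second_order_coefficients(
    analytic_model(function(a, b) 1.5 * b^2 + 0.5 * a^2 - 2 * a * b), 0)
  # xi1 = -xi2 kills the mixed term; interior root of the cubic is 1/2
  root <- stats::uniroot(function(P)
    averaged_rhs_order2(P, ex, -1, 1) / (P * (1 - P)), c(0.01, 0.99))$root
  expect_equal(root, 0.5, tolerance = 1e-8)
})

test_that("the order-2 interior equilibrium equals S12/(S12+S21)", {
  am <- analytic_model(function(a, b) 0.5 * b^2 + 2 * a^2 - 2.5 * a * b)
  ex <- second_order_coefficients(am, 0)
  xi1 <- 0; xi2 <- 1; eps <- 0.05
  pred <- expand_fitness_second_order(ex, xi1, xi2, eps)
  p_star <- unname(pred[1] / (pred[1] + pred[2]))
  root <- stats::uniroot(function(P)
    averaged_rhs_order2(P, ex, xi1, xi2) / (P * (1 - P)), c(0.01, 0.99))$root
  expect_equal(root, p_star, tolerance = 1e-6)
  # and the numeric solve converges there from any interior start
  for (p0 in c(0.1, 0.7)) {
    path <- solve_averaged_P("order2", ex, xi1, xi2, p0, t_end = 80)
    expect_equal(tail(path$P, 1), p_star, tolerance = 1e-4)
  }
})

test_that("classification dispatches the three theorem regimes", {
  # resolved first-order drive: substitution by fitness signs
  c1 <- classify_outcome(0.01, -0.008, list(drive1 = 0.01, quad = 0,
                                            mixed = 0))
  expect_identical(c1$outcome, "substitution_invader_wins")
  expect_identical(c1$p_star, 1)
  expect_identical(c1$regime, "order1")
  c1b <- classify_outcome(-0.01, 0.008, list(drive1 = 0.01, quad = 0,
                                             mixed = 0))
  expect_identical(c1b$outcome, "substitution_resident_wins")
  # published mutual-invasion pair: coexistence at the fitness-ratio limit
  c2 <- classify_outcome(0.00454545, 0.00346302,
                         list(drive1 = 0, quad = 0.1, mixed = 0.01))
  expect_identical(c2$outcome, "coexistence")
  expect_equal(c2$p_star, 0.567580, tolerance = 1e-6)
  # mutual exclusion: bistable boundary equilibria
  c3 <- classify_outcome(-0.004, -0.006, list(drive1 = 0, quad = 0.1,
                                              mixed = 0))
  expect_identical(c3$outcome, "mutual_exclusion")
  expect_identical(c3$p_star, c(0, 1))
  # special substitution regime rejects mutual-invasion sign patterns
  c4 <- classify_outcome(0.004, 0.006, list(drive1 = 0, quad = 0,
                                            mixed = 0.05))
  expect_identical(c4$outcome, "undetermined")
  # degenerate: everything under tolerance
  c5 <- classify_outcome(0.004, -0.004, list(drive1 = 0, quad = 0, mixed = 0))
  expect_identical(c5$regime, "degenerate")
  # neutrality dead band
  c6 <- classify_outcome(1e-12, -0.004, list(drive1 = 0.01, quad = 0,
                                             mixed = 0))
  expect_identical(c6$outcome, "undetermined")
})

test_that("classification is invariant under relabeling the pair", {
  set.seed(1)
  for (rep in 1:20) {
    S12 <- stats::runif(1, -0.01, 0.01)
    S21 <- stats::runif(1, -0.01, 0.01)
    stats_ <- list(drive1 = sample(c(0, 0.01), 1), quad = 0.1, mixed = 0.003)
    a <- classify_outcome(S12, S21, stats_)
    # swapping the strategies swaps the fitnesses and flips the drive sign
    stats_sw <- list(drive1 = -stats_$drive1, quad = stats_$quad,
                     mixed = -stats_$mixed)
    b <- classify_outcome(S21, S12, stats_sw)
    swap_map <- c(substitution_invader_wins = "substitution_resident_wins",
                  substitution_resident_wins = "substitution_invader_wins",
                  coexistence = "coexistence",
                  mutual_exclusion = "mutual_exclusion",
                  undetermined = "undetermined")
    expect_identical(unname(swap_map[a$outcome]), b$outcome)
    if (a$outcome == "coexistence")
      expect_equal(b$p_star, 1 - a$p_star, tolerance = 1e-12)
  }
})

test_that("the chemostat never classifies as coexistence", {
  # whenever S_x(y) > 0 the reverse fitness is negative, so substitution is
  # the unique outcome for any pair
  m <- chemostat_model()
  set.seed(7)
  for (rep in 1:25) {
    x1 <- fig4_x * stats::runif(3, 0.9, 1.1)
    x2 <- x1 + stats::runif(3, -0.02, 0.02)
    cls <- try(classify_pair(m, x1, x2), silent = TRUE)
    if (!inherits(cls, "try-error"))
      expect_false(cls$outcome == "coexistence")
    S12 <- m$closed_form_fitness(x1, x2)
    S21 <- m$closed_form_fitness(x2, x1)
    if (S12 > 1e-12) expect_lt(S21, 0)
  }
})
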
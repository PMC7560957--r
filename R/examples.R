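# Registry of fully parameterized example models: a stochastic chemostat, a
# stochastic Lotka-Volterra competition model, a structured SIRS epidemic
# model, a deterministic prey-predator model with non-equilibrium resident
# dynamics, and an "analytic" fixture exposing a user-chosen two-argument
# fitness surface directly. Defaults are the published parameter sets for
# these models and double as the package's synthetic test-bed.

#' Default parameters of the example models
#'
#' @param name one of \code{"chemostat"}, \code{"lotka_volterra"},
#'   \code{"sirs"}, \code{"prey_predator"}.
#' @return named list of defaults.
#' @export
example_params <- function(name) {
  switch(match.arg(name, c("chemostat", "lotka_volterra", "sirs",
                           "prey_predator")),
    chemostat = list(D = 0.1, rho1 = 1, rho2 = 0.5, a = 1, b = 1),
    lotka_volterra = list(d1 = 1, d2 = 0.5, rho1 = 1, rho2 = 0.8,
                          a = 1, b = 1,
                          cvec = c(1, -11, 11, -4, 1, 0.5)),
    sirs = list(Lambda = 3, delta = 0.2, a = 2, b = 1,
                rho1 = 0.1, rho2 = 0, rho3 = 0, rho4 = 0,
                alpha = function(x) x,
                beta = function(x) 5.65 + 2 * x^2 / (6 + 0.1 * x^2),
                gamma = function(x) 0.3,
                zeta = function(x) exp(-0.5 * x^2)),
    prey_predator = list(a = 2, c = 2, mu = 1, delta = 1, h = 1, T = 1,
                         gamma = 3, lambda = 0.6, sigma = 0.7,
                         alpha = 0, beta = 6))
}

merge_params <- function(name, params) {
  p <- example_params(name)
  for (nm in names(params)) p[[nm]] <- params[[nm]]
  p
}

#' Chemostat invasion fitness (closed form)
#'
#' For resident \eqn{x = (\beta, \gamma, \delta)} the long-run mean resource
#' level is \eqn{E[R] = (\delta + D)/(\gamma\beta)} (neutrality of the
#' resident), so a rare mutant \eqn{y = (\beta', \gamma', \delta')} has
#' fitness \eqn{\gamma'\beta' (\delta+D)/(\gamma\beta) - \delta' - D}.
#'
#' @param params chemostat parameter list (see [example_params()]).
#' @param x,y resident and mutant strategies \code{c(beta, gamma, delta)}.
#' @return invasion fitness (1/time).
#' @export
chemostat_closed_form_fitness <- function(params, x, y) {
  if (x[1] * x[2] <= 0)
    stop("resident uptake x gamma*beta must be positive")
  ER <- (x[3] + params$D) / (x[2] * x[1])
  y[2] * y[1] * ER - y[3] - params$D
}

#' Chemostat example model
#'
#' Bacteria with strategy \eqn{x = (\beta, \gamma, \delta)} (uptake,
#' conversion efficiency, death rate) consuming a nutrient \eqn{R} whose
#' input concentration switches randomly between \eqn{\rho_1 \pm \rho_2}
#' through the bounded map \eqn{2\theta/(1+\theta^2)} of an
#' Ornstein-Uhlenbeck driver.
#'
#' @param params overrides of [example_params()]\code{("chemostat")}.
#' @param stochastic set \code{FALSE} for the deterministic skeleton
#'   (\code{b = 0}, constant input \eqn{\rho_1}).
#' @return an \code{unstructured_model}.
#' @export
chemostat_model <- function(params = list(), stochastic = TRUE) {
  p <- merge_params("chemostat", params)
  D <- p$D; rho1 <- p$rho1; rho2 <- p$rho2
  r_in <- function(theta) rho1 - rho2 * 2 * theta / (1 + theta^2)
  drv <- if (stochastic) ou_driver(p$a, p$b) else ou_driver(p$a, 0)
  unstructured_model(
    growth = function(x, e, theta) x[2] * x[1] * e$e1 - x[3] - D,
    env_ode_intrinsic = function(e, theta) D * (r_in(theta[1]) - e$e1),
    env_ode_impact = function(x, e, theta) -x[1] * e$e1,
    driver = drv,
    dim_e1 = 1L, dim_e2 = 0L, strategy_dim = 3L,
    closed_form_fitness = function(x, y) chemostat_closed_form_fitness(p, x, y),
    model_id = if (stochastic) "chemostat" else "chemostat_deterministic",
    state_box = list(x = matrix(c(0.5, 0.2, 0.01, 3, 1, 0.3), nrow = 2,
                                byrow = TRUE),
                     n = c(0, 5), e1 = c(0.01, 1.5), theta = c(-3, 3)))
}

lv_alpha <- function(cvec, xi, xj) {
  (1 - (xj - xi) * (cvec[1] + cvec[2] * xi^2 + cvec[3] * xi * xj +
                      cvec[4] * xj^2) * exp(cvec[5] * xj^2)) *
    exp(cvec[6] * (xi^2 - xj^2))
}

#' Lotka-Volterra competition fitness (closed form)
#'
#' \eqn{S_x(y) = r(y)\,\kappa\,(1 - \alpha(x, y) K(x)/K(y))} with
#' \eqn{r(x) = e^{-d_1 x^2}}, \eqn{K(x) = e^{-d_2 x^2}} and the published
#' competition kernel \eqn{\alpha}. The prefactor \eqn{\kappa} is the mean
#' growth-rate multiplier induced by the log-normal driver: mode
#' \code{"ou_exact"} uses the exact Ornstein-Uhlenbeck moment
#' \eqn{E[e^{\rho_1\theta}] = e^{\rho_1^2 b^2/(4a)}} (this reproduces the
#' published pairwise fitness values); mode \code{"sigma_eq_b"} uses
#' \eqn{e^{\rho_1^2 b^2/(2a)}}. The prefactor is positive, so it never
#' affects signs or classifications.
#'
#' @param params parameter list (see [example_params()]).
#' @param x,y resident and mutant (scalars).
#' @param prefactor_mode \code{"ou_exact"} (default) or
#'   \code{"sigma_eq_b"}.
#' @return invasion fitness (1/time).
#' @export
lv_closed_form_fitness <- function(params, x, y,
                                   prefactor_mode = c("ou_exact",
                                                      "sigma_eq_b")) {
  prefactor_mode <- match.arg(prefactor_mode)
  p <- params
  r <- function(z) exp(-p$d1 * z^2)
  K <- function(z) exp(-p$d2 * z^2)
  pref <- switch(prefactor_mode,
                 ou_exact = exp(p$rho1^2 * p$b^2 / (4 * p$a)),
                 sigma_eq_b = exp(p$rho1^2 * p$b^2 / (2 * p$a)))
  r(y) * pref * (1 - lv_alpha(p$cvec, x, y) * K(x) / K(y))
}

#' Lotka-Volterra competition example model
#'
#' Scalar strategies with Gaussian-in-trait growth rate and carrying
#' capacity, both modulated log-normally by a shared Ornstein-Uhlenbeck
#' driver, competing through the published non-symmetric kernel. The
#' function-valued environment of the general theory is represented
#' finite-dimensionally: the implicit environment component carries the raw
#' population sizes of the \code{strategies} present, and the pairwise
#' interaction is evaluated inside the growth rate.
#'
#' @param strategies list (or vector) of the strategies whose populations are
#'   simulated; mutant fitness along a trajectory may use any other strategy.
#' @param params overrides of [example_params()]\code{("lotka_volterra")};
#'   element \code{cvec} is \eqn{(c_0,\dots,c_5)}.
#' @param prefactor_mode passed to [lv_closed_form_fitness()].
#' @return an \code{unstructured_model}.
#' @export
lotka_volterra_model <- function(strategies = list(0.5), params = list(),
                                 prefactor_mode = "ou_exact") {
  p <- merge_params("lotka_volterra", params)
  if (!is.list(strategies)) strategies <- as.list(strategies)
  sv <- vapply(strategies, function(s) s[1], 0)
  k <- length(sv)
  r <- function(z) exp(-p$d1 * z^2)
  K <- function(z) exp(-p$d2 * z^2)
  unstructured_model(
    growth = function(x, e, theta) {
      inter <- sum(lv_alpha(p$cvec, sv, x[1]) * e$e2)
      r(x[1]) * exp(p$rho1 * theta[1]) *
        (1 - inter / (K(x[1]) * exp(p$rho2 * theta[1])))
    },
    env_implicit_intrinsic = function(e, theta) numeric(k),
    env_implicit_impact = function(x, e, theta) {
      as.numeric(abs(sv - x[1]) < 1e-12)   # indicator of the matching column
    },
    driver = ou_driver(p$a, p$b),
    dim_e1 = 0L, dim_e2 = k, strategy_dim = 1L,
    closed_form_fitness = function(x, y)
      lv_closed_form_fitness(p, x[1], y[1], prefactor_mode),
    model_id = "lotka_volterra",
    state_box = list(x = c(-1.5, 1.5), n = c(0, 3),
                     e2 = matrix(c(rep(0, k), rep(3, k)), nrow = 2,
                                 byrow = TRUE),
                     theta = c(-3, 3)))
}

sirs_rates <- function(p, x, theta) {
  list(beta  = p$beta(x)  * exp(p$rho1 * theta),
       gamma = p$gamma(x) * exp(p$rho2 * theta),
       alpha = p$alpha(x) * exp(p$rho3 * theta),
       zeta  = p$zeta(x)  * exp(p$rho4 * theta))
}

#' Structured SIRS example model
#'
#' Viral strains \eqn{x} structured into infected and recovered classes
#' \eqn{n_i = (I_i, R_i)}; the environment is \eqn{e = (S, M)} with the
#' susceptible pool \eqn{S} ODE-driven and the total population
#' \eqn{M = S + \sum_j (I_j + R_j)} implicit (explicit one-pass). The
#' transmission rate fluctuates log-normally with an Ornstein-Uhlenbeck
#' driver; recovery, virulence and immunity-loss scaling exponents default
#' to zero.
#'
#' @param params overrides of [example_params()]\code{("sirs")}.
#' @return a \code{structured_model} with 2 classes.
#' @export
sirs_model <- function(params = list()) {
  p <- merge_params("sirs", params)
  Lam <- p$Lambda; dlt <- p$delta
  structured_model(
    transition_matrix = function(x, e, theta) {
      rt <- sirs_rates(p, x[1], theta[1])
      S <- e$e1[1]; M <- e$e2[1]
      matrix(c(rt$beta * S / M - rt$gamma - rt$alpha - dlt * M, 0,
               rt$gamma, -rt$zeta - dlt * M),
             2L, 2L, byrow = TRUE)
    },
    num_classes = 2L,
    env_ode_intrinsic = function(e, theta) (Lam - dlt * e$e1[1]) * e$e2[1],
    env_ode_impact = function(x, e, theta) {
      rt <- sirs_rates(p, x[1], theta[1])
      c(-rt$beta * e$e1[1] / e$e2[1], rt$zeta)
    },
    env_implicit_intrinsic = function(e, theta) e$e1[1],
    env_implicit_impact = function(x, e, theta) c(1, 1),
    driver = ou_driver(p$a, p$b),
    dim_e1 = 1L, dim_e2 = 1L, strategy_dim = 1L,
    closed_form_fitness = function(x, y) sirs_small_noise_fitness(p, x[1], y[1]),
    model_id = "sirs",
    state_box = list(x = c(4, 10), n = c(0.01, 15), e1 = c(0.1, 15),
                     e2 = c(0.2, 15), theta = c(-3, 3)))
}

sirs_endemic_equilibrium <- function(p, x) {
  b <- p$beta(x); g <- p$gamma(x); al <- p$alpha(x); z <- p$zeta(x)
  Lam <- p$Lambda; dlt <- p$delta
  phi <- function(M)
    (g + al + dlt * M) / b + (Lam - dlt * M) / al +
      g * (Lam - dlt * M) / (al * (z + dlt * M)) - 1
  hi <- Lam / dlt * (1 - 1e-12)
  if (phi(1e-9) * phi(hi) > 0)
    stop("no endemic equilibrium: the resident cannot establish ",
         "(establishment condition E[beta - gamma - alpha - Lambda] > 0 fails)")
  M <- stats::uniroot(phi, c(1e-9, hi), tol = 1e-14)$root
  S <- M * (g + al + dlt * M) / b
  I <- M * (Lam - dlt * M) / al
  R <- g * I / (z + dlt * M)
  c(S = S, I = I, R = R, M = M)
}

#' SIRS small-noise invasion fitness
#'
#' Small-noise approximation around the deterministic endemic equilibrium of
#' the resident: \eqn{S_x(y) = (\beta(y)-\beta(x))(\hat S/\hat M +
#' \tfrac12 g \cdot \mathrm{Cov}) - (\alpha(y)-\alpha(x))} (recovery is
#' strategy-independent at the defaults), where \eqn{g} is the Hessian of
#' \eqn{e^{\rho_1\theta} S/M} in \eqn{(S, M, \theta)} at the equilibrium and
#' \eqn{\mathrm{Cov}} is the stationary covariance of \eqn{(S, M, \theta)}
#' from the linearized resident dynamics (continuous Lyapunov equation,
#' solved by the Kronecker identity). The approximation carries an
#' \eqn{O(\rho_1^2)} error of the same order as the covariance term itself.
#'
#' @param params SIRS parameter list.
#' @param x,y resident and mutant strategies (scalars).
#' @return invasion fitness (1/time).
#' @export
sirs_small_noise_fitness <- function(params, x, y) {
  p <- params
  # establishment check (with exact OU moments E[e^{rho theta}])
  mom <- function(rho) exp(rho^2 * p$b^2 / (4 * p$a))
  est <- p$beta(x) * mom(p$rho1) - p$gamma(x) * mom(p$rho2) -
    p$alpha(x) * mom(p$rho3) - p$Lambda
  if (est <= 0)
    stop("establishment condition E[beta - gamma - alpha - Lambda] > 0 fails")
  eq <- sirs_endemic_equilibrium(p, x)
  S <- eq[["S"]]; M <- eq[["M"]]
  rhs <- function(z, th) {
    Sv <- z[1]; Iv <- z[2]; Rv <- z[3]
    Mv <- Sv + Iv + Rv
    rt <- sirs_rates(p, x, th)
    c(p$Lambda * Mv - rt$beta * Iv / Mv * Sv - p$delta * Mv * Sv + rt$zeta * Rv,
      rt$beta * Sv / Mv * Iv - rt$gamma * Iv - rt$alpha * Iv - p$delta * Mv * Iv,
      rt$gamma * Iv - rt$zeta * Rv - p$delta * Mv * Rv)
  }
  z0 <- eq[c("S", "I", "R")]
  h <- 1e-6
  A <- matrix(0, 4, 4)
  for (j in 1:3) {
    zp <- z0; zm <- z0
    zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
    A[1:3, j] <- (rhs(zp, 0) - rhs(zm, 0)) / (2 * h)
  }
  A[1:3, 4] <- (rhs(z0, h) - rhs(z0, -h)) / (2 * h)
  A[4, 4] <- -p$a
  Q <- matrix(0, 4, 4); Q[4, 4] <- p$b^2
  Sig <- lyapunov_solve(A, Q)
  Tm <- rbind(c(1, 0, 0, 0), c(1, 1, 1, 0), c(0, 0, 0, 1))  # (S, M, theta)
  C3 <- Tm %*% Sig %*% t(Tm)
  r1 <- p$rho1
  g <- matrix(0, 3, 3)
  g[1, 2] <- g[2, 1] <- -1 / M^2
  g[1, 3] <- g[3, 1] <- r1 / M
  g[2, 2] <- 2 * S / M^3
  g[2, 3] <- g[3, 2] <- -r1 * S / M^2
  g[3, 3] <- r1^2 * S / M
  corr <- 0.5 * sum(g * C3)
  (p$beta(y) - p$beta(x)) * (S / M + corr) -
    (p$gamma(y) - p$gamma(x)) - (p$alpha(y) - p$alpha(x))
}

# Stationary covariance of dz = A z dt + B dW: solves A S + S A' + Q = 0
# (Q = B B') via vec(S) = -(I (x) A + A (x) I)^{-1} vec(Q).
lyapunov_solve <- function(A, Q) {
  d <- nrow(A)
  Id <- diag(d)
  L <- kronecker(Id, A) + kronecker(A, Id)
  matrix(solve(L, -as.numeric(Q)), d, d)
}

#' Prey-predator example model (evolution of prey timidity)
#'
#' Deterministic model where prey with timidity \eqn{x} forage a fraction
#' \eqn{1/(1 + x p)} of the time under predator density \eqn{p}; the
#' environment is \eqn{e = (p, \sum_j n_j^F)} with the foraging-prey total
#' implicit (explicit in \eqn{e_1}). The monomorphic resident has a stable
#' equilibrium for large \eqn{x} that loses stability through a supercritical
#' Hopf bifurcation as \eqn{x} decreases, giving periodic resident
#' environments.
#'
#' @param params overrides of [example_params()]\code{("prey_predator")}.
#' @return an \code{unstructured_model} (no driver).
#' @export
prey_predator_model <- function(params = list()) {
  p <- merge_params("prey_predator", params)
  a <- p$a; cc <- p$c; mu <- p$mu; dlt <- p$delta; h <- p$h; TT <- p$T
  gam <- p$gamma; lam <- p$lambda; sig <- p$sigma; alp <- p$alpha; bet <- p$beta
  unstructured_model(
    growth = function(x, e, theta) {
      (a - cc * e$e2[1]) / (1 + x[1] * e$e1[1]) - mu -
        bet * e$e1[1] / ((1 + x[1] * e$e1[1]) * (1 + bet * h * e$e2[1]))
    },
    env_ode_intrinsic = function(e, theta) -dlt * e$e1[1],
    env_ode_impact = function(x, e, theta) {
      gam * bet * e$e1[1] /
        ((1 + x[1] * e$e1[1]) * TT *
           (sig * (1 + bet * h * e$e2[1]) + (1 - lam) * alp * e$e1[1]))
    },
    env_implicit_intrinsic = function(e, theta) 0,
    env_implicit_impact = function(x, e, theta) 1 / (1 + x[1] * e$e1[1]),
    driver = no_driver(),
    dim_e1 = 1L, dim_e2 = 1L, strategy_dim = 1L,
    model_id = "prey_predator",
    state_box = list(x = c(0.1, 2), n = c(0, 2), e1 = c(0.01, 2),
                     e2 = c(0, 1.5)))
}

#' Analytic fitness fixture
#'
#' Wraps a user-chosen two-argument fitness surface \eqn{s(x, y)} with
#' \eqn{s(x, x) = 0} directly as a model's closed-form fitness, bypassing
#' simulation. This is the unit-test workhorse for gradient and curvature
#' extraction and for outcome classification.
#'
#' @param s_fun function \code{(x, y) -> numeric(1)}.
#' @param strategy_dim trait dimension.
#' @return an \code{unstructured_model} with only a closed-form fitness.
#' @export
analytic_model <- function(s_fun, strategy_dim = 1L) {
  unstructured_model(growth = NULL, driver = no_driver(),
                     dim_e1 = 0L, dim_e2 = 0L, strategy_dim = strategy_dim,
                     closed_form_fitness = s_fun, model_id = "analytic",
                     state_box = list(x = c(-1, 1), n = c(0, 1)))
}

#' Build a registered example model by name
#'
#' @param name fixture name: \code{"chemostat"}, \code{"lotka_volterra"},
#'   \code{"sirs"}, \code{"prey_predator"}.
#' @param params parameter overrides merged over the defaults.
#' @param ... passed to the specific constructor (e.g. \code{strategies} for
#'   the Lotka-Volterra model, \code{stochastic} for the chemostat).
#' @return a \code{fluct_model}.
#' @export
make_example_model <- function(name, params = list(), ...) {
  switch(match.arg(name, c("chemostat", "lotka_volterra", "sirs",
                           "prey_predator")),
         chemostat = chemostat_model(params, ...),
         lotka_volterra = lotka_volterra_model(params = params, ...),
         sirs = sirs_model(params),
         prey_predator = prey_predator_model(params))
}
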
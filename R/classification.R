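# Averaged slow dynamics of the invader's relative frequency P and the
# classification of invasion outcomes from invasion criteria alone. On the
# slow clock t1 = eps*t the averaged dynamics is logistic in P, driven by the
# selection gradient; when that drive vanishes, on the slower clock
# t2 = eps^2*t the curvature matrices take over and up to three equilibria
# appear, whose stabilities are fully determined by the signs of the pairwise
# invasion fitnesses.

#' Right-hand side of the first-order averaged system
#'
#' \eqn{\dot P = P(1-P)\, g^\top (\xi_2 - \xi_1)} on the \eqn{\epsilon t}
#' clock; the two equilibria 0 and 1 exchange stability with the sign of the
#' drive.
#'
#' @param P relative frequency in \code{[0, 1]} (vectorized).
#' @param gradient selection gradient at the reference strategy.
#' @param xi1,xi2 deviation directions.
#' @return \eqn{\dot P}.
#' @export
averaged_rhs_order1 <- function(P, gradient, xi1, xi2) {
  P * (1 - P) * sum(gradient * (xi2 - xi1))
}

#' Right-hand side of the second-order averaged system
#'
#' \eqn{\dot P = P(1-P)\big[(\xi_2+\xi_1)^\top (C_{22}+C_{21})(\xi_2-\xi_1) +
#' (\tfrac12 - P)(\xi_2-\xi_1)^\top (C_{22}+C_{11})(\xi_2-\xi_1)\big]} on the
#' \eqn{\epsilon^2 t} clock.
#'
#' @param P relative frequency (vectorized).
#' @param expansion a \code{local_expansion}.
#' @param xi1,xi2 deviation directions.
#' @return \eqn{\dot P}.
#' @export
averaged_rhs_order2 <- function(P, expansion, xi1, xi2) {
  dxi <- xi2 - xi1; sxi <- xi2 + xi1
  mixed <- as.numeric(sxi %*% (expansion$C22 + expansion$C21) %*% dxi)
  quad <- as.numeric(dxi %*% (expansion$C22 + expansion$C11) %*% dxi)
  P * (1 - P) * (mixed + (0.5 - P) * quad)
}

#' Interior equilibrium of the averaged system from pairwise fitnesses
#' @param S12 fitness of strategy 2 invading 1, \eqn{S_{x_1}(x_2)}.
#' @param S21 fitness of strategy 1 invading 2, \eqn{S_{x_2}(x_1)}.
#' @return \eqn{p^* = S_{12}/(S_{12}+S_{21})}.
#' @export
p_star_formula <- function(S12, S21) S12 / (S12 + S21)

#' Classify the population-dynamical outcome of an invasion event
#'
#' Dispatches on the regime statistics of the local expansion: when the
#' first-order drive \eqn{g^\top\Delta\xi} is resolved, invasion implies
#' substitution and the signs of \eqn{(S_{12}, S_{21})} give the direction;
#' when it vanishes but the quadratic statistic
#' \eqn{\Delta\xi^\top(C_{22}+C_{11})\Delta\xi} is resolved, the four
#' generic outcomes are substitution either way, protected coexistence at
#' \eqn{p^* = S_{12}/(S_{12}+S_{21})}, or mutual exclusion (bistable
#' boundary equilibria); when both vanish but the mixed statistic is
#' resolved, only substitution occurs; when all three are below tolerance
#' the case is degenerate and higher-order terms (out of scope) decide.
#' A fitness within the dead band is reported as undetermined with a
#' neutrality note, since the theorems assume strict inequalities.
#'
#' @param S12,S21 pairwise invasion fitnesses.
#' @param regime_stats list with \code{drive1} (\eqn{g^\top\Delta\xi}),
#'   \code{quad} (\eqn{\Delta\xi^\top(C_{22}+C_{11})\Delta\xi}) and
#'   \code{mixed} (\eqn{(\xi_2+\xi_1)^\top(C_{22}+C_{21})\Delta\xi}).
#' @param tol dead band for all comparisons; default \code{1e-8}, or pass
#'   3x the propagated fitness SE for ergodic estimates.
#' @return an \code{outcome_classification}: list with \code{regime},
#'   \code{outcome}, \code{p_star} (number, or \code{c(0, 1)} for bistable
#'   basins), \code{theorem}, \code{inputs_echo}, \code{notes}.
#' @export
classify_outcome <- function(S12, S21, regime_stats, tol = 1e-8) {
  stopifnot(is.finite(S12), is.finite(S21))
  echo <- list(S12 = S12, S21 = S21, drive1 = regime_stats$drive1,
               quad = regime_stats$quad, mixed = regime_stats$mixed,
               eps = regime_stats$eps %||% 1, tol = tol)
  out <- function(regime, outcome, p_star, theorem, notes = NULL)
    structure(list(regime = regime, outcome = outcome, p_star = p_star,
                   theorem = theorem, inputs_echo = echo, notes = notes),
              class = "outcome_classification")

  if (abs(S12) <= tol || abs(S21) <= tol)
    return(out("neutral", "undetermined", NA_real_, "none",
               "a pairwise fitness lies inside the neutrality dead band"))

  if (abs(regime_stats$drive1) > tol) {
    if (S12 > 0 && S21 < 0)
      return(out("order1", "substitution_invader_wins", 1,
                 "invasion implies substitution (first order)"))
    if (S12 < 0 && S21 > 0)
      return(out("order1", "substitution_resident_wins", 0,
                 "invasion implies substitution (first order)"))
    return(out("order1", "undetermined", NA_real_,
               "invasion implies substitution (first order)",
               "fitness signs inconsistent with the first-order regime"))
  }
  if (abs(regime_stats$quad) > tol) {
    if (S12 > 0 && S21 < 0)
      return(out("order2_generic", "substitution_invader_wins", 1,
                 "classification theorem (i)"))
    if (S12 < 0 && S21 > 0)
      return(out("order2_generic", "substitution_resident_wins", 0,
                 "classification theorem (ii)"))
    if (S12 > 0 && S21 > 0)
      return(out("order2_generic", "coexistence", p_star_formula(S12, S21),
                 "classification theorem (iii)"))
    return(out("order2_generic", "mutual_exclusion", c(0, 1),
               "classification theorem (iv)",
               "bistable: both boundary equilibria stable, basin probabilities sum to 1"))
  }
  if (abs(regime_stats$mixed) > tol) {
    if (S12 > 0 && S21 < 0)
      return(out("order2_special", "substitution_invader_wins", 1,
                 "special invasion-substitution theorem (i)"))
    if (S12 < 0 && S21 > 0)
      return(out("order2_special", "substitution_resident_wins", 0,
                 "special invasion-substitution theorem (ii)"))
    return(out("order2_special", "undetermined", NA_real_,
               "special invasion-substitution theorem",
               "fitness signs inconsistent with the substitution-only regime"))
  }
  out("degenerate", "undetermined", NA_real_, "none",
      "all regime statistics below tolerance; higher-order terms decide")
}

#' @export
print.outcome_classification <- function(x, ...) {
  cat(sprintf("outcome: %s [%s regime; %s]\n", x$outcome, x$regime, x$theorem))
  if (length(x$p_star) == 2L)
    cat("  bistable boundary equilibria {0, 1}\n")
  else if (is.finite(x$p_star))
    cat(sprintf("  predicted limit p* = %.6g\n", x$p_star))
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Classify an invasion event for a concrete strategy pair
#'
#' Convenience wrapper: builds the local expansion at the reference strategy
#' \eqn{x = (x_1 + x_2)/2}, evaluates \eqn{S_{x_1}(x_2)} and
#' \eqn{S_{x_2}(x_1)} with the requested method, and calls
#' [classify_outcome()].
#'
#' @param model a \code{fluct_model}.
#' @param x1,x2 the two strategies.
#' @param method fitness method.
#' @param config a [sim_config()] for ergodic fitness.
#' @param tol dead band; defaults to 3x the fitness SE (ergodic) or 1e-8.
#' @param ... passed to the fitness machinery.
#' @return an \code{outcome_classification}.
#' @export
classify_pair <- function(model, x1, x2, method = "closed_form",
                          config = NULL, tol = NULL, ...) {
  xref <- (x1 + x2) / 2
  eps <- sqrt(sum((x2 - x1)^2)) / 2
  if (eps == 0) stop("x1 and x2 must differ")
  xi1 <- (x1 - xref) / eps; xi2 <- (x2 - xref) / eps
  exp_ <- second_order_coefficients(model, xref, method = method,
                                    config = config, ...)
  f12 <- invasion_fitness(model, x1, x2, method = method, config = config, ...)
  f21 <- invasion_fitness(model, x2, x1, method = method, config = config, ...)
  if (is.null(tol))
    tol <- if (method == "ergodic") 3 * max(f12$se, f21$se) else 1e-8
  dxi <- xi2 - xi1
  stats <- list(drive1 = eps * sum(exp_$gradient * dxi),
                quad = eps^2 * as.numeric(dxi %*% (exp_$C22 + exp_$C11) %*% dxi),
                mixed = eps^2 * as.numeric((xi2 + xi1) %*%
                                             (exp_$C22 + exp_$C21) %*% dxi),
                eps = eps)
  classify_outcome(f12$value, f21$value, stats, tol = tol)
}

#' Solve the averaged slow dynamics of the relative frequency
#'
#' Order-1 regime: the logistic closed form. Order-2 regime: a stiff-safe
#' numerical solve of [averaged_rhs_order2()], clamped to \code{[0, 1]}.
#' Time is measured on the corresponding slow clock.
#'
#' @param regime \code{"order1"} or \code{"order2"}.
#' @param obj the selection gradient (order 1) or a \code{local_expansion}
#'   (order 2).
#' @param xi1,xi2 deviation directions.
#' @param p0 initial relative frequency in \code{[0, 1]}.
#' @param t_end slow-clock horizon.
#' @param n_out number of output points.
#' @return data.frame with columns \code{t}, \code{P}.
#' @export
solve_averaged_P <- function(regime = c("order1", "order2"), obj, xi1, xi2,
                             p0, t_end, n_out = 201L) {
  regime <- match.arg(regime)
  stopifnot(p0 >= 0, p0 <= 1)
  tt <- seq(0, t_end, length.out = n_out)
  if (regime == "order1") {
    r <- sum(obj * (xi2 - xi1))
    P <- if (p0 %in% c(0, 1)) rep(p0, n_out)
    else 1 / (1 + (1 - p0) / p0 * exp(-r * tt))
    return(data.frame(t = tt, P = P))
  }
  rhs <- function(t, y, parms)
    list(averaged_rhs_order2(min(max(y, 0), 1), obj, xi1, xi2))
  sol <- deSolve::lsoda(p0, tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  data.frame(t = tt, P = pmin(pmax(sol[, 2], 0), 1))
}
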
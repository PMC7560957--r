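# Resident diagnostics: ergodic (Birkhoff) averaging along trajectories, the
# non-growing + stochastic-persistence checks that qualify a population as a
# resident, and attractor characterization for deterministic skeletons.
# Expectations under the invariant measure are never represented explicitly;
# they are long-run time averages with a burn-in.

traj_states <- function(traj) {
  k <- ncol(traj$n)
  lapply(seq_along(traj$times), function(i)
    list(t = traj$times[i],
         n = traj$n[i, ],
         e1 = traj$e1[i, ], e2 = traj$e2[i, ],
         theta = traj$theta[i, ],
         v = if (!is.null(traj$v)) traj$v[i, ] else NULL))
}

#' Time average of an observable along a trajectory
#'
#' Post-burn-in time average with a batch-means standard error: the retained
#' samples are split into \code{n_batches} contiguous batches, and the SE is
#' the standard deviation of batch means over \code{sqrt(n_batches)}, which
#' accounts for serial correlation on scales shorter than a batch.
#'
#' @param traj a \code{trajectory}.
#' @param observable function of a state list
#'   (\code{t, n, e1, e2, theta, v}) returning a scalar.
#' @param burn_in fraction of the record discarded (in \code{[0, 1)}).
#' @param n_batches number of batches for the SE (default 20).
#' @return list with \code{mean}, \code{se}, \code{n_used}, \code{n_batches}.
#' @export
birkhoff_average <- function(traj, observable, burn_in = 0.2,
                             n_batches = 20L) {
  stopifnot(burn_in >= 0, burn_in < 1)
  m <- length(traj$times)
  i0 <- floor(burn_in * m) + 1L
  if (i0 >= m) stop("empty post-burn-in window")
  idx <- i0:m
  vals <- vapply(traj_states(traj)[idx], observable, 0)
  n_b <- max(2L, min(n_batches, floor(length(vals) / 2)))
  bm <- tapply(vals, cut(seq_along(vals), n_b, labels = FALSE), mean)
  list(mean = mean(vals), se = stats::sd(bm) / sqrt(n_b),
       n_used = length(vals), n_batches = n_b)
}

#' Resident diagnostics: non-growing and stochastically persistent
#'
#' Simulates the monomorphic population of strategy \code{x}, estimates its
#' long-run per-capita growth rate by Birkhoff averaging, and estimates the
#' occupancy of neighborhoods of the extinction set (the fraction of time the
#' minimum population is at or below each threshold \eqn{\eta}). The verdict
#' is \code{"resident"} when the growth rate is zero within 3 SE and the
#' occupancy at \eqn{\eta^*} is at most \eqn{\varepsilon^*}; a growth rate
#' significantly different from zero yields \code{"not_resident"}; otherwise
#' \code{"inconclusive"}.
#'
#' @param model a \code{fluct_model}.
#' @param x strategy vector.
#' @param config a [sim_config()].
#' @param init initial state (defaults to the state-box midpoints).
#' @param eta_grid thresholds for the occupancy curve; defaults to a log
#'   grid scaled by the trajectory's median population.
#' @param eta_star,eps_star persistence thresholds: resident requires
#'   occupancy(\code{eta_star}) <= \code{eps_star}. Defaults: 1e-3 times the
#'   median population, and 0.01.
#' @param burn_in passed to [birkhoff_average()].
#' @return a \code{resident_check} list.
#' @export
resident_diagnostics <- function(model, x, config, init = NULL,
                                 eta_grid = NULL, eta_star = NULL,
                                 eps_star = 0.01, burn_in = 0.2) {
  strategies <- list(x)
  if (is.null(init)) init <- default_init(model, 1L)
  traj <- if (inherits(model, "structured_model"))
    simulate_structured(model, strategies, init, config)
  else simulate_polymorphic(model, strategies, init, config)

  lam <- if (inherits(model, "structured_model")) {
    l <- model$num_classes
    birkhoff_average(traj, function(s) {
      e <- list(e1 = s$e1, e2 = s$e2)
      Fv <- model$transition_matrix(x, e, s$theta) %*% s$v[seq_len(l)]
      sum(Fv)
    }, burn_in = burn_in)
  } else {
    birkhoff_average(traj, function(s)
      model$growth(x, list(e1 = s$e1, e2 = s$e2), s$theta),
      burn_in = burn_in)
  }

  m <- length(traj$times)
  idx <- (floor(burn_in * m) + 1L):m
  minpop <- apply(traj$n[idx, , drop = FALSE], 1L, min)
  med <- stats::median(minpop)
  if (is.null(eta_star)) eta_star <- 1e-3 * med
  if (is.null(eta_grid))
    eta_grid <- med * 10^seq(-4, 0, length.out = 9)
  eta_grid <- sort(eta_grid)
  occ <- vapply(eta_grid, function(et) mean(minpop <= et), 0)
  occ_star <- mean(minpop <= eta_star)

  growing <- abs(lam$mean) > 3 * lam$se
  persistent <- occ_star <= eps_star
  verdict <- if (!growing && persistent) "resident"
  else if (growing || !persistent) "not_resident"
  else "inconclusive"

  structure(list(lambda_hat = lam$mean, lambda_se = lam$se,
                 occupancy_eta = stats::setNames(occ, signif(eta_grid, 4)),
                 eta_star = eta_star, eps_star = eps_star,
                 occupancy_star = occ_star, verdict = verdict,
                 trajectory = traj),
            class = "resident_check")
}

#' @export
print.resident_check <- function(x, ...) {
  cat(sprintf("resident check: lambda_hat = %.4g (SE %.3g), occupancy(eta*=%.3g) = %.3g\n",
              x$lambda_hat, x$lambda_se, x$eta_star, x$occupancy_star))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

default_init <- function(model, k) {
  box <- model$state_box
  mid <- function(b) if (is.matrix(b)) (b[1, ] + b[2, ]) / 2 else mean(b)
  if (inherits(model, "structured_model")) {
    l <- model$num_classes
    n0 <- if (!is.null(box$n)) rep(mid(box$n) / l, l) else rep(0.5, l)
    list(n = rep(list(n0), k),
         e1 = if (model$dim_e1) rep(mid(box$e1 %||% c(0, 1)), model$dim_e1),
         theta = numeric(model$driver$dim_theta))
  } else {
    list(n = rep(if (!is.null(box$n)) mid(box$n) else 0.5, k),
         e1 = if (model$dim_e1) rep(mid(box$e1 %||% c(0, 1)), model$dim_e1),
         theta = numeric(model$driver$dim_theta))
  }
}

#' Classify the attractor of a signal or a deterministic model
#'
#' For a deterministic model, integrates past the transient and reports
#' either a stable equilibrium or a limit cycle with its period (Poincare
#' section at the post-transient mean of the first population coordinate,
#' upward crossings, refined by event-located integration). For a sampled
#' signal (a \code{trajectory} or a \code{list(times, signal)}), the period
#' is estimated from interpolated mean crossings.
#'
#' @param x a \code{fluct_model}, \code{trajectory}, or
#'   \code{list(times =, signal =)}.
#' @param ... further arguments; for models: \code{strategy}, and the
#'   transient/window/tolerance controls of the internal attractor search.
#' @return list with \code{type} (\code{"equilibrium"}, \code{"periodic"},
#'   \code{"none"}), \code{tau} and \code{tau_uncertainty} when periodic.
#' @export
detect_period <- function(x, ...) UseMethod("detect_period")

#' @rdname detect_period
#' @param strategy resident strategy (for model input).
#' @param t_transient,t_window,dt_sample attractor search controls.
#' @export
detect_period.fluct_model <- function(x, strategy, t_transient = 1000,
                                      t_window = 120, dt_sample = 0.01, ...) {
  att <- periodic_attractor(x, list(strategy), t_transient = t_transient,
                            t_window = t_window, dt_sample = dt_sample, ...)
  out <- list(type = att$type, tau = att$tau,
              tau_uncertainty = att$tau_uncertainty %||% NA_real_,
              attractor = att)
  if (att$type == "none") out$diagnostics <- att$diagnostics
  out
}

#' @rdname detect_period
#' @export
detect_period.trajectory <- function(x, ...) {
  detect_period(list(times = x$times, signal = x$n[, 1]), ...)
}

#' @rdname detect_period
#' @param eq_tol relative range below which the signal is an equilibrium.
#' @export
detect_period.default <- function(x, eq_tol = 1e-6, ...) {
  tt <- x$times; sig <- x$signal
  lev <- mean(sig)
  if (diff(range(sig)) < eq_tol * max(1, abs(lev)))
    return(list(type = "equilibrium", tau = NA_real_))
  below <- sig[-length(sig)] < lev & sig[-1] >= lev
  up <- which(below)
  if (length(up) < 2L)
    return(list(type = "none", tau = NA_real_,
                diagnostics = "fewer than two upward mean crossings"))
  frac <- (lev - sig[up]) / (sig[up + 1] - sig[up])
  tc <- tt[up] + frac * (tt[up + 1] - tt[up])
  taus <- diff(tc)
  list(type = "periodic", tau = mean(taus),
       tau_uncertainty = if (length(taus) > 1) stats::sd(taus) / sqrt(length(taus))
       else NA_real_)
}
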
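# Dimorphic dynamics in total-size / relative-frequency coordinates
# (N, P) = (n1 + n2, n2/(n1 + n2)) and the empirical fast-slow validation:
# N, the environment and the driver fluctuate on the natural timescale while
# P drifts slowly toward the attractor predicted by the averaged system.

#' Simulate the dimorphic system in (N, P) coordinates
#'
#' Integrates the change-of-variables form of the two-strategy system for
#' strategies \eqn{x + \epsilon\xi_1} and \eqn{x + \epsilon\xi_2}: total
#' size \eqn{N} grows at the frequency-weighted mean growth rate, \eqn{P}
#' follows the replicator equation in the growth-rate difference, the
#' environment receives the frequency-weighted impacts, and the driver is
#' shared. With the same seed and step this is algebraically equivalent to
#' [simulate_polymorphic()] with the two strategies (same noise path), up to
#' the order of the scheme. \eqn{P} is clamped to \code{[0, 1]}; at
#' \eqn{\epsilon = 0} it is exactly conserved.
#'
#' @param model an \code{unstructured_model}.
#' @param x reference strategy.
#' @param xi1,xi2 deviation directions.
#' @param eps strategy separation (>= 0).
#' @param init list with \code{N}, \code{P}, optional \code{e1}, \code{e2},
#'   \code{theta}.
#' @param config a [sim_config()].
#' @return a \code{trajectory} whose \code{n} matrix has columns
#'   \code{(N, P)}.
#' @export
simulate_dimorphic <- function(model, x, xi1, xi2, eps, init, config) {
  stopifnot(inherits(model, "unstructured_model"), eps >= 0,
            init$P >= 0, init$P <= 1)
  x1 <- x + eps * xi1; x2 <- x + eps * xi2
  strategies <- list(x1, x2)
  dt <- config$dt
  n_steps <- ceiling(config$t_end / dt)
  d1 <- model$dim_e1; d2 <- model$dim_e2
  dth <- model$driver$dim_theta

  N <- init$N; P <- init$P
  e1 <- as.numeric(init$e1 %||% numeric(d1))
  theta <- as.numeric(init$theta %||% numeric(dth))
  nvec <- function() c((1 - P) * N, P * N)
  e2 <- solve_env_implicit(model, nvec(), strategies, e1, theta,
                           guess = init$e2 %||% numeric(d2),
                           tol = config$implicit_tol,
                           max_iter = config$implicit_max_iter)

  dW <- noise_path(config$seed, n_steps, model$driver$dim_noise)
  sdt <- sqrt(dt)
  stride <- config$record_stride
  n_rec <- floor(n_steps / stride) + 1L
  rec_t <- numeric(n_rec); rec_NP <- matrix(0, n_rec, 2L)
  rec_e1 <- matrix(0, n_rec, d1); rec_e2 <- matrix(0, n_rec, d2)
  rec_th <- matrix(0, n_rec, dth)
  rec_t[1L] <- 0; rec_NP[1L, ] <- c(N, P)
  if (d1) rec_e1[1L, ] <- e1
  if (d2) rec_e2[1L, ] <- e2
  if (dth) rec_th[1L, ] <- theta
  irec <- 1L

  growth <- model$growth
  G1 <- model$env_ode_intrinsic; H1 <- model$env_ode_impact
  drift <- model$driver$drift; diffusion <- model$driver$diffusion
  clamp_count <- 0L
  guard <- config$overflow_guard

  for (s in seq_len(n_steps)) {
    e <- list(e1 = e1, e2 = e2)
    f1 <- growth(x1, e, theta); f2 <- growth(x2, e, theta)
    dN <- (f1 * (1 - P) + f2 * P) * N
    dP <- P * (1 - P) * (f2 - f1)
    if (d1) {
      de1 <- G1(e, theta)
      if (!is.null(H1))
        de1 <- de1 + H1(x1, e, theta) * (1 - P) * N + H1(x2, e, theta) * P * N
      e1 <- e1 + de1 * dt
    }
    if (dth) {
      B <- diffusion(theta)
      theta <- theta + drift(theta) * dt +
        as.numeric(matrix(B, dth) %*% dW[s, ]) * sdt
    }
    N <- max(N + dN * dt, 0)
    P_new <- P + dP * dt
    if (P_new < 0 || P_new > 1) {
      P_new <- min(max(P_new, 0), 1)
      clamp_count <- clamp_count + 1L
    }
    P <- P_new
    e2 <- solve_env_implicit(model, nvec(), strategies, e1, theta, guess = e2,
                             tol = config$implicit_tol,
                             max_iter = config$implicit_max_iter)
    if (max(abs(c(N, e1, e2, theta, 0))) > guard)
      stop(sprintf("state blow-up at t = %.6g", s * dt))
    if (s %% stride == 0L) {
      irec <- irec + 1L
      rec_t[irec] <- s * dt
      rec_NP[irec, ] <- c(N, P)
      if (d1) rec_e1[irec, ] <- e1
      if (d2) rec_e2[irec, ] <- e2
      if (dth) rec_th[irec, ] <- theta
    }
  }
  traj <- new_trajectory(rec_t[seq_len(irec)],
                         rec_NP[seq_len(irec), , drop = FALSE],
                         rec_e1[seq_len(irec), , drop = FALSE],
                         rec_e2[seq_len(irec), , drop = FALSE],
                         rec_th[seq_len(irec), , drop = FALSE],
                         v = NULL, config = config,
                         model_id = paste0(model$model_id, "_dimorphic"),
                         clip_count = clamp_count)
  colnames(traj$n) <- c("N", "P")
  traj
}

#' Empirical fast-slow validation against the averaged prediction
#'
#' For each \eqn{\epsilon} in a decreasing grid, simulates the dimorphic
#' system out to a fixed horizon on the relevant slow clock
#' (\eqn{t_1 = \epsilon t} in the first-order regime, \eqn{t_2 = \epsilon^2 t}
#' in the second-order regime) and records the supremum of
#' \eqn{|P_t - p^*|} over the second half of the window (the settling
#' time of the averaged system is existential, so the first half is treated
#' as transient). The slow horizon defaults to \eqn{20/|\mathrm{drive}|}
#' so the window scales with the slow rate.
#'
#' @param model an \code{unstructured_model}.
#' @param x,xi1,xi2 reference strategy and deviation directions.
#' @param eps_grid decreasing vector of separations.
#' @param delta closeness target in \code{(0, 1)}.
#' @param config_template a [sim_config()] whose \code{dt} and \code{seed}
#'   are reused; \code{t_end} is derived from the slow horizon.
#' @param classification an \code{outcome_classification} for the pair (from
#'   [classify_pair()]); supplies the regime and \eqn{p^*}.
#' @param p0 initial relative frequency.
#' @param init_fast initial \code{N}, \code{e1}, \code{theta} for the fast
#'   variables.
#' @param t_slow slow-clock horizon override.
#' @return a \code{slow_fast_report}: per-\eqn{\epsilon} supremum deviations,
#'   pass flags at \code{delta}, the predicted \eqn{p^*}, clamp counts.
#' @export
compare_to_averaged <- function(model, x, xi1, xi2, eps_grid, delta,
                                config_template, classification,
                                p0 = 0.5, init_fast = NULL, t_slow = NULL) {
  if (classification$outcome == "undetermined")
    stop("classification is undetermined; no averaged prediction to compare to")
  p_star <- classification$p_star
  if (length(p_star) > 1L)
    stop("bistable pair: sup-deviation to a single p* is not defined")
  regime <- classification$regime
  echo <- classification$inputs_echo
  eps0 <- echo$eps %||% 1
  # eps-free slow rate on the relevant clock (t1 for order 1, t2 for order 2)
  rate <- if (regime == "order1") abs(echo$drive1) / eps0 else
    max(abs(echo$quad), abs(echo$mixed)) / eps0^2
  if (is.null(t_slow)) t_slow <- 20 / rate
  if (is.null(init_fast)) {
    di <- default_init(model, 1L)
    init_fast <- list(N = di$n[1] * 2, e1 = di$e1, theta = di$theta)
  }
  sup_dev <- numeric(length(eps_grid))
  clamps <- integer(length(eps_grid))
  for (i in seq_along(eps_grid)) {
    eps <- eps_grid[i]
    if (eps == 0) {
      sup_dev[i] <- abs(p0 - p_star)
      next
    }
    t_real <- t_slow / (if (regime == "order1") eps else eps^2)
    cfg <- sim_config(t_end = t_real, dt = config_template$dt,
                      seed = config_template$seed,
                      record_stride = max(1L, floor(t_real / config_template$dt / 4000)))
    traj <- simulate_dimorphic(model, x, xi1, xi2, eps,
                               c(init_fast, list(P = p0)), cfg)
    m <- length(traj$times)
    half <- traj$n[(floor(m / 2) + 1L):m, 2L]
    sup_dev[i] <- max(abs(half - p_star))
    clamps[i] <- traj$clip_count
  }
  structure(list(eps_grid = eps_grid, sup_dev = sup_dev,
                 pass = sup_dev <= delta, delta = delta, p_star = p_star,
                 regime = regime, t_slow = t_slow, clamp_counts = clamps),
            class = "slow_fast_report")
}

#' @export
print.slow_fast_report <- function(x, ...) {
  cat(sprintf("slow-fast check (%s regime), p* = %.4g, delta = %g\n",
              x$regime, x$p_star, x$delta))
  for (i in seq_along(x$eps_grid))
    cat(sprintf("  eps = %-8g sup|P - p*| = %.4g  %s\n", x$eps_grid[i],
                x$sup_dev[i], if (x$pass[i]) "pass" else "FAIL"))
  invisible(x)
}
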
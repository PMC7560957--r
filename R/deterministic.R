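# Deterministic skeletons: deSolve-based integration of a model with the
# driver frozen at theta = 0 (valid when the driver's diffusion vanishes or
# the model has no driver). Used for attractor characterization (equilibria,
# limit cycles, Hopf points) and period-averaged fitness.

det_theta0 <- function(model) numeric(model$driver$dim_theta)

# RHS factory in stacked coordinates (n_1..n_k, e1); e2 is solved per call.
det_rhs_factory <- function(model, strategies, tol = 1e-12) {
  if (!is.list(strategies)) strategies <- list(strategies)
  k <- length(strategies); d1 <- model$dim_e1
  theta <- det_theta0(model)
  growth <- model$growth; G1 <- model$env_ode_intrinsic
  H1 <- model$env_ode_impact
  e2_warm <- numeric(model$dim_e2)
  function(t, state, parms) {
    n <- state[seq_len(k)]
    e1 <- state[k + seq_len(d1)]
    e2 <- solve_env_implicit(model, n, strategies, e1, theta,
                             guess = e2_warm, tol = tol)
    e2_warm <<- e2
    e <- list(e1 = e1, e2 = e2)
    dn <- numeric(k)
    for (i in seq_len(k)) dn[i] <- growth(strategies[[i]], e, theta) * n[i]
    de1 <- if (d1) {
      v <- G1(e, theta)
      if (!is.null(H1)) for (j in seq_len(k))
        v <- v + H1(strategies[[j]], e, theta) * n[j]
      v
    } else numeric(0)
    list(c(dn, de1))
  }
}

det_check <- function(model) {
  dth <- model$driver$dim_theta
  if (dth == 0L) return(invisible(TRUE))
  B <- model$driver$diffusion(numeric(dth))
  if (any(abs(B) > 0))
    stop("deterministic analysis requires a driver with zero diffusion")
  invisible(TRUE)
}

det_integrate <- function(model, strategies, state0, times, rtol = 1e-10,
                          atol = 1e-12) {
  rhs <- det_rhs_factory(model, strategies)
  deSolve::lsoda(y = state0, times = times, func = rhs, parms = NULL,
                 rtol = rtol, atol = atol)
}

# Solve RHS = 0 from a starting guess; jittered restarts guard against
# convergence to a boundary (extinction) equilibrium.
find_equilibrium <- function(model, strategies, guess, interior = TRUE,
                             n_restart = 6L, interior_test = NULL) {
  det_check(model)
  if (!is.list(strategies)) strategies <- list(strategies)
  k <- length(strategies)
  rhs <- det_rhs_factory(model, strategies)
  fn <- function(z) unlist(rhs(0, z, NULL))
  if (is.null(interior_test))
    interior_test <- function(z) k == 0L || all(z[seq_len(k)] > 1e-6)
  g <- guess
  for (r in seq_len(n_restart)) {
    z <- tryCatch(newton_solve(fn, g), error = function(e) NULL)
    if (!is.null(z)) {
      ok_res <- sqrt(sum(fn(z)^2)) < 1e-8
      ok_int <- !interior || interior_test(z)
      if (ok_res && ok_int) return(z)
    }
    g <- guess * (1 + 0.2 * r) + 0.05 * r   # jitter away from the boundary
  }
  stop("no interior equilibrium found from the supplied guess")
}

# Damped Newton iteration with a numerical Jacobian; works for any dimension
# (pracma's quasi-Newton solvers reject scalar systems).
newton_solve <- function(fn, z0, tol = 1e-12, max_iter = 60L) {
  z <- z0
  f <- fn(z)
  for (it in seq_len(max_iter)) {
    nrm <- sqrt(sum(f^2))
    if (nrm < tol) return(z)
    J <- num_jacobian(fn, z)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in Newton iteration")
    lam <- 1
    repeat {
      z_new <- z - lam * step
      f_new <- fn(z_new)
      if (all(is.finite(f_new)) && sqrt(sum(f_new^2)) < nrm * (1 - 0.25 * lam))
        break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    z <- z - lam * step
    f <- fn(z)
  }
  if (sqrt(sum(f^2)) < 1e-8) z else stop("Newton iteration did not converge")
}

num_jacobian <- function(fn, z, h_rel = 1e-6) {
  m <- length(fn(z)); d <- length(z)
  J <- matrix(0, m, d)
  for (j in seq_len(d)) {
    h <- h_rel * (1 + abs(z[j]))
    zp <- z; zm <- z
    zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
    J[, j] <- (fn(zp) - fn(zm)) / (2 * h)
  }
  J
}

#' Locate a Hopf bifurcation along a one-parameter model family
#'
#' Tracks the interior equilibrium of the deterministic system across the
#' bracket by warm-started root solves, monitors the maximum real part of the
#' equilibrium Jacobian's eigenvalues (central-difference Jacobian), and
#' bisects the sign change to \code{tol}.
#'
#' @param model_family function \code{x -> fluct_model} (deterministic).
#' @param bracket length-2 numeric; the scan runs from \code{bracket[2]} down
#'   to \code{bracket[1]}.
#' @param eq_guess starting guess for the stacked equilibrium state
#'   \code{(n, e1)} at \code{bracket[2]}.
#' @param strategies_of optional function \code{x -> strategies list} when the
#'   bifurcation parameter is not itself the (single) resident strategy.
#' @param n_scan number of scan points across the bracket.
#' @param tol bisection tolerance on the parameter.
#' @param t_settle pre-integration time at the first scan point (put the
#'   stable side of the family at \code{bracket[2]} so the integration lands
#'   near the interior equilibrium before the first root solve); 0 disables.
#' @param interior_test optional predicate on the stacked equilibrium state
#'   rejecting boundary (extinction) equilibria; defaults to positivity of
#'   the population coordinates.
#' @return list with \code{x_hopf}, \code{equilibrium}, \code{max_re},
#'   \code{n_evals}.
#' @export
find_hopf <- function(model_family, bracket, eq_guess,
                      strategies_of = function(x) list(x),
                      n_scan = 15L, tol = 1e-5, t_settle = 200,
                      interior_test = NULL) {
  eval_count <- 0L
  maxre_at <- function(x, guess) {
    model <- model_family(x)
    strategies <- strategies_of(x)
    z <- find_equilibrium(model, strategies, guess,
                          interior_test = interior_test)
    rhs <- det_rhs_factory(model, strategies)
    fn <- function(s) unlist(rhs(0, s, NULL))
    J <- num_jacobian(fn, z)
    eval_count <<- eval_count + 1L
    list(mre = max(Re(eigen(J, only.values = TRUE)$values)), eq = z)
  }
  xs <- seq(bracket[2], bracket[1], length.out = n_scan)
  guess <- eq_guess
  if (t_settle > 0) {
    out <- tryCatch(
      det_integrate(model_family(xs[1]), strategies_of(xs[1]), eq_guess,
                    c(0, t_settle), rtol = 1e-8, atol = 1e-10),
      error = function(e) NULL)
    if (!is.null(out)) guess <- as.numeric(out[nrow(out), -1])
  }
  prev <- NULL
  lo <- hi <- NA_real_
  s_lo <- NA_real_
  g_lo <- NULL
  for (x in xs) {
    r <- maxre_at(x, guess)
    guess <- r$eq
    if (!is.null(prev) && prev$mre * r$mre < 0) {
      lo <- x; hi <- prev$x
      s_lo <- sign(r$mre); g_lo <- r$eq
      break
    }
    prev <- list(mre = r$mre, x = x, eq = r$eq)
  }
  if (is.na(lo))
    stop("no sign change of the leading eigenvalue across the bracket")
  eq_w <- g_lo
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    r <- maxre_at(mid, eq_w)
    eq_w <- r$eq
    if (sign(r$mre) == s_lo) lo <- mid else hi <- mid
  }
  r_final <- maxre_at((lo + hi) / 2, eq_w)
  list(x_hopf = (lo + hi) / 2, equilibrium = r_final$eq,
       max_re = r_final$mre, n_evals = eval_count)
}

#' Characterize the attractor of a deterministic resident community
#'
#' Integrates past transients and classifies the attractor of the
#' deterministic system as an equilibrium or a limit cycle. For a cycle the
#' period is located by upward crossings of the first population coordinate
#' through its post-transient mean (a Poincare section), refined by
#' event-located integration, and an anchor state on the cycle is stored so
#' observables — in particular a mutant's growth rate — can be averaged over
#' exactly one period. Slowly damped oscillations near a Hopf point are
#' recognized by their shrinking amplitude and classified through the
#' stability of the underlying equilibrium.
#'
#' @param model a deterministic \code{fluct_model} (zero-diffusion driver).
#' @param strategies list of resident strategy vectors.
#' @param init_state stacked initial state \code{(n, e1)}.
#' @param t_transient transient time discarded before classification.
#' @param t_window observation window for the section search.
#' @param dt_sample sampling step inside the window.
#' @param rtol,atol integrator tolerances.
#' @param eq_tol relative amplitude below which the signal is an equilibrium.
#' @return a list with \code{type} (\code{"equilibrium"}, \code{"periodic"}
#'   or \code{"none"}), the period \code{tau} and anchor state for cycles,
#'   or the equilibrium \code{state}; pass it as \code{resident} to
#'   [invasion_fitness()] with \code{method = "periodic"}.
#' @export
periodic_attractor <- function(model, strategies, init_state = NULL,
                               t_transient = 1000, t_window = 120,
                               dt_sample = 0.01, rtol = 1e-10, atol = 1e-12,
                               eq_tol = 1e-7) {
  det_check(model)
  if (!is.list(strategies)) strategies <- list(strategies)
  k <- length(strategies)
  if (is.null(init_state)) init_state <- rep(0.5, k + model$dim_e1)
  rhs <- det_rhs_factory(model, strategies)

  z1 <- init_state
  t_tr <- t_transient
  for (attempt in 1:4) {
    out <- deSolve::lsoda(z1, seq(0, t_tr, length.out = 51), rhs, NULL,
                          maxsteps = 100000, rtol = rtol, atol = atol)
    z1 <- as.numeric(out[nrow(out), -1])
    times <- seq(0, t_window, by = dt_sample)
    out <- deSolve::lsoda(z1, times, rhs, NULL, rtol = rtol, atol = atol,
                          maxsteps = 100000)
    sig <- out[, 2]   # first population coordinate
    rng <- diff(range(sig))
    lev <- mean(sig)
    if (rng < eq_tol * max(1, abs(lev))) {
      # settle the equilibrium exactly
      z <- tryCatch(find_equilibrium(model, strategies, z1),
                    error = function(e) z1)
      return(list(type = "equilibrium", state = z, tau = NA_real_,
                  model = model, strategies = strategies))
    }
    # guard against slowly damped transients near a Hopf point: if the
    # oscillation amplitude is still shrinking across the window, the signal
    # is not on an attractor yet — either a stable focus (classify via the
    # equilibrium's Jacobian) or an unsettled approach to a cycle (extend)
    half <- seq_len(floor(length(sig) / 2))
    amp1 <- diff(range(sig[half])); amp2 <- diff(range(sig[-half]))
    if (amp2 < 0.95 * amp1) {
      z <- tryCatch(find_equilibrium(model, strategies, z1),
                    error = function(e) NULL)
      if (!is.null(z)) {
        fn <- function(s) unlist(rhs(0, s, NULL))
        mre <- max(Re(eigen(num_jacobian(fn, z), only.values = TRUE)$values))
        if (mre < 0)
          return(list(type = "equilibrium", state = z, tau = NA_real_,
                      model = model, strategies = strategies))
      }
      t_tr <- t_tr * 2
      z1 <- as.numeric(out[nrow(out), -1])
      next
    }
    if (amp2 > 1.02 * amp1 && attempt < 4) {
      t_tr <- t_tr * 2
      z1 <- as.numeric(out[nrow(out), -1])
      next
    }
    break
  }
  up <- which(sig[-length(sig)] < lev & sig[-1] >= lev)
  if (length(up) < 3L)
    return(list(type = "none", tau = NA_real_,
                diagnostics = "no repeated mean crossings in the window",
                model = model, strategies = strategies))
  # refine: from the state at the sample before the first crossing, use
  # lsodar to land exactly on the section (sig = lev, increasing)
  cross_root <- function(z0, t_max) {
    rootfun <- function(t, y, p) y[1] - lev
    ev <- deSolve::lsodar(z0, c(0, t_max), rhs, NULL, rtol = rtol, atol = atol,
                          rootfunc = rootfun)
    tr <- attr(ev, "troot")
    if (is.null(tr) || !length(tr)) return(NULL)
    list(t = tr[1], state = as.numeric(ev[nrow(ev), -1]))
  }
  # walk roots until we get an upward crossing
  z0 <- z1; t_acc <- 0
  anchor <- NULL
  for (rep in 1:12) {
    cr <- cross_root(z0, t_window)
    if (is.null(cr)) break
    der <- unlist(rhs(0, cr$state, NULL))[1]
    # nudge past the section before searching again
    step <- dt_sample / 4
    nxt <- deSolve::lsoda(cr$state, c(0, step), rhs, NULL,
                          rtol = rtol, atol = atol)
    z0 <- as.numeric(nxt[nrow(nxt), -1])
    t_acc <- t_acc + cr$t + step
    if (der > 0) { anchor <- cr$state; break }
  }
  if (is.null(anchor))
    return(list(type = "none", tau = NA_real_,
                diagnostics = "no upward section crossing found",
                model = model, strategies = strategies))
  # one full return to the section from the anchor
  step <- dt_sample / 4
  nxt <- deSolve::lsoda(anchor, c(0, step), rhs, NULL, rtol = rtol, atol = atol)
  z0 <- as.numeric(nxt[nrow(nxt), -1])
  tau <- NA_real_
  t_seek <- step
  for (rep in 1:12) {
    cr <- cross_root(z0, t_window)
    if (is.null(cr)) break
    der <- unlist(rhs(0, cr$state, NULL))[1]
    t_seek <- t_seek + cr$t
    if (der > 0) { tau <- t_seek; break }
    nxt <- deSolve::lsoda(cr$state, c(0, step), rhs, NULL,
                          rtol = rtol, atol = atol)
    z0 <- as.numeric(nxt[nrow(nxt), -1])
    t_seek <- t_seek + step
  }
  if (!is.finite(tau))
    return(list(type = "none", tau = NA_real_,
                diagnostics = "period closure failed",
                model = model, strategies = strategies))
  grid_tau <- if (length(up) >= 2L) mean(diff(dt_sample * up)) else NA_real_
  list(type = "periodic", tau = tau, anchor = anchor,
       tau_uncertainty = if (is.finite(grid_tau)) abs(tau - grid_tau) else NA_real_,
       section_level = lev, model = model, strategies = strategies)
}

# Average observables over exactly one period of a periodic attractor by
# integrating cumulative integrals alongside the state.
periodic_average <- function(attractor, observables, rtol = 1e-11,
                             atol = 1e-13) {
  stopifnot(attractor$type == "periodic")
  model <- attractor$model; strategies <- attractor$strategies
  if (!is.list(observables)) observables <- list(observables)
  k <- length(strategies); d1 <- model$dim_e1
  theta <- det_theta0(model)
  base <- det_rhs_factory(model, strategies)
  m <- length(observables)
  aug <- function(t, state, parms) {
    z <- state[seq_len(k + d1)]
    dz <- unlist(base(t, z, NULL))
    n <- z[seq_len(k)]; e1 <- z[k + seq_len(d1)]
    e2 <- solve_env_implicit(model, n, strategies, e1, theta)
    e <- list(e1 = e1, e2 = e2)
    s <- list(n = n, e1 = e1, e2 = e2, theta = theta, t = t)
    dacc <- vapply(observables, function(ob) ob(s, e), 0)
    list(c(dz, dacc))
  }
  out <- deSolve::lsoda(c(attractor$anchor, numeric(m)),
                        c(0, attractor$tau), aug, NULL,
                        rtol = rtol, atol = atol)
  acc <- as.numeric(out[nrow(out), 1 + k + d1 + seq_len(m)])
  acc / attractor$tau
}
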
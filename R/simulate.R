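#' Simulation configuration
#'
#' @param t_end time horizon (model time units).
#' @param dt fixed Euler-Maruyama step (default 1e-3 fixture time units;
#'   larger steps are appropriate for slowly relaxing fixtures).
#' @param seed integer seed; every source of randomness in a run derives from
#'   it, so identical configurations reproduce trajectories bitwise and
#'   different simulators can share a noise path.
#' @param scheme integration scheme; only \code{"euler_maruyama"}.
#' @param implicit_tol residual tolerance for the implicit environment solve.
#' @param implicit_max_iter damped fixed-point iteration cap before the
#'   fallback root solve.
#' @param record_stride record every \code{record_stride}-th step.
#' @param overflow_guard magnitude beyond which the run is declared divergent.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(t_end, dt = 1e-3, seed = 1L, scheme = "euler_maruyama",
                       implicit_tol = 1e-10, implicit_max_iter = 100L,
                       record_stride = 1L, overflow_guard = 1e10) {
  stopifnot(dt > 0, t_end > 0, implicit_tol > 0)
  scheme <- match.arg(scheme, "euler_maruyama")
  structure(list(t_end = t_end, dt = dt, seed = as.integer(seed),
                 scheme = scheme, implicit_tol = implicit_tol,
                 implicit_max_iter = as.integer(implicit_max_iter),
                 record_stride = as.integer(record_stride),
                 overflow_guard = overflow_guard),
            class = "sim_config")
}

# Pre-generate Wiener increments (unscaled standard normals) from a seed
# without disturbing the caller's RNG stream. Runs that agree on (seed, dt)
# share a path for the steps they have in common.
noise_path <- function(seed, n_steps, dim) {
  if (dim == 0L || n_steps == 0L) return(matrix(0, max(n_steps, 0L), dim))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  matrix(stats::rnorm(n_steps * dim), n_steps, dim)
}

#' Solve the implicit environment component
#'
#' Evaluates \eqn{e_2 = G_2(e,\theta) + \sum_j H_2(x_j,e,\theta) n_j}. When
#' the model declares \code{e2_explicit} the right-hand side does not depend
#' on \eqn{e_2} and a single evaluation is exact; otherwise damped fixed-point
#' iteration is used with a root-solve fallback.
#'
#' @param model a \code{fluct_model}.
#' @param n population sizes (vector of length k, or for structured models a
#'   list of class vectors).
#' @param strategies list of strategy vectors (length k).
#' @param e1 current ODE environment component.
#' @param theta current driver state.
#' @param guess starting value (warm start from the previous step).
#' @param tol,max_iter solver controls.
#' @return numeric vector \code{e2} with residual below \code{tol}.
#' @export
solve_env_implicit <- function(model, n, strategies, e1, theta,
                               guess = NULL, tol = 1e-10, max_iter = 100L) {
  d2 <- model$dim_e2
  if (d2 == 0L) return(numeric(0))
  if (is.null(guess)) guess <- numeric(d2)
  rhs <- function(e2) {
    e <- list(e1 = e1, e2 = e2)
    val <- model$env_implicit_intrinsic(e, theta)
    if (!is.null(model$env_implicit_impact) && length(strategies)) {
      for (j in seq_along(strategies)) {
        h2 <- model$env_implicit_impact(strategies[[j]], e, theta)
        val <- val + if (is.list(n)) as.numeric(h2 %*% n[[j]]) else h2 * n[j]
      }
    }
    val
  }
  if (model$e2_explicit) return(rhs(guess))
  e2 <- guess
  omega <- 1
  res_old <- Inf
  for (it in seq_len(max_iter)) {
    target <- rhs(e2)
    res <- sqrt(sum((e2 - target)^2))
    if (res <= tol) return(e2)
    if (res > res_old) omega <- omega / 2   # damp when diverging
    e2 <- (1 - omega) * e2 + omega * target
    res_old <- res
  }
  # fallback: Newton-type root solve on the residual
  sol <- tryCatch(
    pracma::fsolve(function(z) z - rhs(z), e2, tol = tol),
    error = function(e) NULL)
  if (!is.null(sol)) {
    e2 <- sol$x
    res <- sqrt(sum((e2 - rhs(e2))^2))
    if (res <= max(tol, 1e-8)) return(e2)
  } else res <- sqrt(sum((e2 - rhs(e2))^2))
  stop(sprintf("implicit environment solve did not converge (residual %.3e)", res))
}

new_trajectory <- function(times, n, e1, e2, theta, v = NULL, config, model_id,
                           clip_count = 0L, simplex_drift = 0) {
  structure(list(times = times, n = n, e1 = e1, e2 = e2, theta = theta, v = v,
                 config = config, model_id = model_id,
                 clip_count = clip_count, simplex_drift = simplex_drift),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> model '%s': %d samples on [%g, %g], dt = %g, seed = %d\n",
              x$model_id, length(x$times), x$times[1],
              x$times[length(x$times)], x$config$dt, x$config$seed))
  cat(sprintf("  %d population(s); clips at zero: %d\n",
              ncol(x$n), x$clip_count))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  name_block <- function(m, stem) {
    if (is.null(m) || ncol(m) == 0L) return(NULL)
    colnames(m) <- paste0(stem, "_", seq_len(ncol(m)))
    as.data.frame(m)
  }
  blocks <- list(data.frame(t = x$times),
                 name_block(x$n, "n"), name_block(x$e1, "e1"),
                 name_block(x$e2, "e2"), name_block(x$theta, "theta"),
                 name_block(x$v, "v"))
  do.call(cbind, blocks[!vapply(blocks, is.null, TRUE)])
}

#' Simulate the polymorphic unstructured system
#'
#' Fixed-step Euler-Maruyama integration of populations, environment and
#' driver. The driver is stepped with its Wiener increments, populations and
#' \eqn{e_1} explicitly, and \eqn{e_2} re-solved each step (warm-started from
#' the previous value). Populations are clipped at zero (absorbing, matching
#' the invariance of the extinction set in the exact dynamics); clips are
#' counted.
#'
#' @param model an \code{unstructured_model}.
#' @param strategies list of strategy vectors (may be empty to simulate the
#'   environment/driver alone).
#' @param init list with \code{n} (length k), optional \code{e1}, \code{e2}
#'   (initial guess), \code{theta}.
#' @param config a [sim_config()].
#' @return a \code{trajectory}.
#' @export
simulate_polymorphic <- function(model, strategies, init, config) {
  stopifnot(inherits(model, "unstructured_model"), inherits(config, "sim_config"))
  if (!is.list(strategies)) strategies <- list(strategies)
  k <- length(strategies)
  dt <- config$dt
  n_steps <- ceiling(config$t_end / dt)
  d1 <- model$dim_e1; d2 <- model$dim_e2
  dth <- model$driver$dim_theta

  n <- as.numeric(init$n %||% numeric(k))
  if (length(n) != k) stop("init$n must have one entry per strategy")
  e1 <- as.numeric(init$e1 %||% numeric(d1))
  theta <- as.numeric(init$theta %||% numeric(dth))
  e2 <- solve_env_implicit(model, n, strategies, e1, theta,
                           guess = init$e2 %||% numeric(d2),
                           tol = config$implicit_tol,
                           max_iter = config$implicit_max_iter)

  dW <- noise_path(config$seed, n_steps, model$driver$dim_noise)
  sdt <- sqrt(dt)
  stride <- config$record_stride
  n_rec <- floor(n_steps / stride) + 1L
  rec_t <- numeric(n_rec)
  rec_n <- matrix(0, n_rec, k); rec_e1 <- matrix(0, n_rec, d1)
  rec_e2 <- matrix(0, n_rec, d2); rec_th <- matrix(0, n_rec, dth)
  irec <- 1L
  rec_t[1L] <- 0
  if (k) rec_n[1L, ] <- n
  if (d1) rec_e1[1L, ] <- e1
  if (d2) rec_e2[1L, ] <- e2
  if (dth) rec_th[1L, ] <- theta

  growth <- model$growth
  G1 <- model$env_ode_intrinsic; H1 <- model$env_ode_impact
  drift <- model$driver$drift; diffusion <- model$driver$diffusion
  clip_count <- 0L
  guard <- config$overflow_guard

  for (s in seq_len(n_steps)) {
    e <- list(e1 = e1, e2 = e2)
    if (k) {
      fvals <- numeric(k)
      for (i in seq_len(k)) fvals[i] <- growth(strategies[[i]], e, theta)
    }
    if (d1) {
      de1 <- G1(e, theta)
      if (!is.null(H1) && k) {
        for (j in seq_len(k)) de1 <- de1 + H1(strategies[[j]], e, theta) * n[j]
      }
      e1 <- e1 + de1 * dt
    }
    if (dth) {
      B <- diffusion(theta)
      theta <- theta + drift(theta) * dt +
        as.numeric(matrix(B, dth) %*% dW[s, ]) * sdt
    }
    if (k) {
      n_new <- n + fvals * n * dt
      low <- n_new < 0
      if (any(low)) { n_new[low] <- 0; clip_count <- clip_count + sum(low) }
      n <- n_new
    }
    e2 <- solve_env_implicit(model, n, strategies, e1, theta, guess = e2,
                             tol = config$implicit_tol,
                             max_iter = config$implicit_max_iter)
    if (max(abs(c(n, e1, e2, theta, 0))) > guard)
      stop(sprintf("state blow-up at t = %.6g (magnitude > %.1e)", s * dt, guard))
    if (s %% stride == 0L) {
      irec <- irec + 1L
      rec_t[irec] <- s * dt
      if (k) rec_n[irec, ] <- n
      if (d1) rec_e1[irec, ] <- e1
      if (d2) rec_e2[irec, ] <- e2
      if (dth) rec_th[irec, ] <- theta
    }
  }
  new_trajectory(rec_t[seq_len(irec)], rec_n[seq_len(irec), , drop = FALSE],
                 rec_e1[seq_len(irec), , drop = FALSE],
                 rec_e2[seq_len(irec), , drop = FALSE],
                 rec_th[seq_len(irec), , drop = FALSE],
                 v = NULL, config = config, model_id = model$model_id,
                 clip_count = clip_count)
}

#' Simulate the polymorphic structured system
#'
#' Integrates the structured model either in the total-size/structure
#' decomposition \eqn{(\|n_i\|_1, v_i)} — total sizes grow at
#' \eqn{1^\top F v_i} and the class distribution follows the replicator-type
#' equation, with \eqn{v_i} renormalized onto the probability simplex each
#' step — or in raw class coordinates \eqn{\dot n_i = F n_i}. Both forms are
#' algebraically equivalent and agree to the order of the scheme under a
#' shared noise path.
#'
#' @param model a \code{structured_model}.
#' @param strategies list of strategy vectors.
#' @param init list with \code{n}: list of class vectors (raw) or list with
#'   \code{N} (totals) and \code{v} (list of simplex vectors); plus optional
#'   \code{e1}, \code{e2}, \code{theta}.
#' @param config a [sim_config()].
#' @param form \code{"decomposition"} (default) or \code{"raw"}.
#' @return a \code{trajectory}; \code{n} holds total sizes per strategy and
#'   \code{v} the concatenated class distributions.
#' @export
simulate_structured <- function(model, strategies, init, config,
                                form = c("decomposition", "raw")) {
  stopifnot(inherits(model, "structured_model"), inherits(config, "sim_config"))
  form <- match.arg(form)
  if (!is.list(strategies)) strategies <- list(strategies)
  k <- length(strategies)
  l <- model$num_classes
  dt <- config$dt
  n_steps <- ceiling(config$t_end / dt)
  d1 <- model$dim_e1; d2 <- model$dim_e2
  dth <- model$driver$dim_theta

  if (!is.null(init$n)) {
    nvecs <- lapply(init$n, as.numeric)
  } else {
    nvecs <- mapply(function(N, v) N * v, init$N, init$v, SIMPLIFY = FALSE)
  }
  if (any(vapply(nvecs, length, 1L) != l))
    stop("each class vector must have length num_classes")
  if (any(unlist(nvecs) < 0)) stop("class vectors must be non-negative")
  Ntot <- vapply(nvecs, sum, 0)
  vfrac <- lapply(seq_len(k), function(i)
    if (Ntot[i] > 0) nvecs[[i]] / Ntot[i] else rep(1 / l, l))

  e1 <- as.numeric(init$e1 %||% numeric(d1))
  theta <- as.numeric(init$theta %||% numeric(dth))
  class_weights <- function() mapply(function(N, v) N * v, Ntot, vfrac,
                                     SIMPLIFY = FALSE)
  e2 <- solve_env_implicit(model, class_weights(), strategies, e1, theta,
                           guess = init$e2 %||% numeric(d2),
                           tol = config$implicit_tol,
                           max_iter = config$implicit_max_iter)

  dW <- noise_path(config$seed, n_steps, model$driver$dim_noise)
  sdt <- sqrt(dt)
  stride <- config$record_stride
  n_rec <- floor(n_steps / stride) + 1L
  rec_t <- numeric(n_rec)
  rec_N <- matrix(0, n_rec, k); rec_v <- matrix(0, n_rec, k * l)
  rec_e1 <- matrix(0, n_rec, d1); rec_e2 <- matrix(0, n_rec, d2)
  rec_th <- matrix(0, n_rec, dth)
  rec_t[1L] <- 0; rec_N[1L, ] <- Ntot; rec_v[1L, ] <- unlist(vfrac)
  if (d1) rec_e1[1L, ] <- e1
  if (d2) rec_e2[1L, ] <- e2
  if (dth) rec_th[1L, ] <- theta
  irec <- 1L

  Fm <- model$transition_matrix
  G1 <- model$env_ode_intrinsic; H1 <- model$env_ode_impact
  drift <- model$driver$drift; diffusion <- model$driver$diffusion
  ones <- rep(1, l)
  clip_count <- 0L; simplex_drift <- 0
  guard <- config$overflow_guard

  for (s in seq_len(n_steps)) {
    e <- list(e1 = e1, e2 = e2)
    Fs <- lapply(strategies, Fm, e = e, theta = theta)
    if (d1) {
      de1 <- G1(e, theta)
      if (!is.null(H1)) {
        for (j in seq_len(k)) {
          h1 <- H1(strategies[[j]], e, theta)
          de1 <- de1 + as.numeric(matrix(h1, nrow = d1) %*% (vfrac[[j]] * Ntot[j]))
        }
      }
      e1 <- e1 + de1 * dt
    }
    if (dth) {
      B <- diffusion(theta)
      theta <- theta + drift(theta) * dt +
        as.numeric(matrix(B, dth) %*% dW[s, ]) * sdt
    }
    if (form == "decomposition") {
      for (i in seq_len(k)) {
        Fv <- as.numeric(Fs[[i]] %*% vfrac[[i]])
        lam <- sum(Fv)
        N_new <- Ntot[i] + lam * Ntot[i] * dt
        if (N_new < 0) { N_new <- 0; clip_count <- clip_count + 1L }
        v_new <- vfrac[[i]] + (Fv - lam * vfrac[[i]]) * dt
        v_new[v_new < 0] <- 0
        sv <- sum(v_new)
        simplex_drift <- max(simplex_drift, abs(sv - 1))
        vfrac[[i]] <- if (sv > 0) v_new / sv else rep(1 / l, l)
        Ntot[i] <- N_new
      }
    } else {
      for (i in seq_len(k)) {
        ni <- vfrac[[i]] * Ntot[i]
        ni <- ni + as.numeric(Fs[[i]] %*% ni) * dt
        low <- ni < 0
        if (any(low)) { ni[low] <- 0; clip_count <- clip_count + sum(low) }
        Ntot[i] <- sum(ni)
        vfrac[[i]] <- if (Ntot[i] > 0) ni / Ntot[i] else rep(1 / l, l)
      }
    }
    e2 <- solve_env_implicit(model, class_weights(), strategies, e1, theta,
                             guess = e2, tol = config$implicit_tol,
                             max_iter = config$implicit_max_iter)
    if (max(abs(c(Ntot, e1, e2, theta, 0))) > guard)
      stop(sprintf("state blow-up at t = %.6g (magnitude > %.1e)", s * dt, guard))
    if (s %% stride == 0L) {
      irec <- irec + 1L
      rec_t[irec] <- s * dt
      rec_N[irec, ] <- Ntot; rec_v[irec, ] <- unlist(vfrac)
      if (d1) rec_e1[irec, ] <- e1
      if (d2) rec_e2[irec, ] <- e2
      if (dth) rec_th[irec, ] <- theta
    }
  }
  new_trajectory(rec_t[seq_len(irec)], rec_N[seq_len(irec), , drop = FALSE],
                 rec_e1[seq_len(irec), , drop = FALSE],
                 rec_e2[seq_len(irec), , drop = FALSE],
                 rec_th[seq_len(irec), , drop = FALSE],
                 v = rec_v[seq_len(irec), , drop = FALSE],
                 config = config, model_id = model$model_id,
                 clip_count = clip_count, simplex_drift = simplex_drift)
}

#' Export / import a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds columns \code{t, n_*, e1_*, e2_*, theta_*} (plus \code{v_*}
#' for structured runs); the sidecar records the configuration, model id and
#' seed so a run can be reproduced bitwise.
#'
#' @param traj a \code{trajectory}.
#' @param path CSV file path; the sidecar is written to \code{<path>.json}.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(model_id = traj$model_id,
               config = unclass(traj$config),
               clip_count = traj$clip_count,
               simplex_drift = traj$simplex_drift)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @param ncol_n,ncol_e1,ncol_e2,ncol_theta column counts used to rebuild the
#'   blocks when reading (inferred from column names by default).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  block <- function(stem) {
    cols <- grep(paste0("^", stem, "_"), names(df), value = TRUE)
    as.matrix(df[cols])
  }
  cfg <- meta$config
  config <- sim_config(t_end = cfg$t_end, dt = cfg$dt, seed = cfg$seed,
                       implicit_tol = cfg$implicit_tol,
                       implicit_max_iter = cfg$implicit_max_iter,
                       record_stride = cfg$record_stride,
                       overflow_guard = cfg$overflow_guard)
  v <- block("v"); if (ncol(v) == 0L) v <- NULL
  new_trajectory(df$t, block("n"), block("e1"), block("e2"), block("theta"),
                 v = v, config = config, model_id = meta$model_id,
                 clip_count = meta$clip_count %||% 0L,
                 simplex_drift = meta$simplex_drift %||% 0)
}
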
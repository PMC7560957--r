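# Invasion fitness and its local expansion. The fitness of a rare mutant is
# always computed as the time average of its per-capita growth rate along the
# resident attractor (ergodic average, period average, equilibrium value, or
# an analytic override) — never by simulating the mutant's exponentially
# growing/decaying size, which is equivalent but numerically unsafe.

mutant_growth_obs <- function(model, y) {
  if (inherits(model, "structured_model"))
    stop("use structured_mutant_fitness for structured models")
  function(s) model$growth(y, list(e1 = s$e1, e2 = s$e2), s$theta)
}

# Long-run growth rate of a rare structured mutant along a recorded resident
# trajectory: the mutant's class distribution v_t follows the replicator-type
# equation driven by F(y, e_t, theta_t); its growth rate is 1'F v. The
# distribution is integrated with an Euler step at the trajectory's recording
# resolution and the growth averaged after burn-in.
structured_mutant_fitness <- function(model, traj, y, burn_in = 0.2) {
  l <- model$num_classes
  m <- length(traj$times)
  v <- rep(1 / l, l)
  lams <- numeric(m)
  for (i in seq_len(m)) {
    e <- list(e1 = traj$e1[i, ], e2 = traj$e2[i, ])
    Fm <- model$transition_matrix(y, e, traj$theta[i, ])
    Fv <- as.numeric(Fm %*% v)
    lam <- sum(Fv)
    lams[i] <- lam
    if (i < m) {
      dt <- traj$times[i + 1] - traj$times[i]
      v <- v + (Fv - lam * v) * dt
      v[v < 0] <- 0
      v <- v / sum(v)
    }
  }
  i0 <- floor(burn_in * m) + 1L
  vals <- lams[i0:m]
  n_b <- max(2L, min(20L, floor(length(vals) / 2)))
  bm <- tapply(vals, cut(seq_along(vals), n_b, labels = FALSE), mean)
  list(mean = mean(vals), se = stats::sd(bm) / sqrt(n_b))
}

resident_trajectory <- function(model, resident, config, init = NULL) {
  if (inherits(resident, "trajectory")) return(resident)
  strategies <- if (is.list(resident)) resident else list(resident)
  if (is.null(init)) init <- default_init(model, length(strategies))
  if (inherits(model, "structured_model"))
    simulate_structured(model, strategies, init, config)
  else simulate_polymorphic(model, strategies, init, config)
}

#' Invasion fitness of a mutant in a resident environment
#'
#' Computes \eqn{S_x(y)}, the long-run average of the mutant's per-capita
#' growth rate over the environment generated by the resident community.
#' Methods:
#' \describe{
#'   \item{ergodic}{time average of \eqn{f(y, e_t, \theta_t)} along a
#'     simulated (or supplied) resident trajectory, with a batch-means SE;}
#'   \item{periodic}{average over one detected period of the deterministic
#'     resident limit cycle;}
#'   \item{equilibrium}{evaluation at the deterministic resident fixed point;}
#'   \item{closed_form}{the model's analytic override.}
#' }
#'
#' @param model a \code{fluct_model}.
#' @param resident resident strategy vector, list of strategy vectors
#'   (polymorphic resident), a recorded \code{trajectory}, or a periodic
#'   attractor object (for \code{method = "periodic"}).
#' @param y mutant strategy vector.
#' @param method one of \code{"ergodic"}, \code{"periodic"},
#'   \code{"equilibrium"}, \code{"closed_form"}.
#' @param config a [sim_config()] (required for \code{"ergodic"} unless a
#'   trajectory is supplied).
#' @param burn_in burn-in fraction for the ergodic average.
#' @param eq_guess equilibrium guess for \code{method = "equilibrium"}.
#' @param ... attractor search controls for \code{method = "periodic"}.
#' @return an \code{invasion_result}: list with \code{value}, \code{method},
#'   \code{se} (0 for non-ergodic methods), \code{horizon} or \code{period}.
#' @export
invasion_fitness <- function(model, resident, y,
                             method = c("ergodic", "periodic", "equilibrium",
                                        "closed_form"),
                             config = NULL, burn_in = 0.2, eq_guess = NULL,
                             ...) {
  method <- match.arg(method)
  res <- switch(method,
    closed_form = {
      if (is.null(model$closed_form_fitness))
        stop("model has no closed-form fitness override")
      xr <- if (is.list(resident)) resident[[1]] else resident
      list(value = model$closed_form_fitness(xr, y), se = 0, horizon = NA_real_)
    },
    ergodic = {
      if (!inherits(resident, "trajectory") && is.null(config))
        stop("ergodic method needs a sim_config or a recorded trajectory")
      traj <- resident_trajectory(model, resident, config)
      if (inherits(model, "structured_model")) {
        av <- structured_mutant_fitness(model, traj, y, burn_in)
      } else {
        av <- birkhoff_average(traj, mutant_growth_obs(model, y), burn_in)
      }
      list(value = av$mean, se = av$se,
           horizon = traj$times[length(traj$times)])
    },
    periodic = {
      att <- if (is.list(resident) && identical(resident$type, "periodic"))
        resident
      else periodic_attractor(model, if (is.list(resident)) resident
                              else list(resident), ...)
      if (!identical(att$type, "periodic"))
        stop("no periodic attractor found (", att$diagnostics %||% att$type,
             "); use method = 'equilibrium' or 'ergodic'")
      val <- periodic_average(att, function(s, e)
        model$growth(y, e, s$theta))
      list(value = val, se = 0, period = att$tau)
    },
    equilibrium = {
      det_check(model)
      strategies <- if (is.list(resident)) resident else list(resident)
      if (is.null(eq_guess))
        eq_guess <- rep(0.5, length(strategies) + model$dim_e1)
      z <- find_equilibrium(model, strategies, eq_guess)
      k <- length(strategies)
      e1 <- z[k + seq_len(model$dim_e1)]
      n <- z[seq_len(k)]
      e2 <- solve_env_implicit(model, n, strategies, e1, det_theta0(model))
      list(value = model$growth(y, list(e1 = e1, e2 = e2), det_theta0(model)),
           se = 0, horizon = NA_real_)
    })
  structure(c(res, list(method = method)), class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("invasion fitness = %.6g (%s%s)\n", x$value, x$method,
              if (x$se > 0) sprintf(", SE %.2g", x$se) else ""))
  invisible(x)
}

# Build a cached two-argument fitness evaluator s(x_res, y_mut). Resident-side
# objects (trajectories / attractors / equilibria) are cached per distinct
# resident strategy; with the ergodic method all residents share the seed in
# `config`, giving common random numbers across finite-difference stencils.
fitness_surface <- function(model, method, config = NULL, burn_in = 0.2,
                            eq_guess = NULL, ...) {
  cache <- new.env(parent = emptyenv())
  dots <- list(...)
  key <- function(x) paste(format(x, digits = 17), collapse = "|")
  function(xr, y) {
    if (method == "closed_form")
      return(model$closed_form_fitness(xr, y))
    kk <- key(xr)
    obj <- cache[[kk]]
    if (is.null(obj)) {
      obj <- switch(method,
        ergodic = resident_trajectory(model, xr, config),
        periodic = do.call(periodic_attractor,
                           c(list(model, list(xr)), dots)),
        equilibrium = {
          g <- eq_guess %||% rep(0.5, 1 + model$dim_e1)
          find_equilibrium(model, list(xr), g)
        })
      cache[[kk]] <- obj
    }
    if (method == "equilibrium")
      invasion_fitness(model, list(xr), y, method = "equilibrium",
                       eq_guess = obj)$value
    else
      invasion_fitness(model, obj, y, method = method, config = config,
                       burn_in = burn_in)$value
  }
}

default_h <- function(x) 1e-3 * (1 + sqrt(sum(x^2)))

#' Selection gradient at a reference strategy
#'
#' Central finite differences of \eqn{y \mapsto S_x(y)} at \eqn{y = x},
#' componentwise step \code{h}. With the ergodic method all evaluations share
#' one frozen resident trajectory (common random numbers), which removes the
#' dominant Monte-Carlo error from the difference.
#'
#' @param model a \code{fluct_model}.
#' @param x reference strategy.
#' @param method fitness method (see [invasion_fitness()]).
#' @param h finite-difference step (default \code{1e-3 * (1 + ||x||)}).
#' @param config a [sim_config()] for the ergodic method.
#' @param ... passed to the fitness evaluator (attractor controls etc.).
#' @return numeric gradient of length \code{length(x)}.
#' @export
selection_gradient <- function(model, x, method = "closed_form", h = NULL,
                               config = NULL, ...) {
  s <- fitness_surface(model, method, config, ...)
  selection_gradient_(s, x, h)
}

selection_gradient_ <- function(s, x, h = NULL) {
  if (is.null(h)) h <- default_h(x)
  d <- length(x)
  g <- numeric(d)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    g[i] <- (s(x, x + ei) - s(x, x - ei)) / (2 * h)
  }
  g
}

#' Second-order expansion of the fitness surface at a reference strategy
#'
#' Estimates the selection gradient and the four curvature matrices
#' \eqn{C_{11} = \tfrac12 \partial_{xx} s}, \eqn{C_{22} = \tfrac12
#' \partial_{yy} s}, \eqn{C_{21} = \tfrac12 \partial_{yx} s},
#' \eqn{C_{12} = C_{21}^\top} of the two-argument fitness
#' \eqn{s(x', y') = S_{x'}(y')} at \eqn{(x, x)} by mixed central differences.
#' \eqn{C_{11}} and \eqn{C_{22}} are symmetrized; \eqn{C_{12}} is set to the
#' transpose of \eqn{C_{21}} rather than re-estimated. Selective neutrality
#' (\eqn{s(x, x) = 0}) implies the conservation law
#' \eqn{C_{11} + C_{22} + C_{12} + C_{21} = 0}, which is a built-in accuracy
#' check on the finite differences.
#'
#' @inheritParams selection_gradient
#' @return a \code{local_expansion}: list with \code{gradient}, \code{C11},
#'   \code{C22}, \code{C21}, \code{C12}, \code{h}, and
#'   \code{conservation_defect} (the norm of the summed matrices).
#' @export
second_order_coefficients <- function(model, x, method = "closed_form",
                                      h = NULL, config = NULL, ...) {
  s <- fitness_surface(model, method, config, ...)
  if (is.null(h)) h <- default_h(x)
  d <- length(x)
  ev <- function(i) { e <- numeric(d); e[i] <- h; e }
  s00 <- s(x, x)
  grad <- selection_gradient_(s, x, h)
  C22 <- C11 <- C21 <- matrix(0, d, d)
  for (i in seq_len(d)) {
    C22[i, i] <- (s(x, x + ev(i)) - 2 * s00 + s(x, x - ev(i))) / h^2
    C11[i, i] <- (s(x + ev(i), x) - 2 * s00 + s(x - ev(i), x)) / h^2
  }
  if (d > 1L) {
    for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
      C22[i, j] <- C22[j, i] <-
        (s(x, x + ev(i) + ev(j)) - s(x, x + ev(i) - ev(j)) -
           s(x, x - ev(i) + ev(j)) + s(x, x - ev(i) - ev(j))) / (4 * h^2)
      C11[i, j] <- C11[j, i] <-
        (s(x + ev(i) + ev(j), x) - s(x + ev(i) - ev(j), x) -
           s(x - ev(i) + ev(j), x) + s(x - ev(i) - ev(j), x)) / (4 * h^2)
    }
  }
  for (i in seq_len(d)) for (j in seq_len(d)) {
    # (C21)_{ij} = 1/2 d^2 s / (dy_i dx_j)
    C21[i, j] <- (s(x + ev(j), x + ev(i)) - s(x - ev(j), x + ev(i)) -
                    s(x + ev(j), x - ev(i)) + s(x - ev(j), x - ev(i))) /
      (4 * h^2)
  }
  C11 <- C11 / 2; C22 <- C22 / 2; C21 <- C21 / 2
  C12 <- t(C21)
  defect <- max(abs(C11 + C22 + C12 + C21))
  structure(list(gradient = grad, C11 = C11, C22 = C22, C21 = C21, C12 = C12,
                 h = h, conservation_defect = defect),
            class = "local_expansion")
}

#' @export
print.local_expansion <- function(x, ...) {
  cat("local fitness expansion (step h =", format(x$h), ")\n")
  cat("  gradient:", paste(signif(x$gradient, 6), collapse = ", "), "\n")
  cat("  trace C11, C22:", signif(sum(diag(x$C11)), 6), ",",
      signif(sum(diag(x$C22)), 6), "\n")
  cat("  conservation defect |C11+C22+C12+C21|:",
      format(x$conservation_defect, digits = 3), "\n")
  invisible(x)
}

#' Predicted pairwise fitnesses from a local expansion
#'
#' For strategies \eqn{x_i = x + \epsilon \xi_i}, the exact Taylor expansion
#' through second order gives
#' \deqn{S_{x_1}(x_2) = \epsilon\, g^\top(\xi_2-\xi_1) +
#'   \epsilon^2 (\xi_1^\top C_{11} \xi_1 + 2 \xi_1^\top C_{12} \xi_2 +
#'   \xi_2^\top C_{22} \xi_2) + O(\epsilon^3),}
#' and symmetrically for \eqn{S_{x_2}(x_1)}. The first-order parts are
#' antisymmetric; the conservation law makes both sides vanish at
#' \eqn{\xi_1 = \xi_2}.
#'
#' @param expansion a \code{local_expansion}.
#' @param xi1,xi2 deviation directions.
#' @param eps strategy separation scale (> 0).
#' @return named numeric \code{c(S12, S21)}: predicted
#'   \eqn{(S_{x_1}(x_2), S_{x_2}(x_1))}.
#' @export
expand_fitness_second_order <- function(expansion, xi1, xi2, eps) {
  g <- expansion$gradient
  quad <- function(a, b)
    as.numeric(a %*% expansion$C11 %*% a + 2 * a %*% expansion$C12 %*% b +
                 b %*% expansion$C22 %*% b)
  S12 <- eps * sum(g * (xi2 - xi1)) + eps^2 * quad(xi1, xi2)
  S21 <- eps * sum(g * (xi1 - xi2)) + eps^2 * quad(xi2, xi1)
  c(S12 = S12, S21 = S21)
}

#' Locate evolutionarily singular strategies
#'
#' Zeros of the selection gradient. For scalar strategies the gradient is
#' scanned over the bracket and each sign change bisected; for
#' multi-dimensional strategies, quasi-Newton root finding is run from
#' multiple starts and distinct converged roots are returned. A gradient
#' component that never changes sign (e.g. a strictly beneficial trait
#' direction) yields an empty result with diagnostics.
#'
#' @param model a \code{fluct_model}.
#' @param region for d = 1 a bracket \code{c(lo, hi)}; for d > 1 a matrix with
#'   rows \code{lo}, \code{hi}.
#' @param method,h,config,... passed to the gradient evaluator.
#' @param n_scan scan resolution (d = 1) or number of starts (d > 1).
#' @param tol residual tolerance on the gradient norm.
#' @return list with \code{roots} (list of strategies), \code{residuals},
#'   and \code{diagnostics}.
#' @export
find_singular_strategy <- function(model, region, method = "closed_form",
                                   h = NULL, config = NULL, n_scan = 21L,
                                   tol = 1e-6, ...) {
  s <- fitness_surface(model, method, config, ...)
  gfun <- function(x) selection_gradient_(s, x, h)
  d <- model$strategy_dim
  if (d == 1L) {
    xs <- seq(region[1], region[2], length.out = n_scan)
    gs <- vapply(xs, function(z) gfun(z)[1], 0)
    roots <- list(); resid <- numeric(0)
    for (i in seq_len(n_scan)) {
      if (is.finite(gs[i]) && gs[i] == 0) {   # exact zero on the scan grid
        roots <- c(roots, list(xs[i])); resid <- c(resid, 0)
      }
    }
    for (i in seq_len(n_scan - 1L)) {
      if (is.finite(gs[i]) && is.finite(gs[i + 1]) && gs[i] * gs[i + 1] < 0) {
        r <- stats::uniroot(function(z) gfun(z)[1], c(xs[i], xs[i + 1]),
                            tol = 1e-10)
        roots <- c(roots, list(r$root))
        resid <- c(resid, abs(gfun(r$root)[1]))
      }
    }
    diag_msg <- if (!length(roots))
      sprintf("no sign change of the gradient on [%g, %g]; min |g| = %.3g",
              region[1], region[2], min(abs(gs)))
    else NULL
    return(list(roots = roots, residuals = resid, diagnostics = diag_msg))
  }
  lo <- region[1, ]; hi <- region[2, ]
  roots <- list(); resid <- numeric(0)
  best <- Inf
  for (i in seq_len(n_scan)) {
    start <- lo + (hi - lo) * (i - 0.5) / n_scan
    sol <- tryCatch(suppressWarnings(pracma::fsolve(gfun, start, tol = 1e-10)),
                    error = function(e) NULL)
    if (is.null(sol)) {
      best <- min(best, sqrt(sum(gfun(start)^2)))
      next
    }
    rn <- sqrt(sum(gfun(sol$x)^2))
    best <- min(best, rn)
    if (rn <= tol) {
      dup <- any(vapply(roots, function(r) sqrt(sum((r - sol$x)^2)) < 1e-6,
                        TRUE))
      if (!dup) { roots <- c(roots, list(sol$x)); resid <- c(resid, rn) }
    }
  }
  list(roots = roots, residuals = resid,
       diagnostics = if (!length(roots))
         sprintf("no root converged below tol; best residual %.3g", best))
}
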
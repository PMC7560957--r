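#' Stochastic driver specification
#'
#' Defines the external driver process \eqn{\theta_t}, a diffusion
#' \eqn{d\theta_t = A(\theta_t)\,dt + B(\theta_t)\,dW_t} that forces the
#' environment but is itself unaffected by the populations. The driver is
#' simulated with the Euler-Maruyama scheme (Ito interpretation).
#'
#' @param drift function \code{theta -> numeric(dim_theta)}, the drift \eqn{A}.
#' @param diffusion function \code{theta -> matrix(dim_theta, dim_noise)}, the
#'   diffusion coefficient \eqn{B}. A returned vector is treated as a diagonal
#'   column when \code{dim_noise == dim_theta == length(vector)}.
#' @param dim_theta integer, dimension of the driver state.
#' @param dim_noise integer, number of independent Wiener components.
#' @return an object of class \code{driver_spec}.
#' @seealso [ou_driver()], [no_driver()]
#' @export
driver_spec <- function(drift, diffusion, dim_theta, dim_noise) {
  dim_theta <- as.integer(dim_theta)
  dim_noise <- as.integer(dim_noise)
  stopifnot(dim_theta >= 0L, dim_noise >= 0L)
  if (dim_theta > 0L) {
    stopifnot(is.function(drift), is.function(diffusion))
  }
  structure(list(drift = drift, diffusion = diffusion,
                 dim_theta = dim_theta, dim_noise = dim_noise),
            class = "driver_spec")
}

#' Ornstein-Uhlenbeck driver
#'
#' The linear driver \eqn{d\theta = -a\theta\,dt + b\,dW} with stationary
#' mean 0 and stationary variance \eqn{b^2/(2a)}.
#'
#' @param a mean-reversion rate (> 0).
#' @param b noise intensity (>= 0); \code{b = 0} gives a deterministic decay
#'   to 0, useful for switching fixtures to their deterministic skeleton.
#' @return a \code{driver_spec}.
#' @export
ou_driver <- function(a, b) {
  force(a); force(b)
  driver_spec(drift = function(theta) -a * theta,
              diffusion = function(theta) matrix(b, 1L, 1L),
              dim_theta = 1L, dim_noise = 1L)
}

#' Empty driver (deterministic models)
#' @return a zero-dimensional \code{driver_spec}.
#' @export
no_driver <- function() {
  driver_spec(drift = NULL, diffusion = NULL, dim_theta = 0L, dim_noise = 0L)
}

zero_fun <- function(dim) {
  force(dim)
  function(...) numeric(dim)
}

new_fluct_model <- function(kind, fields) {
  m <- fields
  m$kind <- kind
  # fill absent environment callables with structural zeros so the stepper
  # can treat every model uniformly
  if (is.null(m$env_ode_intrinsic))      m$env_ode_intrinsic      <- zero_fun(m$dim_e1)
  if (is.null(m$env_ode_impact))         m$env_ode_impact         <- NULL
  if (is.null(m$env_implicit_intrinsic)) m$env_implicit_intrinsic <- zero_fun(m$dim_e2)
  if (is.null(m$env_implicit_impact))    m$env_implicit_impact    <- NULL
  if (is.null(m$e2_explicit)) m$e2_explicit <- TRUE
  if (is.null(m$model_id)) m$model_id <- "user_model"
  structure(m, class = c(kind, "fluct_model"))
}

#' Unstructured population model specification
#'
#' Encodes the strategy-indexed model class
#' \deqn{\dot n_i = f(x_i, e, \theta)\, n_i,}
#' \deqn{\dot e_1 = G_1(e,\theta) + \sum_j H_1(x_j, e, \theta)\, n_j,}
#' \deqn{e_2 = G_2(e,\theta) + \sum_j H_2(x_j, e, \theta)\, n_j,}
#' with driver \eqn{\dot\theta = A(\theta) + B(\theta)\dot W}. The environment
#' \eqn{e = (e_1, e_2)} has an ODE-driven part \eqn{e_1} and an implicitly
#' defined part \eqn{e_2}. All environment callables receive the environment as
#' a list \code{e = list(e1 =, e2 =)} plus the driver state \code{theta};
#' the growth rate is \code{growth(x, e, theta)}.
#'
#' Strategies are finite real vectors of a fixed dimension per model; the
#' function-valued environments of some competition models are represented
#' finite-dimensionally by carrying the pairwise interaction inside
#' \code{growth}/\code{env_implicit_impact} (see the Lotka-Volterra fixture).
#'
#' @param growth function \code{(x, e, theta) -> numeric(1)}: per-capita growth
#'   rate of strategy \code{x} (1/time).
#' @param env_ode_intrinsic \eqn{G_1}: function \code{(e, theta) -> numeric(dim_e1)}.
#' @param env_ode_impact \eqn{H_1}: function \code{(x, e, theta) -> numeric(dim_e1)},
#'   the per-individual impact on \eqn{\dot e_1}; \code{NULL} means no impact.
#' @param env_implicit_intrinsic \eqn{G_2}: function \code{(e, theta) -> numeric(dim_e2)}.
#' @param env_implicit_impact \eqn{H_2}: function \code{(x, e, theta) -> numeric(dim_e2)};
#'   \code{NULL} means no impact.
#' @param driver a [driver_spec()].
#' @param dim_e1,dim_e2 integer dimensions of the two environment components
#'   (either may be 0).
#' @param strategy_dim integer, dimension d of the strategy space.
#' @param e2_explicit logical: \code{TRUE} when \eqn{G_2} and \eqn{H_2} do not
#'   depend on \eqn{e_2}, in which case the implicit equation is evaluated in a
#'   single pass; otherwise it is solved by damped fixed-point iteration.
#' @param closed_form_fitness optional function \code{(x, y) -> numeric(1)}
#'   giving an analytic invasion fitness override for the model.
#' @param model_id character label used in trajectories and artifacts.
#' @param state_box named list of ranges (each a length-2 numeric or a matrix
#'   with rows \code{c(lo, hi)}) for \code{x}, \code{n}, \code{e1}, \code{e2},
#'   \code{theta}; used by [validate_model()] probes.
#' @return an object of classes \code{unstructured_model}, \code{fluct_model}.
#' @export
unstructured_model <- function(growth,
                               env_ode_intrinsic = NULL, env_ode_impact = NULL,
                               env_implicit_intrinsic = NULL,
                               env_implicit_impact = NULL,
                               driver = no_driver(),
                               dim_e1 = 0L, dim_e2 = 0L, strategy_dim = 1L,
                               e2_explicit = TRUE,
                               closed_form_fitness = NULL,
                               model_id = "user_model",
                               state_box = NULL) {
  stopifnot(is.function(growth) || is.null(growth),
            inherits(driver, "driver_spec"))
  new_fluct_model("unstructured_model", list(
    growth = growth,
    env_ode_intrinsic = env_ode_intrinsic,
    env_ode_impact = env_ode_impact,
    env_implicit_intrinsic = env_implicit_intrinsic,
    env_implicit_impact = env_implicit_impact,
    driver = driver,
    dim_e1 = as.integer(dim_e1), dim_e2 = as.integer(dim_e2),
    strategy_dim = as.integer(strategy_dim),
    e2_explicit = isTRUE(e2_explicit),
    closed_form_fitness = closed_form_fitness,
    model_id = model_id, state_box = state_box))
}

#' Structured population model specification
#'
#' As [unstructured_model()], but each strategy's population is a vector over
#' \code{num_classes} individual states and the scalar growth rate is replaced
#' by a transition-rate matrix \eqn{F(x, e, \theta)} (an
#' \eqn{\ell\times\ell} matrix of rates, 1/time):
#' \eqn{\dot n_i = F(x_i,e,\theta) n_i}. Impact functions \eqn{H_1, H_2}
#' return an \code{dim_e x num_classes} matrix (or a vector of length
#' \code{num_classes} when \code{dim_e == 1}) that multiplies the class vector.
#'
#' @param transition_matrix function \code{(x, e, theta) -> matrix(l, l)}.
#' @param num_classes integer \eqn{\ell \ge 2}; single-class populations must
#'   use [unstructured_model()].
#' @inheritParams unstructured_model
#' @return an object of classes \code{structured_model}, \code{fluct_model}.
#' @export
structured_model <- function(transition_matrix, num_classes,
                             env_ode_intrinsic = NULL, env_ode_impact = NULL,
                             env_implicit_intrinsic = NULL,
                             env_implicit_impact = NULL,
                             driver = no_driver(),
                             dim_e1 = 0L, dim_e2 = 0L, strategy_dim = 1L,
                             e2_explicit = TRUE,
                             closed_form_fitness = NULL,
                             model_id = "user_model",
                             state_box = NULL) {
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L)
    stop("structured_model() requires num_classes >= 2; ",
         "use unstructured_model() for a single class")
  stopifnot(is.function(transition_matrix), inherits(driver, "driver_spec"))
  new_fluct_model("structured_model", list(
    transition_matrix = transition_matrix, num_classes = num_classes,
    env_ode_intrinsic = env_ode_intrinsic,
    env_ode_impact = env_ode_impact,
    env_implicit_intrinsic = env_implicit_intrinsic,
    env_implicit_impact = env_implicit_impact,
    driver = driver,
    dim_e1 = as.integer(dim_e1), dim_e2 = as.integer(dim_e2),
    strategy_dim = as.integer(strategy_dim),
    e2_explicit = isTRUE(e2_explicit),
    closed_form_fitness = closed_form_fitness,
    model_id = model_id, state_box = state_box))
}

#' @export
print.fluct_model <- function(x, ...) {
  cat(sprintf("<%s> '%s'\n", x$kind, x$model_id))
  if (x$kind == "structured_model")
    cat(sprintf("  classes: %d\n", x$num_classes))
  cat(sprintf("  strategy dim: %d | dim(e1): %d | dim(e2): %d | dim(theta): %d\n",
              x$strategy_dim, x$dim_e1, x$dim_e2, x$driver$dim_theta))
  cat(sprintf("  e2 solve: %s | closed-form fitness: %s\n",
              if (x$e2_explicit) "explicit" else "implicit (fixed point)",
              if (is.null(x$closed_form_fitness)) "no" else "yes"))
  invisible(x)
}

is_deterministic <- function(model) {
  d <- model$driver
  if (d$dim_theta == 0L) return(TRUE)
  th0 <- numeric(d$dim_theta)
  all(abs(d$diffusion(th0)) == 0) && all(abs(d$drift(th0)) == 0 | TRUE) &&
    all(abs(d$diffusion(th0 + 0.1)) == 0)
}

box_points <- function(box, n_probe) {
  # deterministic probe points: midpoint, the two "corners", and a small
  # low-discrepancy fill; box is a matrix with rows lo/hi or a length-2 vector
  rng <- function(b) if (is.matrix(b)) b else matrix(b, nrow = 2L)
  b <- rng(box)
  d <- ncol(b)
  pts <- rbind((b[1, ] + b[2, ]) / 2, b[1, ], b[2, ])
  if (n_probe > 3L) {
    k <- n_probe - 3L
    u <- outer(seq_len(k) / (k + 1), rep(1, d))
    # stagger the coordinates so probes are not all on the diagonal
    for (j in seq_len(d)) u[, j] <- (u[, j] + (j - 1) / d) %% 1
    pts <- rbind(pts, sweep(sweep(u, 2, b[2, ] - b[1, ], "*"), 2, b[1, ], "+"))
  }
  pts
}

#' Validate a model specification by numerical probing
#'
#' Checks shape consistency of all declared callables and probes the growth
#' rate (or transition matrix) with central finite differences up to second
#' order in both the strategy and the environment, at a set of deterministic
#' points in the declared state box. Smoothness to that order is what the
#' series expansion of invasion fitness requires.
#'
#' @param model a \code{fluct_model}.
#' @param probe_box optional named list of ranges overriding the model's
#'   \code{state_box}; must contain \code{x}, \code{n}, and ranges for any
#'   nonempty \code{e1}, \code{e2}, \code{theta}.
#' @param n_probe number of probe points per box (>= 3).
#' @param h_rel relative step for finite-difference probes (default 1e-5,
#'   suited to second-order central differences).
#' @param stop_on_failure signal an error on the first problem instead of
#'   collecting problems in the report.
#' @return a \code{model_validation} report: list with \code{ok}, \code{problems}
#'   (character), \code{n_probes}.
#' @export
validate_model <- function(model, probe_box = NULL, n_probe = 8L,
                           h_rel = 1e-5, stop_on_failure = TRUE) {
  box <- probe_box %||% model$state_box
  if (is.null(box))
    stop("no probe_box supplied and the model has no state_box")
  need <- c("x", "n")
  if (model$dim_e1 > 0L) need <- c(need, "e1")
  if (model$dim_e2 > 0L) need <- c(need, "e2")
  if (model$driver$dim_theta > 0L) need <- c(need, "theta")
  miss <- setdiff(need, names(box))
  if (length(miss))
    stop("probe_box is missing ranges for: ", paste(miss, collapse = ", "))

  problems <- character(0)
  fail <- function(msg) {
    if (stop_on_failure) stop(msg, call. = FALSE)
    problems <<- c(problems, msg)
  }
  fmt_pt <- function(x, e, theta)
    sprintf("x=(%s), e1=(%s), e2=(%s), theta=(%s)",
            paste(signif(x, 6), collapse = ","),
            paste(signif(e$e1, 6), collapse = ","),
            paste(signif(e$e2, 6), collapse = ","),
            paste(signif(theta, 6), collapse = ","))

  xs <- box_points(box$x, n_probe)
  e1s <- if (model$dim_e1 > 0L) box_points(box$e1, n_probe) else matrix(0, nrow(xs), 0)
  e2s <- if (model$dim_e2 > 0L) box_points(box$e2, n_probe) else matrix(0, nrow(xs), 0)
  ths <- if (model$driver$dim_theta > 0L) box_points(box$theta, n_probe) else matrix(0, nrow(xs), 0)
  npts <- min(nrow(xs), nrow(e1s), nrow(e2s), nrow(ths))

  rate_fun <- if (model$kind == "structured_model") model$transition_matrix else model$growth
  rate_name <- if (model$kind == "structured_model") "transition_matrix" else "growth"

  check_shape <- function(val, len, field, ptxt) {
    if (!is.numeric(val) || length(val) != len)
      fail(sprintf("%s returned length %d, expected %d [at %s]",
                   field, length(val), len, ptxt))
    else if (any(!is.finite(val)))
      fail(sprintf("%s returned non-finite value at probe point %s", field, ptxt))
  }

  l <- if (model$kind == "structured_model") model$num_classes else 1L
  for (i in seq_len(npts)) {
    x <- xs[i, ]; e <- list(e1 = e1s[i, ], e2 = e2s[i, ]); th <- ths[i, ]
    ptxt <- fmt_pt(x, e, th)

    v <- rate_fun(x, e, th)
    if (model$kind == "structured_model") {
      if (!is.matrix(v) || any(dim(v) != l))
        fail(sprintf("transition_matrix returned dim (%s), expected %dx%d [at %s]",
                     paste(dim(v), collapse = "x"), l, l, ptxt))
      else if (any(!is.finite(v)))
        fail(sprintf("transition_matrix returned non-finite entries at probe point %s", ptxt))
    } else check_shape(v, 1L, "growth", ptxt)

    if (model$dim_e1 > 0L) {
      check_shape(model$env_ode_intrinsic(e, th), model$dim_e1,
                  "env_ode_intrinsic", ptxt)
      if (!is.null(model$env_ode_impact)) {
        h1 <- model$env_ode_impact(x, e, th)
        check_shape(as.numeric(h1), model$dim_e1 * l, "env_ode_impact", ptxt)
      }
    }
    if (model$dim_e2 > 0L) {
      check_shape(model$env_implicit_intrinsic(e, th), model$dim_e2,
                  "env_implicit_intrinsic", ptxt)
      if (!is.null(model$env_implicit_impact)) {
        h2 <- model$env_implicit_impact(x, e, th)
        check_shape(as.numeric(h2), model$dim_e2 * l, "env_implicit_impact", ptxt)
      }
    }
    if (model$driver$dim_theta > 0L) {
      check_shape(model$driver$drift(th), model$driver$dim_theta, "driver$drift", ptxt)
      B <- model$driver$diffusion(th)
      if (length(as.numeric(B)) != model$driver$dim_theta * model$driver$dim_noise)
        fail(sprintf("driver$diffusion has %d entries, expected %d x %d [at %s]",
                     length(as.numeric(B)), model$driver$dim_theta,
                     model$driver$dim_noise, ptxt))
    }

    # finite-difference smoothness probes of the rate function, order <= 2,
    # in x and in e1/e2 components
    probe_dir <- function(make_pt) {
      f0 <- sum(rate_fun(x, e, th))
      hp <- make_pt(+h_rel); hm <- make_pt(-h_rel)
      fp <- sum(rate_fun(hp$x, hp$e, th)); fm <- sum(rate_fun(hm$x, hm$e, th))
      d1 <- (fp - fm) / 2; d2 <- fp - 2 * f0 + fm
      if (!all(is.finite(c(d1, d2))))
        fail(sprintf("%s derivative probe non-finite at %s", rate_name, ptxt))
    }
    for (j in seq_along(x)) {
      probe_dir(function(h) {
        xx <- x; xx[j] <- xx[j] + h * (1 + abs(xx[j])); list(x = xx, e = e)
      })
    }
    for (j in seq_len(model$dim_e1)) {
      probe_dir(function(h) {
        ee <- e; ee$e1[j] <- ee$e1[j] + h * (1 + abs(ee$e1[j])); list(x = x, e = ee)
      })
    }
    for (j in seq_len(model$dim_e2)) {
      probe_dir(function(h) {
        ee <- e; ee$e2[j] <- ee$e2[j] + h * (1 + abs(ee$e2[j])); list(x = x, e = ee)
      })
    }
  }

  structure(list(ok = length(problems) == 0L, problems = problems,
                 n_probes = npts, model_id = model$model_id),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat(sprintf("model '%s': %s (%d probe points)\n", x$model_id,
              if (x$ok) "all probes finite, shapes consistent" else "PROBLEMS",
              x$n_probes))
  for (p in x$problems) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
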
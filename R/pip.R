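# Pairwise and mutual invasibility grids over a one-dimensional strategy
# slice. For stochastic models one resident trajectory is simulated per grid
# row and every mutant in that row is averaged along it — an exact
# consequence of the fitness being a time average over the resident
# environment, and a large compute saving.

#' Pairwise invasibility grid
#'
#' Evaluates \eqn{S(x, y)} for residents \eqn{x} (rows) and mutants \eqn{y}
#' (columns) on a regular grid over a strategy slice, and classifies each
#' cell as \code{plus}, \code{minus} or \code{neutral_band}. The neutral
#' dead band is 3 SE for ergodic fitness and \code{1e-10} for deterministic
#' methods; the diagonal is neutral by selective neutrality.
#'
#' @param model a \code{fluct_model}.
#' @param x_range length-2 range of the slice coordinate.
#' @param n_grid grid size (>= 2).
#' @param method fitness method (see [invasion_fitness()]).
#' @param config a [sim_config()] for ergodic fitness.
#' @param slice optional function mapping the slice coordinate to a strategy
#'   vector (identity for scalar strategies).
#' @param ... further arguments for the fitness machinery.
#' @return an \code{invasibility_grid}: \code{x_grid}, \code{y_grid},
#'   \code{S} and \code{se} matrices (resident rows, mutant columns), and a
#'   character \code{region} matrix.
#' @export
pip_grid <- function(model, x_range, n_grid, method = "closed_form",
                     config = NULL, slice = identity, ...) {
  stopifnot(n_grid >= 2L)
  xg <- seq(x_range[1], x_range[2], length.out = n_grid)
  S <- matrix(NA_real_, n_grid, n_grid)
  SE <- matrix(0, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    xr <- slice(xg[i])
    res_obj <- xr
    if (method == "ergodic")
      res_obj <- resident_trajectory(model, xr, config)
    if (method == "periodic") {
      att <- periodic_attractor(model, list(xr), ...)
      res_obj <- att
    }
    meth_i <- method
    eq_g <- NULL
    if (method == "periodic" && identical(res_obj$type, "equilibrium")) {
      # resident settles to a point: the period average degenerates to the
      # equilibrium value
      meth_i <- "equilibrium"
      eq_g <- res_obj$state
      res_obj <- xr
    }
    for (j in seq_len(n_grid)) {
      fit <- tryCatch(
        invasion_fitness(model, res_obj, slice(xg[j]), method = meth_i,
                         config = config, eq_guess = eq_g, ...),
        error = function(e) NULL)
      if (!is.null(fit)) { S[i, j] <- fit$value; SE[i, j] <- fit$se }
    }
  }
  band <- ifelse(SE > 0, 3 * SE, 1e-10)
  region <- matrix("missing", n_grid, n_grid)
  region[!is.na(S) & S > band] <- "plus"
  region[!is.na(S) & S < -band] <- "minus"
  region[!is.na(S) & abs(S) <= band] <- "neutral_band"
  diag(region)[!is.na(diag(S))] <- "neutral_band"
  structure(list(x_grid = xg, y_grid = xg, S = S, se = SE, region = region,
                 method = method, model_id = model$model_id),
            class = "invasibility_grid")
}

#' Mutual invasibility regions from a pairwise grid
#'
#' Combines \eqn{S(x_1, x_2)} and \eqn{S(x_2, x_1)} per off-diagonal cell:
#' \code{mutual} when both are plus, \code{one_way} when exactly one is,
#' \code{none} when neither; missing cells propagate.
#'
#' @param pip an \code{invasibility_grid} (square).
#' @return character matrix over the same grid.
#' @export
mip_grid <- function(pip) {
  r <- pip$region
  n <- nrow(r)
  out <- matrix("none", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- r[i, j]; b <- r[j, i]
    out[i, j] <- if (a == "missing" || b == "missing") "missing"
    else if (a == "plus" && b == "plus") "mutual"
    else if (a == "plus" || b == "plus") "one_way"
    else "none"
  }
  diag(out) <- "none"
  out
}

#' Export an invasibility grid as long-format CSV
#' @param pip an \code{invasibility_grid}.
#' @param path output CSV path.
#' @export
write_pip <- function(pip, path) {
  df <- expand.grid(x = pip$x_grid, y = pip$y_grid)
  # expand.grid varies the first factor fastest; S is indexed [resident, mutant]
  df$S <- as.numeric(pip$S)
  df$se <- as.numeric(pip$se)
  df$region <- as.character(pip$region)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.invasibility_grid <- function(x, ...) {
  cat(sprintf("<invasibility_grid> %s, %d x %d, method %s\n", x$model_id,
              nrow(x$S), ncol(x$S), x$method))
  tab <- table(x$region)
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
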
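# Shared fixtures and memoised expensive objects (resident trajectories,
# periodic attractors). Helpers are sourced once per test session, so the
# cache is shared across test files.

fig4_x <- c(2, 0.8, 0.095)
fig4_y <- c(1.99, 0.85, 0.09)

.memo <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

# monomorphic chemostat resident trajectory at the reference strategy
chemostat_resident_traj <- function() memo("chemo_resident", {
  cfg <- sim_config(t_end = 2000, dt = 0.01, seed = 101L, record_stride = 5L)
  simulate_polymorphic(chemostat_model(), list(fig4_x),
                       list(n = 0.3, e1 = 1, theta = 0), cfg)
})

# pure Ornstein-Uhlenbeck run (a = b = 1)
ou_model <- function(a = 1, b = 1) {
  unstructured_model(growth = NULL, driver = ou_driver(a, b),
                     dim_e1 = 0L, dim_e2 = 0L, model_id = "ou_only",
                     state_box = list(x = c(0, 1), n = c(0, 1),
                                      theta = c(-3, 3)))
}
ou_traj <- function() memo("ou_traj", {
  cfg <- sim_config(t_end = 2000, dt = 0.01, seed = 42L, record_stride = 5L)
  simulate_polymorphic(ou_model(), list(), list(n = numeric(0)), cfg)
})

pp_model <- function() memo("pp_model", prey_predator_model())
pp_attractor <- function(x) memo(paste0("pp_att_", x), {
  periodic_attractor(pp_model(), list(x))
})

sirs_resident_check <- function() memo("sirs_check", {
  cfg <- sim_config(t_end = 300, dt = 0.002, seed = 7L, record_stride = 25L)
  resident_diagnostics(sirs_model(), 8.7, cfg,
                       init = list(n = list(c(0.8, 0.4)), e1 = 1.6, theta = 0))
})

lv_resident_traj <- function() memo("lv_resident", {
  cfg <- sim_config(t_end = 800, dt = 0.01, seed = 3L, record_stride = 10L)
  simulate_polymorphic(lotka_volterra_model(strategies = list(0.48)),
                       list(0.48), list(n = 0.5), cfg)
})

chemostat_pip <- function() memo("chemo_pip", {
  # one-dimensional slice through the reference pair direction
  slice <- function(s) fig4_x + s * c(-1, 5, -0.5) * 0.01
  list(slice = slice,
       grid = pip_grid(chemostat_model(), c(-1, 1), 9L,
                       method = "closed_form", slice = slice))
})

hopf_result <- function() memo("hopf", {
  find_hopf(function(x) pp_model(), bracket = c(0.3, 1.0),
            eq_guess = c(0.5, 0.5))
})

# slow-fast runs for the chemostat reference pair (xi2 such that
# eps = 0.01 reproduces the pair exactly)
chemo_slowfast <- function(seed, eps_grid) {
  memo(paste0("sf_", seed, "_", paste(eps_grid, collapse = "_")), {
    m <- chemostat_model()
    cls <- classify_pair(m, fig4_x, fig4_y)
    compare_to_averaged(m, fig4_x, xi1 = c(0, 0, 0),
                        xi2 = (fig4_y - fig4_x) / 0.01,
                        eps_grid = eps_grid, delta = 0.1,
                        config_template = sim_config(t_end = 1, dt = 0.02,
                                                     seed = seed),
                        classification = cls, p0 = 0.5,
                        init_fast = list(N = 0.4, e1 = 1, theta = 0))
  })
}
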
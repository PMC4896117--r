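## Shared fixtures for expensive simulations, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

get_spatial_study <- function() fixture("spatial",
  run_spatial_convergence(h_list = c(0.2, 0.1, 0.05, 0.025), dt = 1e-3, T = 1))

get_temporal_study <- function() fixture("temporal",
  run_temporal_convergence(dt_list = c(8e-3, 4e-3, 2e-3, 1e-3),
                           h_fine = 0.05, T = 1, correction = TRUE))

get_temporal_nocorr <- function() fixture("temporal_nocorr",
  run_temporal_convergence(dt_list = c(8e-3, 4e-3, 2e-3, 1e-3),
                           h_fine = 0.05, T = 1, correction = FALSE))

get_mcf_demo <- function() fixture("mcf", run_mcf_wave_demo())

get_gradient_runs <- function() fixture("gradient_runs",
  lapply(1:5, function(s) run_linear_gradient(n_steps = 2000, seed = s)))

## small disc mesh reused across unit tests
get_disc_mesh <- function(h = 0.1) fixture(paste0("disc", h),
  generate_initial_mesh(domain_spec("disc", h = h, rf = 1)))
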
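# Shared fixtures. The full scenario suite is expensive, so it is built once
# per test session and reused by every file that needs it.

.fixture_env <- new.env(parent = emptyenv())

default_suite <- function() {
  if (is.null(.fixture_env$suite))
    .fixture_env$suite <- run_suite(chain_config(), seed = 1)
  .fixture_env$suite
}

# a small, fast configuration for structural tests
small_geometry <- function() {
  chain_geometry(names = c("river", "sea"), areas = c(5e7, 1e9),
                 depths = c(6, 10), n_layers = 3, salinity = c(0, 20))
}

small_config <- function(days = 8, dt = 0.05, ...) {
  # keep the seasonal-volume scaling commensurate with the shortened window
  chain_config(geometry = small_geometry(), days = days, dt = dt,
               forcing = list(hydrograph = list(
                 total_volume_km3 = 150.5 * days / 183)), ...)
}

# single-box geometry for analytic-limit runs
one_box_geometry <- function(salinity = 0) {
  chain_geometry(names = "box", areas = 1e6, depths = 10, n_layers = 5,
                 salinity = salinity)
}

# kinetic parameter set with every process switched off
null_params <- function(...) {
  kinetic_params(kappa_c = c(labile = 0, semilabile = 0, refractory = 0),
                 kappa_p = c(lpoc = 0, rpoc = 0),
                 kappa_fmax = 0, nu_b = c(0, 0), mu_max = c(0, 0),
                 w_p = c(lpoc = 0, rpoc = 0), w_max = 0, m_tau = 0, ...)
}

# forcing for a closed, dark, quiescent system
closed_forcing_t <- function(boundary = NULL) {
  if (is.null(boundary))
    boundary <- stats::setNames(numeric(length(chain_constituents())),
                                chain_constituents())
  list(discharge = 0, temperature = 20, shortwave = 0, current_speed = 0,
       boundary_conc = boundary)
}

random_state <- function(geometry, params, seed = 1, scale = 5) {
  set.seed(seed)
  st <- chain_state(geometry, params)
  st$conc[] <- stats::runif(length(st$conc), 0, scale)
  attr(st, "initial_carbon") <- carbonchain:::.total_carbon(st, geometry)
  st
}
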
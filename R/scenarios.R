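# Scenario suite: named switch sets over a shared forcing, interface flux
# integration, composition fractions, moving averages and run comparison.

.scenario_names <- c("Base", "NoPD", "2xPD", "NoSet", "Floc", "NoMicrobial")

#' Scenario switch set
#'
#' Maps a scenario name to the documented overrides, leaving everything else
#' identical to the baseline: `NoPD` / `2xPD` set the apparent-quantum-yield
#' multiplier to 0 / 2; `NoSet` zeroes the POC sinking velocities; `Floc`
#' switches the maximum flocculation rate from 0 to 0.1 d^-1; `NoMicrobial`
#' zeroes microbial DOC degradation.
#'
#' @param name one of `"Base"`, `"NoPD"`, `"2xPD"`, `"NoSet"`, `"Floc"`,
#'   `"NoMicrobial"`.
#' @return list with `name`, `aqy_scale`, `w_p`, `kappa_fmax`, `kappa_c`
#'   (the last three `NULL` when unchanged).
#' @export
scenario_config <- function(name = "Base") {
  if (!name %in% .scenario_names)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(.scenario_names, collapse = ", "), call. = FALSE)
  sc <- list(name = name, aqy_scale = 1, w_p = NULL, kappa_fmax = NULL,
             kappa_c = NULL)
  switch(name,
         NoPD = { sc$aqy_scale <- 0 },
         `2xPD` = { sc$aqy_scale <- 2 },
         NoSet = { sc$w_p <- c(lpoc = 0, rpoc = 0) },
         Floc = { sc$kappa_fmax <- 0.1 },
         NoMicrobial = {
           sc$kappa_c <- c(labile = 0, semilabile = 0, refractory = 0)
         })
  sc
}

.apply_scenario_params <- function(params, scen) {
  for (nm in c("w_p", "kappa_fmax", "kappa_c"))
    if (!is.null(scen[[nm]])) params[[nm]] <- scen[[nm]]
  params
}

#' Run the scenario suite
#'
#' Generates the synthetic forcing once from the seed and runs every
#' requested scenario on that identical forcing; the baseline is always
#' included.
#'
#' @param config a [chain_config()] (its `scenario` entry is ignored).
#' @param scenarios scenario names to run.
#' @param seed integer seed overriding `config$seed` if given.
#' @return named list of `chain_run` objects, class `chain_suite`.
#' @export
run_suite <- function(config = chain_config(),
                      scenarios = .scenario_names, seed = NULL) {
  for (s in scenarios) scenario_config(s)   # validate names up front
  scenarios <- union("Base", scenarios)
  config <- .merge_config(chain_config(), config, "config")
  if (!is.null(seed)) config$seed <- seed
  if (!inherits(config$forcing, "chain_forcing"))
    config$forcing <- do.call(synthetic_forcing,
                              c(list(days = config$days, seed = config$seed),
                                config$forcing))
  runs <- lapply(scenarios, function(s) {
    cfg <- config
    cfg$scenario <- s
    run_chain(cfg)
  })
  names(runs) <- scenarios
  structure(runs, class = "chain_suite")
}

#' Integrate a flux series to mass
#'
#' Exact integral of a piecewise-constant flux series:
#' `sum(flux) x dt / 1e9` gigagrams.
#' @param flux_gs flux values (g s^-1).
#' @param dt_s duration of each value (s), default one day.
#' @return integrated mass (Gg).
#' @export
flux_integral <- function(flux_gs, dt_s = 86400) sum(flux_gs * dt_s) / 1e9

#' Time-integrated interface flux
#'
#' Integrates the daily-mean flux across a named interface over a day
#' window, summing the requested constituents, in gigagrams of carbon. The
#' daily series is piecewise constant, so the integral is exact and additive
#' over disjoint windows and over constituents.
#'
#' @param run a `chain_run`.
#' @param interface interface name, e.g. `"plume:ocean"` (see
#'   `run$interfaces`).
#' @param t0,t1 first and last day of the window (inclusive).
#' @param constituents constituent names to sum (default: all ten carbon
#'   pools).
#' @return integrated flux (Gg C).
#' @export
integrate_flux <- function(run, interface, t0 = 1, t1 = max(run$time),
                           constituents = .carbon_pools()) {
  if (!interface %in% run$interfaces)
    stop("interface '", interface, "' not in geometry; available: ",
         paste(run$interfaces, collapse = ", "), call. = FALSE)
  if (!(t0 >= 1 && t1 <= max(run$time) && t0 <= t1))
    stop("window [t0, t1] must lie within the run", call. = FALSE)
  f <- run$interface_flux[t0:t1, interface, constituents, drop = FALSE]
  flux_integral(apply(f, 1, sum))
}

#' Composition fractions of integrated fluxes
#'
#' Relative distribution of an integrated flux over the six reported organic
#' carbon classes (marine, winter and spring/summer chromophoric DOC, total
#' non-chromophoric DOC, labile and refractory POC); fractions sum to 1.
#'
#' @param fluxes named numeric of integrated fluxes per constituent (any
#'   units; the three NCDOC classes are pooled).
#' @return named fractions over `cdoc_m`, `cdoc_w`, `cdoc_ss`, `ncdoc`,
#'   `lpoc`, `rpoc`.
#' @export
composition_fractions <- function(fluxes) {
  get0 <- function(nm) if (nm %in% names(fluxes)) fluxes[[nm]] else 0
  grouped <- c(cdoc_m = get0("cdoc_m"), cdoc_w = get0("cdoc_w"),
               cdoc_ss = get0("cdoc_ss"),
               ncdoc = get0("ncdoc1") + get0("ncdoc2") + get0("ncdoc3") +
                 get0("ncdoc"),
               lpoc = get0("lpoc"), rpoc = get0("rpoc"))
  total <- sum(grouped)
  if (total <= 0)
    stop("total flux must be positive for composition fractions",
         call. = FALSE)
  grouped / total
}

#' Centered moving average
#'
#' Symmetric centered mean with edge shrinkage (edge values are renormalized
#' over the weights actually available). Odd windows use a plain centered
#' mean; even windows use the standard centered filter over `window + 1`
#' points with half weights at the two ends, which keeps the filter
#' symmetric so an affine series is unchanged in the interior. A constant
#' series is always unchanged and the smoothed maximum never exceeds the raw
#' maximum.
#'
#' @param series numeric vector.
#' @param window_days window length in samples (>= 1).
#' @return smoothed series, same length.
#' @export
moving_average <- function(series, window_days = 10) {
  stopifnot(window_days >= 1)
  n <- length(series)
  if (window_days %% 2 == 1) {
    half <- (window_days - 1) / 2
    w <- rep(1, window_days)
  } else {
    half <- window_days / 2
    w <- c(0.5, rep(1, window_days - 1), 0.5)
  }
  vapply(seq_len(n), function(i) {
    idx <- (i - half):(i + half)
    ok <- idx >= 1 & idx <= n
    sum(series[idx[ok]] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Compare a scenario run against the baseline
#'
#' Element-wise differences (scenario minus base) of the interface flux
#' series, the concentration fields and the domain DOC stock, plus
#' integrated flux differences per interface.
#'
#' @param base_run,scenario_run `chain_run` objects on identical geometry
#'   and time axes.
#' @return object of class `chain_comparison` with `delta_flux` (array),
#'   `delta_conc` (array), `delta_doc_stock` (series),
#'   `delta_integrated` (interfaces x constituents, Gg C) and the sign
#'   convention in `convention`.
#' @export
compare <- function(base_run, scenario_run) {
  if (!identical(base_run$geometry$names, scenario_run$geometry$names) ||
      !identical(base_run$time, scenario_run$time))
    stop("runs must share geometry and time axes", call. = FALSE)
  d_flux <- scenario_run$interface_flux - base_run$interface_flux
  d_int <- apply(d_flux, c(2, 3), function(x) flux_integral(x))
  structure(list(
    scenario = scenario_run$scenario,
    delta_flux = d_flux,
    delta_conc = scenario_run$conc - base_run$conc,
    delta_doc_stock = domain_stock(scenario_run) - domain_stock(base_run),
    delta_integrated = d_int,
    convention = "scenario - base"),
    class = "chain_comparison")
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat("<chain_comparison>", x$scenario, "- Base\n")
  cat("  peak |delta flux| (g/s):",
      format(max(abs(x$delta_flux)), digits = 4), "\n")
  cat("  final delta domain DOC stock (Gg C):",
      format(utils::tail(x$delta_doc_stock, 1) / 1e9, digits = 4), "\n")
  invisible(x)
}
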
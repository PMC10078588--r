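# Run configuration: defaults, schema-validated loading from YAML, dumping,
# and output writing with a content-hash manifest.

#' Default run configuration
#'
#' The fully resolved configuration of a simulation: geometry, kinetic
#' parameters, optics, scenario, forcing-generator arguments, initial ocean
#' concentrations, run length, time step, spin-up window and seed. Every
#' entry can be overridden from a YAML file ([load_config()]) or by passing
#' a partial list to [run_chain()].
#'
#' @param ... named overrides of top-level entries.
#' @return a named list, class `chain_config`.
#' @export
chain_config <- function(...) {
  cfg <- list(
    geometry = chain_geometry(),
    params = kinetic_params(),
    optics = list(
      iops = default_iops(),
      aqy_phi0 = c(cdoc_w = 5e-5, cdoc_ss = 5e-5, cdoc_m = 5e-6),
      aqy_slope = 0.02,
      transfer = NULL,
      solar_zenith = 30),
    scenario = "Base",
    forcing = list(
      hydrograph = list(total_volume_km3 = 150.5),
      temperature_range = c(0, 18),
      shortwave_range = c(50, 300),
      peak_day = 107,
      current = c(0.08, 0.04, 14)),
    ocean_conc = default_ocean_conc(),
    days = 183,
    dt = 0.01,
    spinup_days = 45,
    seed = 1)
  cfg <- .merge_config(cfg, list(...), "config")
  class(cfg) <- "chain_config"
  cfg
}

# recursive merge of user entries into the default tree, rejecting unknown
# keys and type mismatches with the offending key path
.merge_config <- function(default, user, path) {
  if (is.null(user)) return(default)
  # whole-object replacements
  if (inherits(user, c("chain_forcing", "chain_geometry", "kinetic_params",
                       "iop_library", "chain_config")))
    return(if (inherits(user, "chain_config")) {
      u <- unclass(user)
      d <- if (is.list(default)) default else u
      .merge_list(d, u, path)
    } else user)
  if (inherits(default, "chain_geometry") && is.list(user))
    return(do.call(chain_geometry, .coerce_geometry_args(user, path)))
  if (inherits(default, "kinetic_params") && is.list(user))
    return(do.call(kinetic_params, user))
  if (inherits(default, "iop_library")) {
    if (is.character(user)) return(read_iops(user))
    stop("config key '", path,
         "' must be an iop_library or a path to an IOP CSV", call. = FALSE)
  }
  if (is.list(default) && is.list(user)) return(.merge_list(default, user, path))
  # leaf: type check
  if (is.numeric(default) && length(default) &&
      !(is.numeric(user) || (is.list(user) && all(vapply(user, is.numeric, TRUE)))))
    stop("config key '", path, "' must be numeric, got ",
         class(user)[1], call. = FALSE)
  if (is.character(default) && !is.character(user))
    stop("config key '", path, "' must be character, got ",
         class(user)[1], call. = FALSE)
  if (is.list(user)) user <- unlist(user)
  if (!is.null(names(default)) && is.null(names(user)) &&
      length(user) == length(default))
    names(user) <- names(default)
  user
}

.merge_list <- function(default, user, path) {
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(path, unknown, sep = "$"), collapse = ", "),
         call. = FALSE)
  for (nm in names(user))
    default[[nm]] <- .merge_config(default[[nm]], user[[nm]],
                                   paste(path, nm, sep = "$"))
  default
}

.coerce_geometry_args <- function(user, path) {
  allowed <- names(formals(chain_geometry))
  unknown <- setdiff(names(user), allowed)
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(path, unknown, sep = "$"), collapse = ", "),
         call. = FALSE)
  for (nm in setdiff(names(user), c("names", "edges")))
    user[[nm]] <- unlist(user[[nm]])
  if (!is.null(user$names)) user$names <- unlist(user$names)
  if (!is.null(user$edges) && !is.data.frame(user$edges))
    user$edges <- as.data.frame(lapply(user$edges, unlist))
  user
}

#' Load a run configuration from YAML
#'
#' Reads a structured-text configuration and resolves it against the full
#' default set: an empty file yields the complete default configuration;
#' unknown keys and type mismatches are rejected with the offending key
#' paths.
#'
#' @param path YAML file path.
#' @return a resolved `chain_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("config file must parse to a mapping", call. = FALSE)
  cfg <- .merge_config(unclass(chain_config()), raw, "config")
  class(cfg) <- "chain_config"
  cfg
}

#' Dump a configuration to YAML
#'
#' Serializes the resolved configuration (geometry fields, kinetic
#' parameters, optics scalars, forcing-generator arguments, run controls) to
#' structured text. The IOP library is not embedded; pass `iops_csv` to
#' write it alongside (the YAML then omits it and reloading uses the
#' default library unless the key is pointed at the CSV).
#'
#' @param config a `chain_config`.
#' @param path output YAML path.
#' @param iops_csv optional path for the IOP library CSV.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path, iops_csv = NULL) {
  g <- config$geometry
  ser <- list(
    geometry = list(names = g$names, areas = g$areas, depths = g$depths,
                    n_layers = g$n_layers, salinity = g$salinity,
                    edges = list(from = g$edges$from, to = g$edges$to,
                                 weight = g$edges$weight)),
    params = lapply(unclass(config$params), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    optics = list(aqy_phi0 = as.list(config$optics$aqy_phi0),
                  aqy_slope = config$optics$aqy_slope,
                  solar_zenith = config$optics$solar_zenith),
    scenario = config$scenario,
    forcing = if (inherits(config$forcing, "chain_forcing")) NULL else
      config$forcing,
    ocean_conc = as.list(config$ocean_conc),
    days = config$days, dt = config$dt,
    spinup_days = config$spinup_days, seed = config$seed)
  ser <- ser[!vapply(ser, is.null, TRUE)]
  if (!is.null(iops_csv)) write_iops(config$optics$iops, iops_csv)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Write run outputs to a directory
#'
#' Emits the full run record as plain text: the state field (one row per
#' day, box and layer with one column per constituent), optical diagnostics,
#' interface fluxes, benthic stocks, the budget ledger, the resolved
#' configuration and IOP library, plus a JSON manifest with an MD5 content
#' hash per file. Deterministic runs re-emit identical hashes.
#'
#' @param run a `chain_run`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (`file`, `md5`), invisibly.
#' @export
write_outputs <- function(run, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  g <- run$geometry
  nb <- length(g$names)
  nl <- g$n_layers
  days <- length(run$time)
  idx <- expand.grid(layer = seq_len(nl), box = seq_len(nb),
                     day = seq_len(days))
  state <- data.frame(day = idx$day, box = g$names[idx$box],
                      layer = idx$layer)
  for (const in chain_constituents())
    state[[const]] <- as.vector(aperm(run$conc[, const, , , drop = FALSE],
                                      c(4, 3, 1, 2)))
  utils::write.csv(state, file.path(dir, "state.csv"), row.names = FALSE)
  optics <- data.frame(day = rep(run$time, nb),
                       box = rep(g$names, each = days),
                       kd_par = as.vector(run$kd_par),
                       par_surface = as.vector(run$par_surface))
  utils::write.csv(optics, file.path(dir, "optics.csv"), row.names = FALSE)
  fx <- expand.grid(day = run$time, interface = run$interfaces,
                    stringsAsFactors = FALSE)
  for (const in chain_constituents())
    fx[[const]] <- as.vector(run$interface_flux[, , const])
  utils::write.csv(fx, file.path(dir, "fluxes.csv"), row.names = FALSE)
  led <- run$ledger
  ledger_df <- data.frame(
    quantity = c(paste0("inflow_", names(led$inflow)),
                 paste0("outflow_", names(led$outflow)),
                 paste0("lake_", names(led$lake)),
                 paste0("deposition_", names(led$deposition)),
                 paste0("resuspension_", names(led$resuspension)),
                 "microbial_co2", "photo_co2", "predation_co2",
                 "primary_production", "audit_relative_residual"),
    grams = c(led$inflow, led$outflow, led$lake, led$deposition,
              led$resuspension, led$microbial_co2, led$photo_co2,
              led$predation_co2, led$primary_production,
              run$audit$relative))
  utils::write.csv(ledger_df, file.path(dir, "ledger.csv"), row.names = FALSE)
  dump_config(run$config, file.path(dir, "config.yaml"),
              iops_csv = file.path(dir, "iops.csv"))
  files <- c("state.csv", "optics.csv", "fluxes.csv", "ledger.csv",
             "config.yaml", "iops.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
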
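# The box-chain simulator: geometry, state, advection, the operator-split
# time step (advect -> optics -> photochemistry -> kinetics -> settling /
# resuspension) and the full run driver with its conservative carbon ledger.

#' Transported constituents
#'
#' The twelve state variables carried in every layer of every box: three
#' chromophoric DOC classes (marine, winter riverine, spring/summer
#' riverine), three non-chromophoric DOC lability classes, labile and
#' refractory POC, inorganic suspended sediment, two phytoplankton groups
#' (carbon) and dissolved inorganic nitrogen.
#' @return character vector of constituent names.
#' @export
chain_constituents <- function() {
  c("cdoc_m", "cdoc_w", "cdoc_ss", "ncdoc1", "ncdoc2", "ncdoc3",
    "lpoc", "rpoc", "iss", "b1", "b2", "din")
}

.carbon_pools <- function() {
  c("cdoc_m", "cdoc_w", "cdoc_ss", "ncdoc1", "ncdoc2", "ncdoc3",
    "lpoc", "rpoc", "b1", "b2")
}

#' Box-chain geometry
#'
#' An ordered chain of boxes from the river inflow to the ocean, each with a
#' surface area, depth, equal-thickness vertical layers and a prescribed
#' salinity. Flow moves along directed interfaces; a box without a
#' downstream target exports to the open ocean. Branch weights on the
#' interfaces out of a box must sum to 1, allowing multiple delta mouths.
#'
#' The default five-box chain (river inflow, delta, delta mouth, plume
#' bounded by the 10 m isobath analogue, coastal ocean) is sized so that at
#' seasonal-mean discharge the river-delta transit takes about 3 days and
#' the plume transit about 3 weeks.
#'
#' @param names box names, in downstream order.
#' @param areas surface areas (m^2).
#' @param depths depths (m), > 0.
#' @param n_layers vertical layers per box (equal thickness).
#' @param salinity prescribed salinity per box.
#' @param edges `data.frame(from, to, weight)` of interfaces by box index,
#'   `to = NA` meaning export; defaults to the linear chain.
#' @return object of class `chain_geometry`.
#' @export
chain_geometry <- function(names = c("pilot", "delta", "mouth", "plume", "ocean"),
                           areas = c(5e7, 4e8, 1e8, 2e9, 1e10),
                           depths = c(8, 5, 4, 8, 20),
                           n_layers = 10,
                           salinity = c(0, 0, 0.5, 5, 25),
                           edges = NULL) {
  nb <- length(names)
  stopifnot(length(areas) == nb, length(depths) == nb,
            length(salinity) == nb, all(depths > 0), all(areas > 0),
            n_layers >= 1)
  if (is.null(edges))
    edges <- data.frame(from = seq_len(nb),
                        to = c(seq_len(nb)[-1], NA),
                        weight = 1)
  if (any(!is.na(edges$to) & edges$to <= edges$from))
    stop("interfaces must point downstream (from < to)", call. = FALSE)
  for (b in unique(edges$from)) {
    w <- sum(edges$weight[edges$from == b])
    if (abs(w - 1) > 1e-12)
      stop("branch weights out of box '", names[b], "' must sum to 1",
           call. = FALSE)
  }
  # fraction of river discharge passing through each box
  q_frac <- numeric(nb)
  q_frac[1] <- 1
  for (i in seq_len(nrow(edges))) {
    if (!is.na(edges$to[i]))
      q_frac[edges$to[i]] <- q_frac[edges$to[i]] +
        q_frac[edges$from[i]] * edges$weight[i]
  }
  interface <- paste(names[edges$from],
                     ifelse(is.na(edges$to), "export", names[edges$to]),
                     sep = ":")
  structure(list(names = names, areas = areas, depths = depths,
                 n_layers = n_layers, dz = depths / n_layers,
                 volumes = areas * depths, salinity = salinity,
                 edges = edges, interfaces = interface, q_frac = q_frac),
            class = "chain_geometry")
}

#' Four-mouth delta geometry preset
#'
#' Variant of the default chain in which the delta splits into four mouths
#' (south, Emmonak, middle, north) with branch weights 0.79 / 0.07 / 0.07 /
#' 0.07, all converging on the plume box.
#' @return a [chain_geometry()].
#' @export
chain_geometry_branched <- function() {
  nms <- c("pilot", "delta", "sm", "emk", "mm", "nm", "plume", "ocean")
  edges <- data.frame(
    from = c(1, 2, 2, 2, 2, 3, 4, 5, 6, 7, 8),
    to = c(2, 3, 4, 5, 6, 7, 7, 7, 7, 8, NA),
    weight = c(1, 0.79, 0.07, 0.07, 0.07, 1, 1, 1, 1, 1, 1))
  chain_geometry(names = nms,
                 areas = c(5e7, 4e8, 6e7, 2e7, 2e7, 2e7, 2e9, 1e10),
                 depths = c(8, 5, 4, 4, 4, 4, 8, 20),
                 salinity = c(0, 0, 0.5, 0.5, 0.5, 0.5, 5, 25),
                 edges = edges)
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat("<chain_geometry>", length(x$names), "boxes,", x$n_layers,
      "layers each\n")
  print(data.frame(box = x$names, area_m2 = x$areas, depth_m = x$depths,
                   salinity = x$salinity, q_fraction = x$q_frac))
  invisible(x)
}

#' Initialize the chain state
#'
#' Concentrations start from the day-1 river boundary values in fresh boxes
#' (salinity < 2) and from prescribed ocean concentrations elsewhere; the
#' benthic sediment pool starts at 10 kg m^-2 (inorganic-sediment
#' equivalent, split 95 % inorganic / 5 % POC).
#'
#' @param geometry a [chain_geometry()].
#' @param params a [kinetic_params()].
#' @param river_conc named day-1 river concentrations (g m^-3).
#' @param ocean_conc named ocean concentrations (g m^-3).
#' @return object of class `chain_state`.
#' @export
chain_state <- function(geometry, params = kinetic_params(),
                        river_conc = NULL, ocean_conc = default_ocean_conc()) {
  const <- chain_constituents()
  nb <- length(geometry$names)
  nl <- geometry$n_layers
  conc <- matrix(0, length(const), nb * nl, dimnames = list(const, NULL))
  if (is.null(river_conc))
    river_conc <- stats::setNames(numeric(length(const)), const)
  for (b in seq_len(nb)) {
    src <- if (geometry$salinity[b] < 2) river_conc else ocean_conc
    conc[, .cell_idx(geometry, b)] <- src[const]
  }
  benthic <- matrix(rep(params$benthic_init, nb), nrow = 3,
                    dimnames = list(c("iss", "lpoc", "rpoc"), geometry$names))
  ledger <- .new_ledger(const)
  st <- structure(list(conc = conc, benthic = benthic, ledger = ledger,
                       t = 0), class = "chain_state")
  attr(st, "initial_carbon") <- .total_carbon(st, geometry)
  st
}

#' Default ocean-end concentrations
#'
#' Time-constant marine concentrations (limited-measurement convention):
#' marine chromophoric DOC, non-chromophoric DOC of 0.48 g C m^-3 split by
#' lability, low POC, 1.77 g m^-3 inorganic sediment, small phytoplankton
#' seed stocks and marine inorganic nitrogen.
#' @return named concentration vector (g m^-3).
#' @export
default_ocean_conc <- function() {
  nc <- lability_split(0.48)
  c(cdoc_m = 0.3, cdoc_w = 0, cdoc_ss = 0.1,
    ncdoc1 = unname(nc["ncdoc1"]), ncdoc2 = unname(nc["ncdoc2"]),
    ncdoc3 = unname(nc["ncdoc3"]),
    lpoc = 0.02, rpoc = 0.08, iss = 1.77, b1 = 0.05, b2 = 0.05, din = 0.1)
}

.cell_idx <- function(geometry, box) {
  (box - 1L) * geometry$n_layers + seq_len(geometry$n_layers)
}

.new_ledger <- function(const) {
  z <- stats::setNames(numeric(length(const)), const)
  list(inflow = z, lake = z, outflow = z,
       deposition = c(iss = 0, lpoc = 0, rpoc = 0),
       resuspension = c(iss = 0, lpoc = 0, rpoc = 0),
       microbial_co2 = 0, photo_co2 = 0, predation_co2 = 0,
       primary_production = 0)
}

.total_carbon <- function(state, geometry) {
  nl <- geometry$n_layers
  vol_cell <- rep(geometry$volumes / nl, each = nl)
  water <- sum(state$conc[.carbon_pools(), , drop = FALSE] %*% vol_cell)
  benth <- sum((state$benthic["lpoc", ] + state$benthic["rpoc", ]) *
                 geometry$areas)
  water + benth
}

#' Carbon budget audit
#'
#' Closure check of the budget ledger: initial stock + boundary inflows +
#' primary production must equal current stock (water column + benthic POC)
#' + exports + the CO2 sinks (microbial, photochemical, grazing
#' respiration). Returns the residual relative to total carbon throughput.
#'
#' @param state a `chain_state`.
#' @param geometry the matching [chain_geometry()].
#' @return list with `residual` (g C), `relative` and the individual terms.
#' @export
chain_audit <- function(state, geometry) {
  led <- state$ledger
  cp <- .carbon_pools()
  sources <- attr(state, "initial_carbon") + sum(led$inflow[cp]) +
    sum(led$lake[cp]) + led$primary_production
  sinks <- .total_carbon(state, geometry) + sum(led$outflow[cp]) +
    led$microbial_co2 + led$photo_co2 + led$predation_co2
  resid <- sources - sinks
  list(residual = resid, relative = abs(resid) / max(sources, 1e-300),
       sources = sources, sinks = sinks)
}

#' Upwind advection along the chain
#'
#' First-order upwind transfer of volume-mean concentration between
#' consecutive boxes, split by branch weights, with river boundary inflow
#' into the first box, optional lake input, and export past the terminal
#' box recorded in the ledger. Salinity is prescribed forcing, not
#' transported.
#'
#' @param state a `chain_state`.
#' @param geometry a [chain_geometry()].
#' @param discharge river discharge (m^3 s^-1), >= 0.
#' @param boundary_conc named river concentrations (g m^-3).
#' @param dt time step (days); must satisfy the advective CFL limit
#'   `Q dt < V` in every box.
#' @param lake optional list `(volume_m3_day, conc)` for the delta lake
#'   source.
#' @param lake_box box index receiving the lake input.
#' @return the updated state; `attr(, "interface_mass")` holds the per-
#'   interface, per-constituent mass moved this step (g).
#' @export
advect <- function(state, geometry, discharge, boundary_conc, dt,
                   lake = NULL, lake_box = 2L) {
  if (discharge < 0) stop("discharge must be nonnegative", call. = FALSE)
  const <- chain_constituents()
  nb <- length(geometry$names)
  nl <- geometry$n_layers
  conc <- state$conc
  edges <- geometry$edges
  out_q <- geometry$q_frac * discharge           # m^3 s^-1 leaving each box
  frac_out <- out_q * 86400 * dt / geometry$volumes
  if (any(frac_out >= 1)) {
    b <- which.max(frac_out)
    stop(sprintf(
      "advective CFL violation in box '%s': Q dt = %.3g m^3 exceeds volume %.3g m^3",
      geometry$names[b], out_q[b] * 86400 * dt, geometry$volumes[b]),
      call. = FALSE)
  }
  cmean <- matrix(0, length(const), nb)
  for (b in seq_len(nb))
    cmean[, b] <- rowMeans(conc[, .cell_idx(geometry, b), drop = FALSE])
  # removal (relative, so every layer keeps its vertical structure)
  for (b in seq_len(nb))
    if (frac_out[b] > 0)
      conc[, .cell_idx(geometry, b)] <- conc[, .cell_idx(geometry, b)] *
        (1 - frac_out[b])
  iface_mass <- matrix(0, nrow(edges), length(const),
                       dimnames = list(geometry$interfaces, const))
  for (i in seq_len(nrow(edges))) {
    from <- edges$from[i]
    mass <- out_q[from] * edges$weight[i] * 86400 * dt * cmean[, from]
    iface_mass[i, ] <- mass
    if (is.na(edges$to[i])) {
      state$ledger$outflow <- state$ledger$outflow + mass
    } else {
      conc[, .cell_idx(geometry, edges$to[i])] <-
        conc[, .cell_idx(geometry, edges$to[i])] +
        mass / geometry$volumes[edges$to[i]]
    }
  }
  if (discharge > 0) {
    mass_in <- discharge * 86400 * dt * boundary_conc[const]
    conc[, .cell_idx(geometry, 1L)] <- conc[, .cell_idx(geometry, 1L)] +
      mass_in / geometry$volumes[1L]
    state$ledger$inflow <- state$ledger$inflow + mass_in
  }
  if (!is.null(lake) && lake$volume_m3_day > 0) {
    mass_lake <- lake$volume_m3_day * dt * lake$conc[const]
    conc[, .cell_idx(geometry, lake_box)] <-
      conc[, .cell_idx(geometry, lake_box)] +
      mass_lake / geometry$volumes[lake_box]
    state$ledger$lake <- state$ledger$lake + mass_lake
  }
  state$conc <- conc
  attr(state, "interface_mass") <- iface_mass
  state
}

#' Optics and photochemistry configuration
#'
#' Bundles the IOP library, apparent-quantum-yield spectrum, photodegradation
#' transfer matrix, solar zenith angle and semi-analytical attenuation
#' coefficients used by the stepper.
#' @param iops an `iop_library`.
#' @param aqy an [aqy_spectrum()].
#' @param transfer a [photo_transfer_matrix()].
#' @param solar_zenith degrees.
#' @param kd_coefs semi-analytical coefficients.
#' @return list of class `chain_optics`.
#' @export
chain_optics <- function(iops = default_iops(), aqy = aqy_spectrum(),
                         transfer = photo_transfer_matrix(),
                         solar_zenith = 30,
                         kd_coefs = c(0.005, 4.18, 0.52, 10.8)) {
  grid <- iops$grid
  # absorption/backscatter contribution matrices over the optical pools
  c2chl <- kinetic_params()$c_to_chl
  A_abs <- cbind(cdoc_m = iops$a_star_cdoc_m,
                 cdoc_w = iops$a_star_cdoc_w,
                 cdoc_ss = iops$a_star_cdoc_ss,
                 lpoc = iops$a_star_spm, rpoc = iops$a_star_spm,
                 iss = iops$a_star_spm,
                 b1 = iops$a_star_phi * 1000 / c2chl[1],
                 b2 = iops$a_star_phi * 1000 / c2chl[2])
  A_bb <- cbind(cdoc_m = 0 * iops$bb_w, cdoc_w = 0 * iops$bb_w,
                cdoc_ss = 0 * iops$bb_w,
                lpoc = iops$bb_star_spm, rpoc = iops$bb_star_spm,
                iss = iops$bb_star_spm,
                b1 = 0 * iops$bb_w, b2 = 0 * iops$bb_w)
  aq <- aqy_eval(aqy, grid$wavelengths)
  photo_weight <- cbind(
    cdoc_w = aq[, "cdoc_w"] * iops$a_star_cdoc_w,
    cdoc_ss = aq[, "cdoc_ss"] * iops$a_star_cdoc_ss,
    cdoc_m = aq[, "cdoc_m"] * iops$a_star_cdoc_m) * 12.011 * 86400
  structure(list(iops = iops, grid = grid, aqy = aqy, transfer = transfer,
                 solar_zenith = solar_zenith, kd_coefs = kd_coefs,
                 A_abs = A_abs, A_bb = A_bb, photo_weight = photo_weight),
            class = "chain_optics")
}

# photodegradation rate coefficients (d^-1 per class) for one box:
# k_c[layer] = 86400 * 12.011 * sum_bands AQY_c a*_c pf_diff / a_t
.box_photo_rates <- function(ed, a_t, dz, optics) {
  grid <- optics$grid
  nl <- ncol(a_t)
  pf <- photon_flux(ed, grid$wavelengths, grid$band_width)  # bands x (nl+1)
  pf_diff <- (pf[, seq_len(nl), drop = FALSE] -
                pf[, seq_len(nl) + 1L, drop = FALSE]) /
    rep(dz, each = nrow(pf))
  ratio <- pf_diff / a_t
  ratio[a_t <= 0] <- 0
  t(crossprod(ratio, optics$photo_weight))   # classes x layers
}

#' Advance the chain one time step
#'
#' Operator sequence: advection, optics (attenuation and irradiance
#' profiles), photochemistry, kinetics (microbial degradation, hydrolysis,
#' flocculation, phytoplankton growth/exudation/grazing), then settling and
#' resuspension. Every mass removal is limited to the donor pool, so
#' concentrations stay nonnegative and every transfer is conservative; all
#' sinks and sources are tallied in the budget ledger.
#'
#' @param state a `chain_state`.
#' @param forcing_t list with this step's `discharge` (m^3 s^-1),
#'   `temperature` (degrees C), `shortwave` (W m^-2), `current_speed`
#'   (m s^-1), `boundary_conc` (named, g m^-3), optional `lake`
#'   (`volume_m3_day`, `conc`) and optional `salinity` (per box).
#' @param geometry a [chain_geometry()].
#' @param params a [kinetic_params()].
#' @param optics a [chain_optics()].
#' @param dt time step (days), > 0.
#' @return updated state; attributes `interface_mass` (g moved per
#'   interface), `kd_par` (vertically averaged, per box) and `par_surface`
#'   (top-layer mid PAR, W m^-2, per box).
#' @export
chain_step <- function(state, forcing_t, geometry, params, optics, dt) {
  stopifnot(dt > 0)
  const <- chain_constituents()
  nb <- length(geometry$names)
  nl <- geometry$n_layers
  sal_box <- if (!is.null(forcing_t$salinity)) forcing_t$salinity else
    geometry$salinity
  # --- advection -----------------------------------------------------------
  state <- advect(state, geometry, forcing_t$discharge,
                  forcing_t$boundary_conc, dt, lake = forcing_t$lake)
  iface_mass <- attr(state, "interface_mass")
  conc <- state$conc
  led <- state$ledger
  vol_cell <- rep(geometry$volumes / nl, each = nl)
  # --- optics + photochemistry per box ------------------------------------
  ed0 <- if (!is.null(forcing_t$ed0)) forcing_t$ed0 else
    build_surface_spectrum(forcing_t$shortwave, optics$grid)
  kd_par_box <- numeric(nb)
  par_surface <- numeric(nb)
  par_cell <- numeric(nb * nl)
  opt_rows <- colnames(optics$A_abs)
  for (b in seq_len(nb)) {
    cells <- .cell_idx(geometry, b)
    cb <- conc[opt_rows, cells, drop = FALSE]
    a_t <- optics$iops$a_w + optics$A_abs %*% cb
    b_b <- optics$iops$bb_w + optics$A_bb %*% cb
    kd <- kd_spectrum(a_t, b_b, optics$solar_zenith, optics$kd_coefs)
    prof <- propagate(ed0, kd, rep(geometry$dz[b], nl), optics$grid)
    par_cell[cells] <- prof$par_by_layer
    par_surface[b] <- prof$par_by_layer[1]
    kd_par_box[b] <- mean(prof$kd_par, na.rm = TRUE)
    if (optics$aqy$scale > 0 && forcing_t$shortwave > 0) {
      k_pd <- .box_photo_rates(prof$ed, a_t, rep(geometry$dz[b], nl), optics)
      for (cls in c("cdoc_w", "cdoc_ss", "cdoc_m")) {
        loss <- pmin(k_pd[cls, ] * dt, 1) * conc[cls, cells]
        if (all(loss == 0)) next
        conc[cls, cells] <- conc[cls, cells] - loss
        tm <- unclass(optics$transfer)[cls, ]
        conc["cdoc_m", cells] <- conc["cdoc_m", cells] + tm[["cdoc_m"]] * loss
        conc["ncdoc3", cells] <- conc["ncdoc3", cells] + tm[["ncdoc3"]] * loss
        led$photo_co2 <- led$photo_co2 +
          sum(tm[["dic"]] * loss * vol_cell[cells])
      }
    }
  }
  # --- kinetics (vectorized over all cells) -------------------------------
  tC <- forcing_t$temperature
  th_c <- temp_factor(tC, params$kt_c, params$t_ref)
  th_p <- temp_factor(tC, params$kt_p, params$t_ref)
  th_b <- temp_factor(tC, params$kt_b, params$t_ref)
  cn <- params$c_n_ratio
  # microbial degradation of the six DOC pools (terminal CO2 sink, N release)
  for (pool in names(params$doc_class_map)) {
    k <- params$kappa_c[[params$doc_class_map[[pool]]]] * th_c
    if (k <= 0) next
    loss <- pmin(k * dt, 1) * conc[pool, ]
    conc[pool, ] <- conc[pool, ] - loss
    conc["din", ] <- conc["din", ] + loss / cn
    led$microbial_co2 <- led$microbial_co2 + sum(loss * vol_cell)
  }
  # hydrolysis of POC into DOC
  for (pool in names(params$kappa_p)) {
    k <- params$kappa_p[[pool]] * th_p
    if (k <= 0) next
    loss <- pmin(k * dt, 1) * conc[pool, ]
    dest <- params$hydrolysis_routing[[pool]]
    conc[pool, ] <- conc[pool, ] - loss
    conc[dest, ] <- conc[dest, ] + loss
  }
  # salinity-driven flocculation of riverine CDOC into refractory POC
  if (params$kappa_fmax > 0) {
    kf <- flocculation_rate(sal_box, params)       # per box
    kf_cell <- rep(kf, each = nl)
    for (pool in c("cdoc_w", "cdoc_ss")) {
      loss <- pmin(kf_cell * dt, 1) * conc[pool, ]
      conc[pool, ] <- conc[pool, ] - loss
      conc["rpoc", ] <- conc["rpoc", ] + loss
    }
  }
  # phytoplankton growth, exudation, grazing
  light_lim <- par_cell / (par_cell + params$e_k)
  n_lim <- conc["din", ] / (conc["din", ] + params$k_n)
  lim <- pmin(light_lim, n_lim)
  growth <- rbind(params$mu_max[[1]] * th_b * lim * conc["b1", ],
                  params$mu_max[[2]] * th_b * lim * conc["b2", ]) * dt
  uptake <- colSums(growth) / cn
  scale <- ifelse(uptake > 0, pmin(1, conc["din", ] / uptake), 1)
  growth <- sweep(growth, 2, scale, `*`)
  conc["din", ] <- pmax(0, conc["din", ] - colSums(growth) / cn)
  for (g in 1:2) {
    bpool <- c("b1", "b2")[g]
    conc[bpool, ] <- conc[bpool, ] + (1 - params$kappa_b) * growth[g, ]
    conc["cdoc_m", ] <- conc["cdoc_m", ] + params$kappa_b * growth[g, ]
    led$primary_production <- led$primary_production +
      sum(growth[g, ] * vol_cell)
    pred <- pmin(params$nu_b[[g]] * th_b * conc[bpool, ] * dt, 1) *
      conc[bpool, ]
    conc[bpool, ] <- conc[bpool, ] - pred
    conc["lpoc", ] <- conc["lpoc", ] + params$f_b[["lpoc"]] * pred
    conc["rpoc", ] <- conc["rpoc", ] + params$f_b[["rpoc"]] * pred
    conc["ncdoc1", ] <- conc["ncdoc1", ] + params$predation_to_ncdoc1 * pred
    conc["din", ] <- conc["din", ] + params$predation_to_remin * pred / cn
    led$predation_co2 <- led$predation_co2 +
      sum(params$predation_to_remin * pred * vol_cell)
  }
  # --- settling and resuspension per box ----------------------------------
  tau <- params$c_d * params$rho_w * forcing_t$current_speed^2
  resus_flux <- resuspension_flux(tau, params) * 86400 * dt  # g m^-2
  for (b in seq_len(nb)) {
    cells <- .cell_idx(geometry, b)
    dz <- geometry$dz[b]
    for (pool in c("lpoc", "rpoc", "iss")) {
      w <- if (pool == "iss")
        iss_settling_velocity(conc[pool, cells], params)
      else rep(params$w_p[[pool]], nl)
      if (all(w == 0)) next
      moved <- pmin(w * dt / dz, 1) * conc[pool, cells]   # donor-limited
      conc[pool, cells] <- conc[pool, cells] - moved +
        c(0, moved[-nl])
      dep <- moved[nl] * dz                               # g m^-2 to benthos
      state$benthic[pool, b] <- state$benthic[pool, b] + dep
      led$deposition[pool] <- led$deposition[pool] + dep * geometry$areas[b]
    }
    if (resus_flux > 0) {
      take_iss <- min(params$resusp_frac_iss * resus_flux,
                      state$benthic["iss", b])
      poc_pool <- state$benthic["lpoc", b] + state$benthic["rpoc", b]
      take_poc <- min((1 - params$resusp_frac_iss) * resus_flux, poc_pool)
      take <- c(iss = take_iss,
                lpoc = if (poc_pool > 0)
                  take_poc * state$benthic["lpoc", b] / poc_pool else 0,
                rpoc = if (poc_pool > 0)
                  take_poc * state$benthic["rpoc", b] / poc_pool else 0)
      bottom <- cells[nl]
      for (pool in names(take)) {
        state$benthic[pool, b] <- state$benthic[pool, b] - take[[pool]]
        conc[pool, bottom] <- conc[pool, bottom] + take[[pool]] / dz
        led$resuspension[pool] <- led$resuspension[pool] +
          take[[pool]] * geometry$areas[b]
      }
    }
  }
  if (any(!is.finite(conc)) || any(conc < -1e-9)) {
    bad <- which(!is.finite(conc) | conc < -1e-9, arr.ind = TRUE)[1, ]
    stop("invalid state after step at t = ", state$t, ": constituent '",
         rownames(conc)[bad[1]], "', cell ", bad[2], call. = FALSE)
  }
  state$conc <- conc
  state$ledger <- led
  state$t <- state$t + dt
  attr(state, "interface_mass") <- iface_mass
  attr(state, "kd_par") <- kd_par_box
  attr(state, "par_surface") <- par_surface
  state
}

#' Run the box-chain simulation
#'
#' Drives [chain_step()] over the full run window with daily piecewise-
#' constant forcing, records daily output (all state variables, vertically
#' averaged attenuation, surface PAR, benthic stocks and interface fluxes)
#' and closes the carbon budget ledger. Deterministic given configuration
#' and seed; the first `spinup_days` days are flagged in the output.
#'
#' @param config a [chain_config()] list (any missing entries are filled
#'   with defaults).
#' @return object of class `chain_run`.
#' @export
run_chain <- function(config = chain_config()) {
  config <- .merge_config(chain_config(), config, "config")
  geometry <- config$geometry
  params <- config$params
  scen <- scenario_config(config$scenario)
  params <- .apply_scenario_params(params, scen)
  optics <- chain_optics(
    iops = config$optics$iops,
    aqy = aqy_spectrum(phi0 = config$optics$aqy_phi0,
                       slope = config$optics$aqy_slope,
                       scale = scen$aqy_scale),
    transfer = photo_transfer_matrix(config$optics$transfer),
    solar_zenith = config$optics$solar_zenith)
  forcing <- config$forcing
  if (!inherits(forcing, "chain_forcing"))
    forcing <- do.call(synthetic_forcing,
                       c(list(days = config$days, seed = config$seed),
                         forcing))
  days <- config$days
  steps_per_day <- max(1L, round(1 / config$dt))
  dt <- 1 / steps_per_day
  const <- chain_constituents()
  nb <- length(geometry$names)
  nl <- geometry$n_layers
  state <- chain_state(geometry, params,
                       river_conc = forcing$boundary_conc[1, ],
                       ocean_conc = config$ocean_conc)
  conc_out <- array(NA_real_, c(days, length(const), nb, nl),
                    dimnames = list(NULL, const, geometry$names, NULL))
  kd_par <- matrix(NA_real_, days, nb, dimnames = list(NULL, geometry$names))
  par_surface <- kd_par
  benthic_out <- array(NA_real_, c(days, 3, nb),
                       dimnames = list(NULL, c("iss", "lpoc", "rpoc"),
                                       geometry$names))
  n_if <- length(geometry$interfaces)
  flux_out <- array(0, c(days, n_if, length(const)),
                    dimnames = list(NULL, geometry$interfaces, const))
  for (d in seq_len(days)) {
    lake_conc <- forcing$boundary_conc[d, ]
    forcing_t <- list(
      discharge = forcing$discharge[d],
      temperature = forcing$temperature[d],
      shortwave = forcing$shortwave[d],
      current_speed = forcing$current_speed[d],
      boundary_conc = forcing$boundary_conc[d, ],
      ed0 = build_surface_spectrum(forcing$shortwave[d], optics$grid),
      lake = if (!is.null(forcing$lake))
        list(volume_m3_day = forcing$lake$volume_m3[d], conc = lake_conc))
    day_mass <- matrix(0, n_if, length(const))
    for (s in seq_len(steps_per_day)) {
      state <- chain_step(state, forcing_t, geometry, params, optics, dt)
      day_mass <- day_mass + attr(state, "interface_mass")
    }
    for (b in seq_len(nb))
      conc_out[d, , b, ] <- state$conc[, .cell_idx(geometry, b)]
    kd_par[d, ] <- attr(state, "kd_par")
    par_surface[d, ] <- attr(state, "par_surface")
    benthic_out[d, , ] <- state$benthic
    flux_out[d, , ] <- day_mass / 86400       # daily mean flux, g s^-1
  }
  audit <- chain_audit(state, geometry)
  structure(list(config = config, geometry = geometry, params = params,
                 optics = optics, forcing = forcing,
                 scenario = config$scenario,
                 time = seq_len(days), conc = conc_out,
                 kd_par = kd_par, par_surface = par_surface,
                 benthic = benthic_out,
                 interface_flux = flux_out,
                 interfaces = geometry$interfaces,
                 ledger = state$ledger, final_state = state,
                 audit = audit, spinup_days = config$spinup_days,
                 dt = dt, seed = config$seed),
            class = "chain_run")
}

#' Domain stock time series
#'
#' Daily whole-domain water-column stock of the selected pools (g).
#' @param run a `chain_run`.
#' @param pools constituent names (default: the six DOC classes).
#' @return numeric vector, one value per day.
#' @export
domain_stock <- function(run, pools = c("cdoc_m", "cdoc_w", "cdoc_ss",
                                        "ncdoc1", "ncdoc2", "ncdoc3")) {
  g <- run$geometry
  nl <- g$n_layers
  vol_layer <- g$volumes / nl
  sapply(seq_along(run$time), function(d) {
    m <- run$conc[d, pools, , , drop = FALSE]
    sum(apply(m, 3, sum) * vol_layer)   # every (pool, layer) cell has vol_layer[b]

  })
}
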
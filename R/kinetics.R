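# Non-photochemical reaction kinetics: microbial degradation, hydrolysis,
# flocculation, settling, resuspension and phytoplankton rates. All rates are
# pure functions of local state, temperature, salinity and light; the chain
# stepper applies them as conservative mass transfers.

#' Kinetic parameter set
#'
#' Rate constants and auxiliary parameters of the carbon kinetics. Defaults
#' are the published parameter set of the model this package implements:
#' exudation fraction 0.2; microbial degradation of labile / semi-labile /
#' refractory DOC 0.025 / 0.01 / 0.001 d^-1; hydrolysis of labile / refractory
#' POC 0.03 / 0.006 d^-1; maximum flocculation rate 0 (baseline; 0.1 d^-1 in
#' the flocculation scenario) peaking at salinity 1.0 with shape parameters
#' 5.0 (sub-optimal) and 0.25 (super-optimal); implicit second-order grazing
#' 1.5 m^3 (g C)^-1 d^-1; POC fractions of phytoplankton death 0.1 / 0.5;
#' POC sinking 1.0 / 0.4 m d^-1; sediment settling saturating at 2.0 m d^-1
#' with half-saturation 51 g m^-3; critical shear stress 0.005 Pa and
#' resuspension coefficient 1e-5 g m^-2 s^-1 Pa^-1.
#'
#' Temperature response functions, the DOC-class-to-rate mapping, hydrolysis
#' routing and the routing of the non-POC remainder of grazing losses are not
#' fixed by the published table; the defaults here (Q10 of about 2 shared by
#' all three temperature functions; winter riverine CDOC treated as most
#' refractory; hydrolysate routed to non-chromophoric pools; grazing remainder
#' split equally between labile NCDOC and remineralization) are package
#' choices, all overridable.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of class `kinetic_params`.
#' @export
kinetic_params <- function(...) {
  p <- list(
    kappa_b = 0.2,
    kappa_c = c(labile = 0.025, semilabile = 0.01, refractory = 0.001), # d^-1
    kappa_p = c(lpoc = 0.03, rpoc = 0.006),                             # d^-1
    kappa_fmax = 0.0,                                                   # d^-1
    s_max = 1.0,
    kappa_c1 = 5.0,
    kappa_c2 = 0.25,
    nu_b = c(1.5, 1.5),              # m^3 (g C)^-1 d^-1 per phytoplankton group
    f_b = c(lpoc = 0.1, rpoc = 0.5),
    w_p = c(lpoc = 1.0, rpoc = 0.4), # m d^-1
    w_max = 2.0,                     # m d^-1
    k_iss = 51.0,                    # g m^-3
    tau_crit = 0.005,                # Pa
    m_tau = 1.0e-5,                  # g m^-2 s^-1 Pa^-1
    kt_c = 0.069, kt_p = 0.069, kt_b = 0.069,  # degC^-1
    t_ref = 20,                      # degC
    mu_max = c(2.0, 1.5),            # d^-1 per phytoplankton group
    e_k = 30,                        # W m^-2 PAR half saturation
    k_n = 0.025,                     # g N m^-3
    c_to_chl = c(40.0, 28.6),        # g C (g chl)^-1
    c_n_ratio = 106 * 12.011 / (16 * 14.007),  # g C per g N (Redfield)
    # lability class applied to each DOC pool
    doc_class_map = c(cdoc_m = "labile", cdoc_ss = "semilabile",
                      cdoc_w = "refractory", ncdoc1 = "labile",
                      ncdoc2 = "semilabile", ncdoc3 = "refractory"),
    # destination DOC pool of hydrolysed POC
    hydrolysis_routing = c(lpoc = "ncdoc1", rpoc = "ncdoc3"),
    # routing of the grazing remainder 1 - sum(f_b) = 0.4
    predation_to_ncdoc1 = 0.2,
    predation_to_remin = 0.2,
    # resuspension partition and benthic pool
    resusp_frac_iss = 0.95,
    benthic_init = c(iss = 9500, lpoc = 250, rpoc = 250),  # g m^-2
    c_d = 0.0025,                    # bottom drag coefficient
    rho_w = 1025                     # kg m^-3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (i in seq_along(dots)) {        # positional: a repeated name wins last
    nm <- names(dots)[i]
    v <- dots[[i]]
    if (is.list(v)) v <- unlist(v)
    if (is.numeric(p[[nm]]) && !is.numeric(v))
      stop("kinetic parameter '", nm, "' must be numeric, got ",
           class(v)[1], call. = FALSE)
    if (!is.null(names(p[[nm]])) && length(v) == length(p[[nm]]) &&
        is.null(names(v)))
      names(v) <- names(p[[nm]])
    p[[nm]] <- v
  }
  if (sum(p$f_b) > 1)
    stop("f_b components must sum to at most 1", call. = FALSE)
  structure(p, class = "kinetic_params")
}

#' Exponential temperature response
#'
#' `theta = exp(kt (t - t_ref))`; equals 1 at the reference temperature and
#' about 2 per 10 degrees C at the default `kt = 0.069`.
#'
#' @param t temperature (degrees C).
#' @param kt temperature coefficient (degC^-1).
#' @param t_ref reference temperature (degrees C).
#' @return dimensionless multiplier, > 0.
#' @export
temp_factor <- function(t, kt = 0.069, t_ref = 20) exp(kt * (t - t_ref))

#' Heterotrophic microbial degradation rate of a DOC class
#'
#' First-order loss `kappa_c[class] theta_c(t) [DOC]`, a terminal
#' remineralization sink (CO2 in the budget ledger). The lability class is
#' either given directly (`"labile"`, `"semilabile"`, `"refractory"`) or
#' looked up from a DOC pool name via `params$doc_class_map`.
#'
#' @param doc_class_conc concentration of the class (g C m^-3), >= 0.
#' @param class_index lability class or DOC pool name.
#' @param t temperature (degrees C).
#' @param params a [kinetic_params()].
#' @return degradation rate (g C m^-3 d^-1).
#' @export
microbial_degradation_rate <- function(doc_class_conc, class_index, t, params) {
  cls <- .doc_lability(class_index, params)
  params$kappa_c[[cls]] * temp_factor(t, params$kt_c, params$t_ref) *
    doc_class_conc
}

.doc_lability <- function(class_index, params) {
  if (class_index %in% names(params$kappa_c)) return(class_index)
  if (class_index %in% names(params$doc_class_map))
    return(params$doc_class_map[[class_index]])
  stop("unknown DOC class index: ", class_index, call. = FALSE)
}

#' Hydrolysis rate of a POC class to DOC
#'
#' First-order conversion `kappa_p[class] theta_p(t) [POC]`; the mass is
#' removed from the POC class and routed to the DOC pool named in
#' `params$hydrolysis_routing`.
#'
#' @param poc_conc POC concentration (g C m^-3), >= 0.
#' @param class_index `"lpoc"` or `"rpoc"`.
#' @inheritParams microbial_degradation_rate
#' @return hydrolysis rate (g C m^-3 d^-1).
#' @export
hydrolysis_rate <- function(poc_conc, class_index, t, params) {
  if (!class_index %in% names(params$kappa_p))
    stop("unknown POC class index: ", class_index, call. = FALSE)
  params$kappa_p[[class_index]] * temp_factor(t, params$kt_p, params$t_ref) *
    poc_conc
}

#' Salinity-dependent flocculation rate
#'
#' Bell-shaped curve peaking at the salinity of maximum coagulation `S_max`:
#' below the peak `kappa_f = kappa_fmax exp(-kappa_c1 (S - S_max)^2)`, at or
#' above it `kappa_f = kappa_fmax exp(-kappa_c2 (S_max - S)^2)`. Applied only
#' to the riverine chromophoric DOC classes, whose flocculated mass becomes
#' refractory POC.
#'
#' @param s salinity (dimensionless), >= 0; vectorized.
#' @param params a [kinetic_params()].
#' @return flocculation rate (d^-1).
#' @export
flocculation_rate <- function(s, params) {
  ifelse(s < params$s_max,
         params$kappa_fmax * exp(-params$kappa_c1 * (s - params$s_max)^2),
         params$kappa_fmax * exp(-params$kappa_c2 * (params$s_max - s)^2))
}

#' Concentration-dependent sediment settling velocity
#'
#' Michaelis-Menten-like saturating velocity
#' `w = w_max [ISS] / ([ISS] + k_ISS)`: the effective settling velocity
#' declines toward zero in dilute water and approaches `w_max` in the
#' sediment-laden river.
#'
#' @param iss_conc inorganic suspended sediment concentration (g m^-3).
#' @param params a [kinetic_params()].
#' @return settling velocity (m d^-1), in `[0, w_max)`.
#' @export
iss_settling_velocity <- function(iss_conc, params) {
  params$w_max * iss_conc / (iss_conc + params$k_iss)
}

#' Settling tendency between vertical layers
#'
#' Donor-based vertical flux divergence `w (C_above - C_here) / dz` for a
#' constant settling velocity; the top layer takes `C_above = 0` and the
#' bottom-layer export is recorded by the caller as deposition.
#'
#' @param conc_above concentration in the layer above (g m^-3); 0 at the top.
#' @param conc_here concentration in the current layer (g m^-3).
#' @param w settling velocity (m d^-1), >= 0.
#' @param dz layer thickness (m), > 0.
#' @return concentration tendency (g m^-3 d^-1).
#' @export
settling_flux <- function(conc_above, conc_here, w, dz) {
  if (any(dz <= 0)) stop("layer thickness must be positive", call. = FALSE)
  if (any(w < 0)) stop("settling velocity must be nonnegative", call. = FALSE)
  w * (conc_above - conc_here) / dz
}

#' Critical-shear resuspension flux
#'
#' Zero below the critical shear stress; linear in the excess stress above it:
#' `M_tau (tau - tau_crit)`. The chain stepper adds the resuspended mass to
#' the bottom layer, partitioned between inorganic sediment and the POC
#' classes and limited to the available benthic pool.
#'
#' @param tau bottom shear stress (Pa), >= 0; vectorized.
#' @param params a [kinetic_params()].
#' @return resuspension mass flux (g m^-2 s^-1).
#' @export
resuspension_flux <- function(tau, params) {
  params$m_tau * pmax(0, tau - params$tau_crit)
}

#' Phytoplankton growth, exudation and grazing rates
#'
#' Growth is `mu_max theta_B(t) min(PAR/(PAR + E_k), DIN/(DIN + K_N)) B`
#' (minimum of light and nitrogen limitation); a fixed fraction `kappa_b` of
#' growth is exuded as marine chromophoric DOC. Grazing is an implicit
#' second-order loss `nu_B theta_B(t) B^2`, of which fractions `f_b` become
#' labile and refractory POC and the remainder is routed to labile
#' non-chromophoric DOC and to remineralization. Nitrogen is consumed and
#' regenerated at a fixed C:N ratio.
#'
#' @param b phytoplankton carbon (g C m^-3).
#' @param din dissolved inorganic nitrogen (g N m^-3).
#' @param par mid-layer photosynthetically active radiation (W m^-2).
#' @param t temperature (degrees C).
#' @param group phytoplankton group, 1 or 2.
#' @param params a [kinetic_params()].
#' @return list with components `growth`, `exudation`, `predation` (all
#'   g C m^-3 d^-1), `poc_production` (named, per POC class),
#'   `ncdoc1_production`, `predation_remin`, `din_uptake` and `din_release`
#'   (g N m^-3 d^-1).
#' @export
phyto_rates <- function(b, din, par, t, group = 1, params) {
  stopifnot(b >= 0, din >= 0, par >= 0)
  theta <- temp_factor(t, params$kt_b, params$t_ref)
  lim <- pmin(par / (par + params$e_k), din / (din + params$k_n))
  growth <- params$mu_max[[group]] * theta * lim * b
  predation <- params$nu_b[[group]] * theta * b^2
  list(growth = growth,
       exudation = params$kappa_b * growth,
       predation = predation,
       poc_production = params$f_b * predation,
       ncdoc1_production = params$predation_to_ncdoc1 * predation,
       predation_remin = params$predation_to_remin * predation,
       din_uptake = growth / params$c_n_ratio,
       din_release = params$predation_to_remin * predation / params$c_n_ratio)
}
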
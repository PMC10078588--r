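# Hyperspectral light field: surface spectrum, total IOPs, diffuse
# attenuation, and Beer-Lambert propagation through the layered column.

# Planck constant (J s), speed of light (m s^-1), Avogadro number (mol^-1)
.h_planck <- 6.62607015e-34
.c_light <- 2.99792458e8
.n_avogadro <- 6.02214076e23

#' Surface downwelling irradiance spectrum
#'
#' Distributes broadband shortwave irradiance over the spectral grid. Only the
#' UV-visible fraction (0.43) of the shortwave flux is retained, and the
#' relative band weights follow a normalized black-body (Planck) spectral
#' distribution at the solar effective temperature restricted to the grid, so
#' that the band values summed times the band width integrate exactly to
#' 0.43 x shortwave.
#'
#' @param shortwave broadband shortwave irradiance (W m^-2), scalar >= 0.
#' @param grid a [spectral_grid()].
#' @param uv_vis_fraction fraction of shortwave in the UV-visible range.
#' @param t_sun black-body temperature (K).
#' @return per-band irradiance (W m^-2 nm^-1), length = number of bands.
#' @export
build_surface_spectrum <- function(shortwave, grid = spectral_grid(),
                                   uv_vis_fraction = 0.43, t_sun = 5778) {
  if (!is.finite(shortwave) || shortwave < 0)
    stop("shortwave irradiance must be a nonnegative number", call. = FALSE)
  wl_m <- grid$wavelengths * 1e-9
  planck <- wl_m^-5 / (exp(.h_planck * .c_light / (wl_m * 1.380649e-23 * t_sun)) - 1)
  w <- planck / sum(planck * grid$band_width)   # normalized: sum(w * dl) = 1
  uv_vis_fraction * shortwave * w
}

#' Total absorption spectrum from constituent concentrations
#'
#' Sums pure-water absorption with the mass-specific absorption of the three
#' chromophoric DOC classes, phytoplankton chlorophyll and suspended
#' particulate matter (SPM = inorganic suspended sediment + both POC classes).
#' Chlorophyll is derived from phytoplankton carbon with fixed
#' carbon-to-chlorophyll ratios per group.
#'
#' @param conc named numeric vector of concentrations (g m^-3): any subset of
#'   `cdoc_w`, `cdoc_ss`, `cdoc_m`, `lpoc`, `rpoc`, `iss`, `b1`, `b2`
#'   (phytoplankton carbon). Missing names are treated as zero.
#' @param iops an `iop_library`.
#' @param c_to_chl carbon:chlorophyll-a mass ratios (g C per g chl) for the
#'   two phytoplankton groups.
#' @return per-band total absorption `a_t` (m^-1).
#' @export
total_absorption <- function(conc, iops, c_to_chl = c(40.0, 28.6)) {
  conc <- .as_conc(conc)
  if (any(conc < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  spm <- conc[["iss"]] + conc[["lpoc"]] + conc[["rpoc"]]
  chl_mg <- 1000 * (conc[["b1"]] / c_to_chl[1] + conc[["b2"]] / c_to_chl[2])
  iops$a_w +
    iops$a_star_cdoc_w * conc[["cdoc_w"]] +
    iops$a_star_cdoc_ss * conc[["cdoc_ss"]] +
    iops$a_star_cdoc_m * conc[["cdoc_m"]] +
    iops$a_star_phi * chl_mg +
    iops$a_star_spm * spm
}

#' Total backscatter spectrum
#'
#' `b_b = bb_w + bb*_SPM x [SPM]` with SPM = ISS + LPOC + RPOC.
#' @inheritParams total_absorption
#' @return per-band backscatter (m^-1).
#' @export
total_backscatter <- function(conc, iops) {
  conc <- .as_conc(conc)
  spm <- conc[["iss"]] + conc[["lpoc"]] + conc[["rpoc"]]
  iops$bb_w + iops$bb_star_spm * spm
}

.opt_names <- c("cdoc_m", "cdoc_w", "cdoc_ss", "lpoc", "rpoc", "iss", "b1", "b2")

.as_conc <- function(conc) {
  out <- stats::setNames(numeric(length(.opt_names)), .opt_names)
  if (is.null(names(conc))) {
    if (length(conc) != 0 && length(conc) != length(.opt_names))
      stop("unnamed concentration vector must have length ",
           length(.opt_names), call. = FALSE)
    if (length(conc)) out[] <- conc
    return(out)
  }
  unknown <- setdiff(names(conc), .opt_names)
  if (length(unknown))
    conc <- conc[setdiff(names(conc), unknown)]  # transported non-optical pools
  out[names(conc)] <- conc
  out
}

#' Spectral diffuse attenuation coefficient
#'
#' Semi-analytical form combining total absorption and backscatter:
#' `kd = (1 + m0 theta_s) a_t + m1 (1 - m2 exp(-m3 a_t)) b_b`, with the
#' published coefficient set `(m0, m1, m2, m3) = (0.005, 4.18, 0.52, 10.8)`
#' and solar zenith angle `theta_s` in degrees.
#'
#' @param a_t per-band total absorption (m^-1), > 0.
#' @param b_b per-band total backscatter (m^-1), >= 0.
#' @param solar_zenith solar zenith angle, degrees, in `[0, 90)`.
#' @param coefs semi-analytical coefficients `(m0, m1, m2, m3)`.
#' @return per-band diffuse attenuation (m^-1); always >= `a_t`.
#' @export
kd_spectrum <- function(a_t, b_b, solar_zenith = 30,
                        coefs = c(0.005, 4.18, 0.52, 10.8)) {
  if (any(a_t <= 0)) stop("total absorption must be positive", call. = FALSE)
  if (any(b_b < 0)) stop("backscatter must be nonnegative", call. = FALSE)
  if (solar_zenith < 0 || solar_zenith >= 90)
    stop("solar zenith must be in [0, 90) degrees: no downwelling path",
         call. = FALSE)
  (1 + coefs[1] * solar_zenith) * a_t +
    coefs[2] * (1 - coefs[3] * exp(-coefs[4] * a_t)) * b_b
}

#' Propagate downwelling irradiance through vertical layers
#'
#' Beer-Lambert attenuation: irradiance at each lower interface equals the
#' irradiance above times `exp(-kd dz)` per band. Mid-layer irradiance (used
#' for rate calculations) is the interface value attenuated over half the
#' layer. PAR is the 400--700 nm integral.
#'
#' @param ed_surface per-band surface irradiance (W m^-2 nm^-1).
#' @param kd per-band diffuse attenuation: either a vector (uniform over
#'   layers) or a matrix `bands x layers` (m^-1).
#' @param layer_thicknesses vector of layer thicknesses (m), all > 0.
#' @param grid a [spectral_grid()].
#' @return object of class `irradiance_profile`: list with `ed` (bands x
#'   interfaces), `ed_mid` (bands x layers), `kd`, `par_interface`,
#'   `par_by_layer` (mid-layer PAR, W m^-2), `kd_par` (per layer, m^-1) and
#'   the grid.
#' @export
propagate <- function(ed_surface, kd, layer_thicknesses, grid = spectral_grid()) {
  dz <- layer_thicknesses
  if (any(dz <= 0)) stop("layer thicknesses must be positive", call. = FALSE)
  nb <- length(grid$wavelengths)
  nl <- length(dz)
  if (is.null(dim(kd))) kd <- matrix(kd, nrow = nb, ncol = nl)
  stopifnot(nrow(kd) == nb, ncol(kd) == nl, length(ed_surface) == nb)
  ed <- matrix(0, nb, nl + 1L)
  ed_mid <- matrix(0, nb, nl)
  ed[, 1L] <- ed_surface
  for (j in seq_len(nl)) {
    att <- exp(-kd[, j] * dz[j])
    ed[, j + 1L] <- ed[, j] * att
    ed_mid[, j] <- ed[, j] * exp(-kd[, j] * dz[j] / 2)
  }
  par_bands <- grid$wavelengths >= 400 & grid$wavelengths <= 700
  par_if <- colSums(ed[par_bands, , drop = FALSE]) * grid$band_width
  par_mid <- colSums(ed_mid[par_bands, , drop = FALSE]) * grid$band_width
  kd_par <- rep(NA_real_, nl)
  pos <- par_if[-length(par_if)] > 0 & par_if[-1L] > 0
  kd_par[pos] <- -log(par_if[-1L][pos] / par_if[-(nl + 1L)][pos]) / dz[pos]
  structure(list(ed = ed, ed_mid = ed_mid, kd = kd, dz = dz,
                 par_interface = par_if, par_by_layer = par_mid,
                 kd_par = kd_par, grid = grid),
            class = "irradiance_profile")
}

#' Photon flux of a spectral irradiance band
#'
#' Unit bridge from band energy flux to photon flux for quantum-yield
#' photochemistry: `ed x band_width x lambda x 1e-9 / (h c N_A)`.
#'
#' @param ed_band irradiance in the band (W m^-2 nm^-1), >= 0; vectorized.
#' @param lambda band centre wavelength (nm).
#' @param band_width band width (nm).
#' @return photon flux (mol photons m^-2 s^-1).
#' @export
photon_flux <- function(ed_band, lambda, band_width = 5) {
  ed_band * band_width * lambda * 1e-9 / (.h_planck * .c_light * .n_avogadro)
}
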
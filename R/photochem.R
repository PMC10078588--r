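# Photodegradation of chromophoric DOC: spectral photon absorption
# apportioned among absorbers drives apparent-quantum-yield mass transfers
# between CDOC classes, to non-chromophoric DOC, and weakly to a
# photomineralization (CO2) sink.

.cdoc_classes <- c("cdoc_w", "cdoc_ss", "cdoc_m")

#' Apparent quantum yield spectrum
#'
#' AQY (mol C transformed per mol photons absorbed) declining exponentially
#' with wavelength from its 290 nm value:
#' `AQY(lambda) = scale x phi0 x exp(-slope (lambda - 290))`. The scenario
#' multiplier `scale` is 1 for the baseline, 0 when photodegradation is
#' switched off and 2 when doubled.
#'
#' @param phi0 named AQY at 290 nm per CDOC class (`cdoc_w`, `cdoc_ss`,
#'   `cdoc_m`), mol C (mol photons)^-1. The marine class is an order of
#'   magnitude less photoreactive than the riverine classes by default.
#' @param slope spectral decay (nm^-1).
#' @param scale scenario multiplier (dimensionless, >= 0).
#' @return object of class `aqy_spectrum`.
#' @export
aqy_spectrum <- function(phi0 = c(cdoc_w = 5e-5, cdoc_ss = 5e-5, cdoc_m = 5e-6),
                         slope = 0.02, scale = 1) {
  stopifnot(all(phi0 >= 0), slope >= 0, scale >= 0)
  if (!all(.cdoc_classes %in% names(phi0)))
    stop("phi0 must name all CDOC classes: ",
         paste(.cdoc_classes, collapse = ", "), call. = FALSE)
  structure(list(phi0 = phi0[.cdoc_classes], slope = slope, scale = scale),
            class = "aqy_spectrum")
}

#' Evaluate an AQY spectrum on a wavelength axis
#' @param aqy an [aqy_spectrum()].
#' @param wavelengths wavelengths (nm).
#' @return matrix `bands x classes` of AQY values.
#' @export
aqy_eval <- function(aqy, wavelengths) {
  decay <- exp(-aqy$slope * (wavelengths - 290))
  out <- outer(decay, aqy$scale * aqy$phi0)
  colnames(out) <- names(aqy$phi0)
  out
}

#' Photodegradation transfer matrix
#'
#' Row-stochastic matrix giving, for each source CDOC class, the fraction of
#' photodegraded carbon routed to marine CDOC, to refractory non-chromophoric
#' DOC, and to the dissolved inorganic carbon (photomineralization) sink. The
#' direct mineralization fraction is kept small: photobleaching (carbon
#' retained in dissolved pools with absorption lost) dominates over direct
#' conversion to CO2.
#'
#' @param m matrix with rows `cdoc_w`, `cdoc_ss`, `cdoc_m` and columns
#'   `cdoc_m`, `ncdoc3`, `dic`; rows must sum to 1.
#' @return validated matrix of class `photo_transfer_matrix`.
#' @export
photo_transfer_matrix <- function(m = NULL) {
  if (is.null(m)) {
    m <- rbind(cdoc_w = c(cdoc_m = 0.30, ncdoc3 = 0.69, dic = 0.01),
               cdoc_ss = c(cdoc_m = 0.30, ncdoc3 = 0.69, dic = 0.01),
               cdoc_m = c(cdoc_m = 0.00, ncdoc3 = 0.99, dic = 0.01))
  }
  m <- as.matrix(m)
  if (!identical(rownames(m), .cdoc_classes) ||
      !identical(colnames(m), c("cdoc_m", "ncdoc3", "dic")))
    stop("transfer matrix must have rows cdoc_w, cdoc_ss, cdoc_m and ",
         "columns cdoc_m, ncdoc3, dic", call. = FALSE)
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12))
    stop("transfer matrix rows must be nonnegative and sum to 1",
         call. = FALSE)
  structure(m, class = c("photo_transfer_matrix", "matrix", "array"))
}

#' Photons absorbed per CDOC class in a layer
#'
#' Apportions the photons lost across a layer among absorbers by their share
#' of total absorption: per band, photons absorbed by class `c` per unit
#' volume are `(photon_flux(top) - photon_flux(bottom)) (a_c / a_t) / dz`.
#' Bands with zero total absorption contribute nothing. Summed over all
#' absorbers (classes, water, and the other constituents) the apportioned
#' photons equal the total absorbed photons.
#'
#' @param profile an `irradiance_profile` from [propagate()].
#' @param a_t per-band total absorption (m^-1).
#' @param a_class matrix `bands x classes` of class absorption (m^-1), each
#'   band-wise <= `a_t`.
#' @param layer layer index.
#' @return matrix `bands x classes` of volumetric photon absorption rates
#'   (mol photons m^-3 s^-1); `attr(, "total")` holds the per-class band sums.
#' @export
absorbed_photons_by_class <- function(profile, a_t, a_class, layer = 1) {
  a_class <- as.matrix(a_class)
  if (any(a_class > a_t + 1e-12 * pmax(1, a_t)))
    stop("class absorption exceeds total absorption in some band",
         call. = FALSE)
  wl <- profile$grid$wavelengths
  bw <- profile$grid$band_width
  dz <- profile$dz[layer]
  pf_top <- photon_flux(profile$ed[, layer], wl, bw)
  pf_bot <- photon_flux(profile$ed[, layer + 1L], wl, bw)
  share <- a_class / ifelse(a_t > 0, a_t, 1)
  share[a_t <= 0, ] <- 0
  out <- (pf_top - pf_bot) / dz * share
  structure(out, total = colSums(out))
}

#' Apply photodegradation to a box state
#'
#' Converts per-class photon absorption into carbon mass transfer using the
#' AQY spectrum: the loss from class `c` is
#' `sum_lambda AQY_c(lambda) photons_c(lambda) x 12.011` (g C m^-3 s^-1),
#' limited so no class is driven below zero within the step, and distributed
#' to marine CDOC, refractory NCDOC and the DIC ledger by the transfer
#' matrix. A zero AQY scale (photodegradation switched off) yields zero
#' tendencies.
#'
#' @param state named concentrations (g m^-3) including the CDOC classes.
#' @param photons_by_class matrix `bands x classes` (mol photons m^-3 s^-1).
#' @param aqy an [aqy_spectrum()].
#' @param matrix a [photo_transfer_matrix()].
#' @param dt time step (days) used for the availability limit.
#' @param wavelengths band centres (nm) matching `photons_by_class` rows.
#' @return list with `tendency` (named g C m^-3 d^-1 for `cdoc_w`, `cdoc_ss`,
#'   `cdoc_m`, `ncdoc3`) and `dic_rate` (g C m^-3 d^-1 to the
#'   photomineralization ledger).
#' @export
photo_transform <- function(state, photons_by_class, aqy, matrix, dt,
                            wavelengths) {
  matrix <- photo_transfer_matrix(unclass(matrix))
  aqy_m <- aqy_eval(aqy, wavelengths)      # bands x classes
  photons_by_class <- as.matrix(photons_by_class)
  if (any(photons_by_class < 0))
    stop("photon absorption must be nonnegative", call. = FALSE)
  cls <- .cdoc_classes
  loss <- colSums(aqy_m[, cls, drop = FALSE] *
                    photons_by_class[, cls, drop = FALSE]) * 12.011 * 86400
  # limit: no class loses more than its available mass within dt
  avail <- vapply(cls, function(k) state[[k]], numeric(1))
  if (dt > 0) loss <- pmin(loss, avail / dt)
  tend <- stats::setNames(numeric(4), c(cls, "ncdoc3"))
  tend[cls] <- -loss
  gains <- drop(loss %*% unclass(matrix)[cls, , drop = FALSE])
  tend["cdoc_m"] <- tend["cdoc_m"] + gains[["cdoc_m"]]
  tend["ncdoc3"] <- tend["ncdoc3"] + gains[["ncdoc3"]]
  list(tendency = tend, dic_rate = gains[["dic"]])
}
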
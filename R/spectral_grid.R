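#' Spectral wavelength grid
#'
#' Defines the wavelength axis on which all inherent optical properties,
#' irradiance spectra and photochemical quantities are evaluated. The default
#' covers the UV-visible range 285--700 nm at 5 nm spacing (84 bands), the
#' resolution at which the simulator attenuates light and apportions photons.
#'
#' @param from,to first and last band centre (nm).
#' @param by band width (nm).
#' @return An object of class `spectral_grid`: a list with `wavelengths`
#'   (ascending numeric vector, nm) and `band_width` (nm).
#' @examples
#' g <- spectral_grid()
#' length(g$wavelengths) # 84
#' @export
spectral_grid <- function(from = 285, to = 700, by = 5) {
  stopifnot(from > 0, to > from, by > 0)
  wl <- seq(from, to, by = by)
  structure(list(wavelengths = wl, band_width = by), class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %d bands, %g-%g nm at %g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$band_width))
  invisible(x)
}

# Pure-water absorption (m^-1), coarse table assembled from published
# laboratory determinations (UV and visible), linearly interpolated to the
# working grid.
.water_absorption_table <- function() {
  data.frame(
    wavelength = c(285, 300, 320, 340, 360, 380, 400, 420, 440, 460, 480,
                   500, 520, 540, 560, 580, 600, 620, 640, 660, 680, 700),
    a_w = c(0.0280, 0.0141, 0.0082, 0.0056, 0.0046, 0.0055, 0.00663,
            0.00530, 0.00635, 0.00922, 0.0127, 0.0204, 0.0409, 0.0474,
            0.0619, 0.0856, 0.2224, 0.2644, 0.3292, 0.4098, 0.4650, 0.6240)
  )
}

#' Default inherent optical property library
#'
#' Mass-specific absorption and backscatter spectra for every optically active
#' constituent, evaluated on a common spectral grid. Chromophoric DOC (CDOC)
#' classes use exponential spectra `a*(lambda) = a*_300 exp(-S (lambda - 300))`
#' with class-specific slopes (winter riverine steeper than spring/summer,
#' marine steepest) and `a*_300` magnitudes placed in the riverine range of
#' absorption-to-carbon ratios (roughly 2--4 m^2 g C^-1 at 300 nm).
#' Phytoplankton absorption is a chlorophyll-specific two-peak shape,
#' suspended-particulate absorption an exponential, and particulate
#' backscatter spectrally flat. All spectra are user-overridable, either by
#' argument or via [read_iops()].
#'
#' @param grid a [spectral_grid()].
#' @param a_star_300 named numeric: CDOC absorption per carbon mass at 300 nm
#'   (m^2 g C^-1) for classes `w` (winter riverine), `ss` (spring/summer
#'   riverine) and `m` (marine).
#' @param s_cdoc named numeric: CDOC spectral slopes (nm^-1), same classes.
#' @param bb_star_spm spectrally flat SPM-specific backscatter (m^2 g^-1).
#' @return Object of class `iop_library`: list of per-band vectors `a_w`,
#'   `a_star_cdoc_w`, `a_star_cdoc_ss`, `a_star_cdoc_m`, `a_star_phi`,
#'   `a_star_spm`, `bb_w`, `bb_star_spm`, plus the `grid`.
#' @export
default_iops <- function(grid = spectral_grid(),
                         a_star_300 = c(w = 3.2, ss = 2.6, m = 1.2),
                         s_cdoc = c(w = 0.018, ss = 0.016, m = 0.022),
                         bb_star_spm = 0.01) {
  wl <- grid$wavelengths
  tab <- .water_absorption_table()
  a_w <- stats::approx(tab$wavelength, tab$a_w, xout = wl, rule = 2)$y
  cdoc <- function(cls) a_star_300[[cls]] * exp(-s_cdoc[[cls]] * (wl - 300))
  # chlorophyll-specific absorption: blue and red peaks plus a UV shoulder
  a_phi <- 0.05 * exp(-((wl - 440)^2) / (2 * 30^2)) +
    0.02 * exp(-((wl - 675)^2) / (2 * 12^2)) +
    0.02 * exp(-((wl - 310)^2) / (2 * 40^2))
  a_spm <- 0.04 * exp(-0.011 * (wl - 440))
  bb_w <- 0.0019 * (400 / wl)^4.32
  iops <- list(
    a_w = a_w,
    a_star_cdoc_w = cdoc("w"),
    a_star_cdoc_ss = cdoc("ss"),
    a_star_cdoc_m = cdoc("m"),
    a_star_phi = a_phi,
    a_star_spm = a_spm,
    bb_w = bb_w,
    bb_star_spm = rep(bb_star_spm, length(wl)),
    grid = grid
  )
  validate_iops(structure(iops, class = "iop_library"))
}

#' Validate an IOP library
#'
#' Checks that every spectrum is nonnegative, defined on the same grid, and
#' that CDOC spectra decay monotonically above 350 nm.
#' @param iops an `iop_library`.
#' @return the validated object, invisibly usable.
#' @export
validate_iops <- function(iops) {
  wl <- iops$grid$wavelengths
  spectra <- setdiff(names(iops), "grid")
  for (nm in spectra) {
    v <- iops[[nm]]
    if (length(v) != length(wl))
      stop("IOP spectrum '", nm, "' is not defined on the library grid",
           call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0))
      stop("IOP spectrum '", nm, "' must be finite and nonnegative",
           call. = FALSE)
  }
  above <- wl > 350
  for (nm in c("a_star_cdoc_w", "a_star_cdoc_ss", "a_star_cdoc_m")) {
    if (sum(above) > 1 && any(diff(iops[[nm]][above]) > 0))
      stop("CDOC spectrum '", nm, "' must decay monotonically above 350 nm",
           call. = FALSE)
  }
  iops
}

#' Read / write an IOP library as CSV
#'
#' Plain-text interchange format: columns `wavelength_nm`, `a_w`,
#' `a_star_cdoc_w`, `a_star_cdoc_ss`, `a_star_cdoc_m`, `a_star_phi`,
#' `a_star_spm`, `bb_w`, `bb_star_spm`.
#'
#' @param path CSV file path.
#' @return `read_iops()` returns an `iop_library`; `write_iops()` returns
#'   `path` invisibly.
#' @export
read_iops <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "a_w", "a_star_cdoc_w", "a_star_cdoc_ss",
            "a_star_cdoc_m", "a_star_phi", "a_star_spm", "bb_w", "bb_star_spm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("IOP CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  wl <- df$wavelength_nm
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelength_nm must be strictly increasing", call. = FALSE)
  bw <- if (length(wl) > 1) diff(wl)[1] else 5
  grid <- structure(list(wavelengths = wl, band_width = bw),
                    class = "spectral_grid")
  iops <- c(as.list(df[setdiff(need, "wavelength_nm")]), list(grid = grid))
  validate_iops(structure(iops, class = "iop_library"))
}

#' @rdname read_iops
#' @param iops an `iop_library`.
#' @export
write_iops <- function(iops, path) {
  df <- data.frame(wavelength_nm = iops$grid$wavelengths)
  for (nm in c("a_w", "a_star_cdoc_w", "a_star_cdoc_ss", "a_star_cdoc_m",
               "a_star_phi", "a_star_spm", "bb_w", "bb_star_spm"))
    df[[nm]] <- iops[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
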
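test_that("surface spectrum integrates to the UV-visible fraction of shortwave", {
  g <- spectral_grid()
  spec <- build_surface_spectrum(200, g)
  expect_equal(sum(spec) * g$band_width, 86)        # 0.43 x 200
  expect_equal(build_surface_spectrum(0, g), rep(0, 84))
  # weights are identical up to scale for different inputs
  s1 <- build_surface_spectrum(100, g)
  s2 <- build_surface_spectrum(350, g)
  expect_equal(s2 / sum(s2), s1 / sum(s1), tolerance = 1e-12)
  expect_error(build_surface_spectrum(-1, g), "nonnegative")
})

test_that("spectral integral is stable under grid refinement", {
  coarse <- spectral_grid(285, 700, 5)
  fine <- spectral_grid(285, 700, 2.5)
  ic <- sum(build_surface_spectrum(200, coarse)) * coarse$band_width
  iff <- sum(build_surface_spectrum(200, fine)) * fine$band_width
  expect_lt(abs(iff - ic) / ic, 0.005)
})

test_that("total absorption is the water spectrum plus linear constituent terms", {
  iops <- default_iops()
  a0 <- total_absorption(c(cdoc_w = 0), iops)
  expect_equal(a0, iops$a_w)
  conc <- c(cdoc_w = 1.5, cdoc_ss = 2, cdoc_m = 0.3, lpoc = 0.5, rpoc = 1,
            iss = 20, b1 = 0.1, b2 = 0.2)
  a1 <- total_absorption(conc, iops)
  a2 <- total_absorption(2 * conc, iops)
  expect_equal(a2 - iops$a_w, 2 * (a1 - iops$a_w), tolerance = 1e-12)
  # single CDOC class at 2 g C m^-3: hand summation on three bands
  a <- total_absorption(c(cdoc_ss = 2), iops)
  for (band in c(1, 40, 84))
    expect_equal(a[band] - iops$a_w[band], 2 * iops$a_star_cdoc_ss[band])
  expect_error(total_absorption(c(cdoc_w = -1), iops), "nonnegative")
})

test_that("semi-analytical kd matches the closed form and its limits", {
  # absorption-only limit
  expect_equal(kd_spectrum(c(0.5, 1, 2), c(0, 0, 0), solar_zenith = 0),
               c(0.5, 1, 2))
  # direct evaluation of the closed form
  kd <- kd_spectrum(1.0, 0.01, solar_zenith = 0)
  expect_equal(kd, 1 + 4.18 * (1 - 0.52 * exp(-10.8)) * 0.01,
               tolerance = 1e-12)
  expect_equal(kd, 1.0418, tolerance = 1e-4)
  # kd >= a_t and nondecreasing in absorption and backscatter
  a <- seq(0.05, 3, length.out = 50)
  expect_true(all(kd_spectrum(a, 0.02) >= a))
  expect_true(all(diff(kd_spectrum(a, 0.02)) > 0))
  expect_true(all(kd_spectrum(1, c(0.01, 0.02)) ==
                    cummax(kd_spectrum(1, c(0.01, 0.02)))))
  expect_error(kd_spectrum(1, 0.01, solar_zenith = 90), "zenith")
})

test_that("Beer-Lambert propagation attenuates, composes and conserves monotonicity", {
  g <- spectral_grid()
  ed0 <- build_surface_spectrum(300, g)
  p1 <- propagate(ed0, rep(1, 84), 1, g)
  expect_equal(p1$ed[, 2] / p1$ed[, 1], rep(exp(-1), 84))
  # transparent water
  p0 <- propagate(ed0, rep(0, 84), c(1, 1), g)
  expect_equal(p0$ed[, 3], ed0)
  # two half layers equal one full layer at the bottom interface
  kd <- runif(84, 0.1, 2)
  pa <- propagate(ed0, matrix(kd, 84, 2), c(1, 1), g)
  pb <- propagate(ed0, matrix(kd, 84, 1), 2, g)
  expect_equal(pa$ed[, 3], pb$ed[, 2], tolerance = 1e-12)
  # energy monotonicity with depth in every band, random states
  set.seed(42)
  for (i in 1:5) {
    iops <- default_iops()
    conc <- c(cdoc_w = runif(1, 0, 5), cdoc_ss = runif(1, 0, 5),
              cdoc_m = runif(1, 0, 1), lpoc = runif(1, 0, 2),
              rpoc = runif(1, 0, 3), iss = runif(1, 0, 100),
              b1 = runif(1, 0, 0.5), b2 = runif(1, 0, 0.5))
    kd <- kd_spectrum(total_absorption(conc, iops),
                      total_backscatter(conc, iops))
    pr <- propagate(ed0, kd, rep(0.5, 10), g)
    expect_true(all(diff(t(pr$ed)) <= 1e-14))
  }
})

test_that("water-only kd_par matches a brute-force band-by-band oracle", {
  g <- spectral_grid()
  iops <- default_iops()
  ed0 <- build_surface_spectrum(250, g)
  kd <- kd_spectrum(iops$a_w, iops$bb_w, solar_zenith = 30)
  dz <- rep(0.5, 8)
  prof <- propagate(ed0, kd, dz, g)
  # oracle: loop over bands and interfaces explicitly
  par_bands <- which(g$wavelengths >= 400)
  ed <- matrix(0, length(g$wavelengths), length(dz) + 1)
  ed[, 1] <- ed0
  for (j in seq_along(dz)) for (b in seq_along(g$wavelengths))
    ed[b, j + 1] <- ed[b, j] * exp(-kd[b] * dz[j])
  par_if <- colSums(ed[par_bands, ]) * g$band_width
  kd_par_oracle <- -log(par_if[-1] / par_if[-length(par_if)]) / dz
  expect_equal(prof$kd_par, kd_par_oracle, tolerance = 1e-12)
})

test_that("photon flux implements the energy-to-photons unit bridge", {
  expect_equal(photon_flux(0, 400), 0)
  expect_equal(photon_flux(1, 400, 5), 1.672e-5, tolerance = 1e-3)
  expect_equal(photon_flux(1, 400, 5),
               5 * 400e-9 / (6.62607015e-34 * 2.99792458e8 * 6.02214076e23),
               tolerance = 1e-12)
  expect_equal(photon_flux(1, 800, 5), 2 * photon_flux(1, 400, 5))
  expect_equal(photon_flux(3, 500, 5), 3 * photon_flux(1, 500, 5))
})

test_that("IOP libraries validate and round-trip through CSV", {
  iops <- default_iops()
  f <- tempfile(fileext = ".csv")
  write_iops(iops, f)
  iops2 <- read_iops(f)
  for (nm in setdiff(names(iops), "grid"))
    expect_equal(iops2[[nm]], iops[[nm]], tolerance = 1e-12)
  bad <- iops
  bad$a_w[3] <- -1
  expect_error(validate_iops(bad), "nonnegative")
})
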
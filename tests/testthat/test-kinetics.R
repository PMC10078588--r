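params <- kinetic_params()

test_that("temperature response is exponential around the reference", {
  expect_equal(temp_factor(20, 0.069, 20), 1.0)
  expect_equal(temp_factor(30, 0.069, 20), exp(0.69))
  expect_equal(temp_factor(30, 0.069, 20), 1.9937, tolerance = 1e-4)
  t <- seq(-2, 30, by = 0.5)
  expect_true(all(diff(temp_factor(t)) > 0))
})

test_that("microbial degradation is first order with the tabulated rates", {
  expect_equal(microbial_degradation_rate(1.0, "labile", 20, params), 0.025)
  expect_equal(microbial_degradation_rate(1.0, "ncdoc3", 20, params), 0.001)
  # refractory e-folding time 1000 d at reference temperature
  expect_equal(1 / microbial_degradation_rate(1, "refractory", 20, params),
               1000)
  p0 <- kinetic_params(kappa_c = c(labile = 0, semilabile = 0,
                                   refractory = 0))
  expect_equal(microbial_degradation_rate(5, "labile", 25, p0), 0)
  expect_error(microbial_degradation_rate(1, "plutonium", 20, params),
               "unknown DOC class")
})

test_that("POC hydrolysis rates give 23 and 116 day half-lives", {
  expect_equal(log(2) / hydrolysis_rate(1, "lpoc", 20, params), 23,
               tolerance = 0.01)
  expect_equal(log(2) / hydrolysis_rate(1, "rpoc", 20, params), 116,
               tolerance = 0.005)
  expect_equal(hydrolysis_rate(0, "lpoc", 20, params), 0)
})

test_that("flocculation curve evaluates both branches and peaks at S_max", {
  pf <- kinetic_params(kappa_fmax = 0.1)
  expect_equal(flocculation_rate(1.0, pf), 0.1)
  expect_equal(flocculation_rate(0, pf), 0.1 * exp(-5))
  expect_equal(flocculation_rate(0, pf), 6.738e-4, tolerance = 1e-4)
  expect_equal(flocculation_rate(2, pf), 0.1 * exp(-0.25))
  expect_equal(flocculation_rate(2, pf), 0.07788, tolerance = 1e-4)
  # brute-force scan: continuous at S_max, maximum exactly kappa_fmax
  s <- seq(0, 30, by = 1e-3)
  kf <- flocculation_rate(s, pf)
  expect_equal(max(kf), 0.1)
  expect_equal(s[which.max(kf)], 1.0)
  expect_lt(max(abs(diff(kf))), 1e-3)   # no jump anywhere on the scan
  # baseline parameter set switches flocculation off entirely
  expect_equal(flocculation_rate(s, params), rep(0, length(s)))
})

test_that("sediment settling velocity saturates like Michaelis-Menten", {
  expect_equal(iss_settling_velocity(0, params), 0)
  expect_equal(iss_settling_velocity(51, params), 1.0)   # half saturation
  expect_equal(iss_settling_velocity(1e9, params), 2.0, tolerance = 1e-6)
  conc <- seq(0, 500, by = 5)
  w <- iss_settling_velocity(conc, params)
  expect_true(all(diff(w) > 0) && all(w < 2))
})

test_that("settling tendencies telescope to bottom-layer export", {
  set.seed(3)
  conc <- runif(10, 0, 8)
  w <- 0.7
  dz <- 0.5
  tend <- settling_flux(c(0, conc[-10]), conc, w, dz)
  # column-integrated tendency equals minus the export through the bottom
  expect_equal(sum(tend * dz), -w * conc[10], tolerance = 1e-12)
  # uniform column: zero interior tendency
  u <- settling_flux(c(0, rep(2, 9)), rep(2, 10), w, dz)
  expect_equal(u[-1], rep(0, 9))
  expect_equal(settling_flux(c(0, conc[-10]), conc, 0, dz), rep(0, 10))
})

test_that("resuspension is zero below and linear above the critical stress", {
  expect_equal(resuspension_flux(0.005, params), 0)
  expect_equal(resuspension_flux(0.003, params), 0)
  expect_equal(resuspension_flux(0.015, params), 1e-7)
  tau <- seq(0, 0.05, by = 1e-3)
  fl <- resuspension_flux(tau, params)
  expect_true(all(fl[tau <= 0.005] == 0))
  expect_true(all(diff(fl) >= 0))
})

test_that("phytoplankton rates follow the limitation and grazing formulation", {
  # dark limit: no growth, grazing unchanged
  dark <- phyto_rates(1, 1, 0, 20, 1, params)
  expect_equal(dark$growth, 0)
  expect_equal(dark$predation, 1.5)
  expect_equal(dark$poc_production, c(lpoc = 0.15, rpoc = 0.75))
  # exudation is the fixed fraction of growth
  lit <- phyto_rates(2, 1, 200, 20, 1, params)
  expect_equal(lit$exudation, 0.2 * lit$growth)
  expect_gt(lit$growth, 0)
  # nitrogen bookkeeping at fixed C:N
  expect_equal(lit$din_uptake, lit$growth / params$c_n_ratio)
})

test_that("rate functions are homogeneous of their stated order", {
  lam <- 3.7
  expect_equal(microbial_degradation_rate(lam * 2, "labile", 12, params),
               lam * microbial_degradation_rate(2, "labile", 12, params))
  expect_equal(hydrolysis_rate(lam * 1.1, "rpoc", 8, params),
               lam * hydrolysis_rate(1.1, "rpoc", 8, params))
  p1 <- phyto_rates(1, 50, 500, 20, 2, params)     # nutrient/light replete
  p2 <- phyto_rates(lam, 50, 500, 20, 2, params)
  expect_equal(p2$predation, lam^2 * p1$predation) # second order in biomass
})

test_that("instantaneous carbon tendencies sum to zero against a term-by-term oracle", {
  set.seed(11)
  for (rep in 1:10) {
    st <- as.list(stats::setNames(runif(12, 0, 6), chain_constituents()))
    tC <- runif(1, 0, 25)
    s <- runif(1, 0, 30)
    pf <- kinetic_params(kappa_fmax = 0.1)
    tend <- stats::setNames(numeric(12), chain_constituents())
    sinks <- 0   # CO2 ledger
    sources <- 0 # primary production
    # microbial degradation of the six DOC pools
    for (pool in names(pf$doc_class_map)) {
      r <- microbial_degradation_rate(st[[pool]], pool, tC, pf)
      tend[pool] <- tend[pool] - r
      sinks <- sinks + r
    }
    # hydrolysis
    for (pool in c("lpoc", "rpoc")) {
      r <- hydrolysis_rate(st[[pool]], pool, tC, pf)
      tend[pool] <- tend[pool] - r
      tend[pf$hydrolysis_routing[[pool]]] <-
        tend[pf$hydrolysis_routing[[pool]]] + r
    }
    # flocculation
    for (pool in c("cdoc_w", "cdoc_ss")) {
      r <- flocculation_rate(s, pf) * st[[pool]]
      tend[pool] <- tend[pool] - r
      tend["rpoc"] <- tend["rpoc"] + r
    }
    # phytoplankton
    for (g in 1:2) {
      bp <- c("b1", "b2")[g]
      pr <- phyto_rates(st[[bp]], st$din, 80, tC, g, pf)
      tend[bp] <- tend[bp] + pr$growth - pr$exudation - pr$predation
      tend["cdoc_m"] <- tend["cdoc_m"] + pr$exudation
      tend["lpoc"] <- tend["lpoc"] + pr$poc_production[["lpoc"]]
      tend["rpoc"] <- tend["rpoc"] + pr$poc_production[["rpoc"]]
      tend["ncdoc1"] <- tend["ncdoc1"] + pr$ncdoc1_production
      sinks <- sinks + pr$predation_remin
      sources <- sources + pr$growth
    }
    carbon <- setdiff(chain_constituents(), c("iss", "din"))
    net <- sum(tend[carbon]) + sinks - sources
    scale <- sum(abs(tend[carbon])) + sinks + sources
    expect_lt(abs(net) / scale, 1e-12)
    expect_true(all(tend[carbon] + 1e-12 >= -sapply(st[carbon], max) * 10))
  }
})

test_that("parameter constructor rejects unknown names and bad fractions", {
  expect_error(kinetic_params(kappa_zz = 1), "unknown kinetic parameter")
  expect_error(kinetic_params(f_b = c(lpoc = 0.6, rpoc = 0.6)), "sum")
})
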
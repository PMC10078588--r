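test_that("advection conserves mass and respects the trivial limits", {
  g <- small_geometry()
  p <- null_params()
  zero_bc <- stats::setNames(numeric(12), chain_constituents())
  # pulse injected in box 1: chain stock plus export equals the injection
  st <- chain_state(g, p, river_conc = zero_bc, ocean_conc = zero_bc)
  st$conc["cdoc_ss", 1:3] <- c(9, 3, 1)   # the three layers of box 1
  injected <- sum(st$conc["cdoc_ss", 1:3]) * g$volumes[1] / 3
  for (i in 1:600)
    st <- advect(st, g, discharge = 6000, boundary_conc = zero_bc, dt = 0.05)
  vol_cell <- rep(g$volumes / 3, each = 3)
  remaining <- sum(st$conc["cdoc_ss", ] * vol_cell)
  exported <- st$ledger$outflow[["cdoc_ss"]]
  expect_equal(remaining + exported, injected, tolerance = 1e-10)
  expect_gt(exported / injected, 0.5)
  # Q = 0 moves nothing
  st0 <- chain_state(g, p, river_conc = zero_bc, ocean_conc = zero_bc)
  st0$conc["iss", ] <- 5
  st0b <- advect(st0, g, 0, zero_bc, dt = 0.05)
  expect_equal(st0b$conc, st0$conc)
  expect_equal(sum(attr(st0b, "interface_mass")), 0)
})

test_that("uniform concentration under steady flow gives equal interface fluxes", {
  g <- chain_geometry()
  p <- null_params()
  bc <- stats::setNames(rep(2, 12), chain_constituents())
  st <- chain_state(g, p, river_conc = bc, ocean_conc = bc)
  st <- advect(st, g, 10000, bc, dt = 0.01)
  m <- attr(st, "interface_mass")
  expect_equal(unname(m[, "lpoc"]),
               rep(10000 * 2 * 86400 * 0.01, nrow(m)), tolerance = 1e-12)
})

test_that("the CFL guard aborts naming the limiting box", {
  g <- chain_geometry(names = c("tiny", "big"), areas = c(1e4, 1e9),
                      depths = c(2, 10), salinity = c(0, 20))
  st <- chain_state(g, null_params())
  bc <- stats::setNames(numeric(12), chain_constituents())
  expect_error(advect(st, g, 5000, bc, dt = 0.1), "tiny")
})

test_that("null dynamics leave the state unchanged", {
  g <- small_geometry()
  p <- null_params()
  st <- random_state(g, p, seed = 2)
  before <- st$conc
  opt <- chain_optics(aqy = aqy_spectrum(scale = 0))
  for (i in 1:20)
    st <- chain_step(st, closed_forcing_t(), g, p, opt, dt = 0.05)
  expect_equal(st$conc, before, tolerance = 1e-14)
  expect_equal(chain_audit(st, g)$relative, 0, tolerance = 1e-14)
})

test_that("a closed system conserves total carbon over 1000 steps", {
  g <- small_geometry()
  # no transport, no settling, no resuspension, no light, no microbes:
  # hydrolysis, flocculation and grazing keep cycling carbon internally
  p <- kinetic_params(kappa_c = c(labile = 0, semilabile = 0, refractory = 0),
                      w_p = c(lpoc = 0, rpoc = 0), w_max = 0, m_tau = 0,
                      kappa_fmax = 0.1)
  st <- random_state(g, p, seed = 8)
  opt <- chain_optics(aqy = aqy_spectrum(scale = 0))
  f <- closed_forcing_t()
  for (i in 1:1000)
    st <- chain_step(st, f, g, p, opt, dt = 0.01)
  audit <- chain_audit(st, g)
  expect_lt(audit$relative, 1e-10)
  expect_true(all(st$conc >= 0))
})

test_that("single-process decays match their closed forms within 1 percent", {
  g <- one_box_geometry()
  opt <- chain_optics(aqy = aqy_spectrum(scale = 0))
  f <- closed_forcing_t()
  run_decay <- function(params, pool, days, dt = 0.01) {
    st <- chain_state(g, params,
                      river_conc = stats::setNames(numeric(12),
                                                   chain_constituents()))
    st$conc[pool, ] <- 1
    for (i in seq_len(round(days / dt)))
      st <- chain_step(st, f, g, params, opt, dt = dt)
    mean(st$conc[pool, ])
  }
  # labile DOC: half-life ln 2 / 0.025 = 27.73 d
  p1 <- null_params()
  p1$kappa_c["labile"] <- 0.025
  expect_equal(run_decay(p1, "ncdoc1", log(2) / 0.025), 0.5,
               tolerance = 0.01)
  # labile POC hydrolysis: half-life 23.1 d (mass reappears as NCDOC1)
  p2 <- null_params()
  p2$kappa_p["lpoc"] <- 0.03
  expect_equal(run_decay(p2, "lpoc", log(2) / 0.03), 0.5, tolerance = 0.01)
  # flocculation at the optimum salinity: rate 0.1 per day
  g_salt <- one_box_geometry(salinity = 1.0)
  p3 <- null_params(kappa_fmax = 0.1)
  st <- chain_state(g_salt, p3,
                    river_conc = stats::setNames(numeric(12),
                                                 chain_constituents()))
  st$conc["cdoc_w", ] <- 1
  for (i in seq_len(round(log(2) / 0.1 / 0.01)))
    st <- chain_step(st, f, g_salt, p3, opt, dt = 0.01)
  expect_equal(mean(st$conc["cdoc_w", ]), 0.5, tolerance = 0.01)
})

test_that("runs are deterministic given configuration and seed", {
  cfg <- small_config(days = 6)
  r1 <- run_chain(cfg)
  r2 <- run_chain(cfg)
  expect_identical(r1$conc, r2$conc)
  expect_identical(r1$interface_flux, r2$interface_flux)
  expect_identical(r1$ledger, r2$ledger)
})

test_that("a full-length run completes with a closed ledger and sane output", {
  r <- run_chain(small_config(days = 30, dt = 0.02))
  expect_lt(r$audit$relative, 1e-6)
  expect_true(all(r$conc >= 0))
  expect_true(all(is.finite(r$kd_par)))
  expect_true(all(r$kd_par > 0))
  expect_equal(dim(r$conc), c(30, 12, 2, 3))
  expect_equal(r$spinup_days, 45)
})

test_that("halving the time step barely changes the day-90 DOC stock", {
  doc_pools <- c("cdoc_m", "cdoc_w", "cdoc_ss", "ncdoc1", "ncdoc2", "ncdoc3")
  r1 <- run_chain(chain_config(days = 90, dt = 0.01))
  r2 <- run_chain(chain_config(days = 90, dt = 0.005))
  s1 <- domain_stock(r1, doc_pools)[90]
  s2 <- domain_stock(r2, doc_pools)[90]
  expect_lt(abs(s1 - s2) / s1, 0.005)
})

test_that("a conservative tracer dilutes monotonically along the chain", {
  # river-sourced refractory NCDOC with every reaction off: at steady state
  # each box's concentration is a mixture of upstream water and cannot
  # exceed the upstream concentration
  g <- chain_geometry()
  p <- null_params()
  bc <- stats::setNames(numeric(12), chain_constituents())
  bc["ncdoc3"] <- 6
  zero <- stats::setNames(numeric(12), chain_constituents())
  st <- chain_state(g, p, river_conc = zero, ocean_conc = zero)
  opt <- chain_optics(aqy = aqy_spectrum(scale = 0))
  f <- c(closed_forcing_t(), list())
  f$discharge <- 15000
  f$boundary_conc <- bc
  for (i in 1:4000) st <- chain_step(st, f, g, p, opt, dt = 0.05)
  prof <- vapply(seq_along(g$names), function(b)
    mean(st$conc["ncdoc3", (b - 1) * 10 + 1:10]), 0)
  expect_true(all(diff(prof) <= 1e-9))
  expect_equal(prof[1], 6, tolerance = 0.01)
})
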
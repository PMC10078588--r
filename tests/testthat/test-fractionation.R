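make_records <- function(a300_values, doc_values, slope = 0.017,
                         months = rep(c(1, 5, 8), length.out = length(a300_values))) {
  g <- spectral_grid()
  shape <- exp(-slope * (g$wavelengths - 300))
  lapply(seq_along(a300_values), function(i)
    cdom_record(sprintf("2019-%02d-10", months[i]), doc_values[i],
                a300_values[i] * shape, g))
}

test_that("the DOC ~ a300 intercept recovers non-chromophoric DOC", {
  a300 <- seq(2, 40, length.out = 12)
  recs <- make_records(a300, 0.48 + 0.2 * a300)
  fit <- ncdoc_intercept(recs)
  expect_equal(fit$intercept, 0.48, tolerance = 1e-10)
  expect_equal(fit$slope, 0.2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # all-DOC-equal degenerate direction: slope 0, intercept = DOC
  flat <- ncdoc_intercept(make_records(a300, rep(3.2, 12)))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_equal(flat$intercept, 3.2, tolerance = 1e-10)
  expect_error(ncdoc_intercept(recs[1:2]), "at least 3")
  expect_error(ncdoc_intercept(make_records(rep(5, 4), 1:4)), "zero variance")
})

test_that("noisy regression recovers the intercept within three standard errors", {
  set.seed(404)
  n <- 50
  a300 <- runif(n, 2, 40)
  doc <- 0.48 + 0.2 * a300 + rnorm(n, 0, 0.05)
  fit <- ncdoc_intercept(make_records(a300, pmax(doc, 0.01)))
  expect_lt(abs(fit$intercept - 0.48), 3 * fit$se)
})

test_that("seasonal mass-specific spectra follow from construction", {
  g <- spectral_grid()
  iops <- default_iops()
  # one record: a* equals a_cdom / CDOC exactly
  r1 <- cdom_record("2019-01-10", doc = 4, a_cdom = iops$a_star_cdoc_w * 2.5,
                    grid = g)
  sp1 <- mass_specific_spectra(list(r1, r1, r1), ncdoc = 1.5)  # CDOC = 2.5
  expect_equal(sp1$a_star_w, iops$a_star_cdoc_w, tolerance = 1e-12)
  expect_null(sp1$a_star_ss)
  # records generated from a known spectrum are recovered band-wise
  cdocs <- c(1.2, 3.4, 0.7)
  recs <- lapply(cdocs, function(cc)
    cdom_record("2019-06-01", doc = cc + 0.5,
                a_cdom = iops$a_star_cdoc_ss * cc, grid = g))
  sp <- mass_specific_spectra(recs, ncdoc = 0.5)
  expect_equal(sp$a_star_ss, iops$a_star_cdoc_ss, tolerance = 1e-12)
  # records with nonpositive CDOC are excluded
  bad <- cdom_record("2019-06-01", doc = 0.4,
                     a_cdom = iops$a_star_cdoc_ss, grid = g)
  expect_message(sp2 <- mass_specific_spectra(c(recs, list(bad)), 0.5),
                 "excluded")
  expect_equal(sp2$excluded, 4L)
})

test_that("nonnegative unmixing recovers mixtures and never returns negatives", {
  iops <- default_iops()
  w <- iops$a_star_cdoc_w; ss <- iops$a_star_cdoc_ss; m <- iops$a_star_cdoc_m
  d1 <- decompose_spectrum(2 * w, w, ss, m)
  expect_equal(unname(d1$conc), c(2, 0, 0), tolerance = 1e-10)
  expect_lt(d1$residual_norm, 1e-10)
  mix <- 2 * w + 1 * ss
  d2 <- decompose_spectrum(mix, w, ss, m)
  expect_equal(unname(d2$conc), c(2, 1, 0), tolerance = 1e-8)
  # oracle: the unconstrained least-squares solution of the noiseless
  # two-component mixture is already nonnegative, so both must agree
  ols <- qr.solve(cbind(w, ss), mix)
  expect_equal(unname(d2$conc[c("cdoc_w", "cdoc_ss")]), unname(ols),
               tolerance = 1e-8)
  # unphysical negative spectrum: all-zero concentrations, large residual
  d3 <- decompose_spectrum(-w, w, ss, m)
  expect_equal(unname(d3$conc), c(0, 0, 0))
  expect_gt(d3$residual_norm, 1)
  expect_true(all(d3$residual <= 0))   # residuals reported, not clipped
  expect_error(decompose_spectrum(w, w, 2 * w, m), "collinear")
})

test_that("the lability split is exact and closed", {
  expect_equal(lability_split(1.0),
               c(ncdoc1 = 0.030, ncdoc2 = 0.097, ncdoc3 = 0.873))
  expect_equal(lability_split(0), c(ncdoc1 = 0, ncdoc2 = 0, ncdoc3 = 0))
  x <- c(0.3, 1.7, 12.345)
  sp <- lability_split(x)
  expect_equal(rowSums(sp), x, tolerance = 0)   # closure is exact
})

test_that("noiseless synthetic spectra invert to the truth", {
  ds <- synthetic_cdom_dataset(n = 10, noise_sd = 0, seed = 5)
  iops <- default_iops()
  for (i in seq_along(ds$records)) {
    d <- decompose_spectrum(ds$records[[i]]$a_cdom, iops$a_star_cdoc_w,
                            iops$a_star_cdoc_ss, iops$a_star_cdoc_m)
    expect_equal(unname(d$conc),
                 as.numeric(ds$truth[i, c("cdoc_w", "cdoc_ss", "cdoc_m")]),
                 tolerance = 1e-8)
  }
  # seeded determinism
  ds2 <- synthetic_cdom_dataset(n = 10, noise_sd = 0, seed = 5)
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$records[[3]]$a_cdom, ds2$records[[3]]$a_cdom)
})

test_that("noisy unmixing recovers total riverine CDOC despite the ill-conditioned split", {
  # the winter and spring/summer spectra are near-collinear exponentials, so
  # band noise scrambles the split between them but barely moves their sum
  iops <- default_iops()
  ds <- synthetic_cdom_dataset(n = 50, noise_sd = 0.02, seed = 17)
  tot_err <- vapply(seq_len(50), function(i) {
    d <- decompose_spectrum(ds$records[[i]]$a_cdom, iops$a_star_cdoc_w,
                            iops$a_star_cdoc_ss, iops$a_star_cdoc_m)
    tot <- sum(d$conc[c("cdoc_w", "cdoc_ss")])
    truth <- sum(ds$truth[i, c("cdoc_w", "cdoc_ss")])
    abs(tot - truth) / truth
  }, 0)
  expect_lt(stats::median(tot_err), 0.05)
})

test_that("fractionation reconstructs total DOC exactly", {
  ds <- synthetic_cdom_dataset(n = 30, noise_sd = 0.05, seed = 9)
  fr <- fractionate_cdom(ds$records)
  tot <- with(fr$result, cdoc_w + cdoc_ss + cdoc_m + ncdoc)
  expect_equal(tot, fr$result$doc, tolerance = 1e-12)
  expect_true(all(fr$result$ncdoc >= 0))
  expect_true(all(as.matrix(fr$result[, 1:4]) >= 0))
})

test_that("CDOM records round-trip through the CSV interface", {
  ds <- synthetic_cdom_dataset(n = 4, noise_sd = 0, seed = 2)
  g <- ds$records[[1]]$grid
  df <- data.frame(date = vapply(ds$records, function(r)
    format(r$date), ""), doc_gCm3 = vapply(ds$records, `[[`, 0, "doc"))
  amat <- t(vapply(ds$records, `[[`, numeric(84), "a_cdom"))
  colnames(amat) <- paste0("a_", g$wavelengths)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(df, amat), f, row.names = FALSE)
  recs <- read_cdom_csv(f)
  expect_length(recs, 4)
  expect_equal(recs[[2]]$a_cdom, ds$records[[2]]$a_cdom, tolerance = 1e-9)
  expect_equal(recs[[2]]$doc, ds$records[[2]]$doc)
})
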
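# S3 methods for run, forcing and suite objects.

#' @export
print.chain_run <- function(x, ...) {
  cat("<chain_run>", x$scenario, "scenario,", length(x$time), "days,",
      length(x$geometry$names), "boxes x", x$geometry$n_layers, "layers\n")
  cat(sprintf("  dt = %g d, seed = %s, spin-up flagged: first %d days\n",
              x$dt, format(x$seed), x$spinup_days))
  cat(sprintf("  carbon audit relative residual: %.3g\n", x$audit$relative))
  last <- utils::tail(x$interfaces, 1)
  doc <- integrate_flux(x, last, constituents = c("cdoc_m", "cdoc_w",
                                                  "cdoc_ss", "ncdoc1",
                                                  "ncdoc2", "ncdoc3"))
  poc <- integrate_flux(x, last, constituents = c("lpoc", "rpoc"))
  cat(sprintf("  %s: DOC %.1f Gg C, POC %.1f Gg C over the run\n",
              last, doc, poc))
  invisible(x)
}

#' Summarize a chain run
#'
#' Integrated DOC and POC fluxes (Gg C) across every interface over the
#' post-spin-up window, the six-class composition at the terminal
#' interface, and the budget ledger totals.
#'
#' @param object a `chain_run`.
#' @param t0 first day of the integration window (default: after spin-up).
#' @param ... unused.
#' @return a list with `fluxes` (data.frame), `composition`, `ledger_GgC`
#'   and `audit`, invisibly; printed as a side effect.
#' @export
summary.chain_run <- function(object, t0 = object$spinup_days + 1, ...) {
  doc_pools <- c("cdoc_m", "cdoc_w", "cdoc_ss", "ncdoc1", "ncdoc2", "ncdoc3")
  poc_pools <- c("lpoc", "rpoc")
  fluxes <- data.frame(
    interface = object$interfaces,
    doc_GgC = vapply(object$interfaces, function(i)
      integrate_flux(object, i, t0 = t0, constituents = doc_pools), 0),
    poc_GgC = vapply(object$interfaces, function(i)
      integrate_flux(object, i, t0 = t0, constituents = poc_pools), 0),
    row.names = NULL)
  last <- utils::tail(object$interfaces, 1)
  by_class <- vapply(c(doc_pools, poc_pools), function(p)
    integrate_flux(object, last, t0 = t0, constituents = p), 0)
  comp <- composition_fractions(by_class)
  led <- object$ledger
  ledger_ggc <- c(inflow = sum(led$inflow[.carbon_pools()]),
                  lake = sum(led$lake[.carbon_pools()]),
                  outflow = sum(led$outflow[.carbon_pools()]),
                  microbial_co2 = led$microbial_co2,
                  photo_co2 = led$photo_co2,
                  predation_co2 = led$predation_co2,
                  primary_production = led$primary_production) / 1e9
  out <- list(scenario = object$scenario, window = c(t0, max(object$time)),
              fluxes = fluxes, composition = comp,
              ledger_GgC = ledger_ggc, audit = object$audit)
  cat(sprintf("Scenario %s, integration window day %d-%d\n",
              object$scenario, t0, max(object$time)))
  print(fluxes, digits = 4)
  cat("\nComposition at", last, "(fractions):\n")
  print(round(comp, 3))
  cat("\nLedger (Gg C):\n")
  print(round(ledger_ggc, 3))
  cat(sprintf("\nCarbon audit relative residual: %.3g\n",
              object$audit$relative))
  invisible(out)
}

#' Plot a chain run
#'
#' Four base-graphics panels: river discharge, DOC flux across each
#' interface, vertically averaged attenuation of photosynthetically active
#' radiation per box, and the domain DOC/POC stocks; the spin-up window is
#' shaded.
#'
#' @param x a `chain_run`.
#' @param ... passed to `matplot`.
#' @export
plot.chain_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    u <- graphics::par("usr")
    graphics::rect(0, u[3], x$spinup_days, u[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  graphics::plot(x$time, x$forcing$discharge, type = "l",
                 xlab = "day of run", ylab = "discharge (m3/s)",
                 main = "river forcing")
  shade()
  doc_pools <- c("cdoc_m", "cdoc_w", "cdoc_ss", "ncdoc1", "ncdoc2", "ncdoc3")
  fl <- sapply(x$interfaces, function(i)
    apply(x$interface_flux[, i, doc_pools], 1, sum)) * 86400 / 1e9
  graphics::matplot(x$time, fl, type = "l", lty = 1,
                    xlab = "day of run", ylab = "DOC flux (Gg C/d)",
                    main = "interface DOC flux", ...)
  graphics::legend("topright", legend = x$interfaces, col = seq_len(ncol(fl)),
                   lty = 1, cex = 0.6, bty = "n")
  shade()
  graphics::matplot(x$time, x$kd_par, type = "l", lty = 1,
                    xlab = "day of run", ylab = "Kd_PAR (1/m)",
                    main = "attenuation by box")
  shade()
  doc_stock <- domain_stock(x) / 1e9
  poc_stock <- domain_stock(x, pools = c("lpoc", "rpoc")) / 1e9
  graphics::matplot(x$time, cbind(doc_stock, poc_stock), type = "l", lty = 1,
                    col = c("black", "brown"),
                    xlab = "day of run", ylab = "stock (Gg C)",
                    main = "domain stocks")
  graphics::legend("topright", legend = c("DOC", "POC"),
                   col = c("black", "brown"), lty = 1, bty = "n")
  shade()
  invisible(x)
}

#' @export
as.data.frame.chain_run <- function(x, ...) {
  g <- x$geometry
  nb <- length(g$names)
  nl <- g$n_layers
  days <- length(x$time)
  idx <- expand.grid(layer = seq_len(nl), box = seq_len(nb),
                     day = seq_len(days))
  out <- data.frame(day = idx$day, box = g$names[idx$box], layer = idx$layer)
  for (const in chain_constituents())
    out[[const]] <- as.vector(aperm(x$conc[, const, , , drop = FALSE],
                                    c(4, 3, 1, 2)))
  out
}

#' @export
print.chain_forcing <- function(x, ...) {
  cat("<chain_forcing>", x$days, "days, seed", format(x$seed), "\n")
  cat(sprintf("  discharge %.0f-%.0f m3/s (volume %.1f km3), temperature %.1f-%.1f C, shortwave %.0f-%.0f W/m2\n",
              min(x$discharge), max(x$discharge),
              sum(x$discharge) * 86400 / 1e9,
              min(x$temperature), max(x$temperature),
              min(x$shortwave), max(x$shortwave)))
  invisible(x)
}

#' @export
plot.chain_forcing <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t <- seq_len(x$days)
  graphics::plot(t, x$discharge, type = "l", xlab = "day",
                 ylab = "m3/s", main = "discharge")
  graphics::plot(t, x$temperature, type = "l", xlab = "day",
                 ylab = "degC", main = "temperature")
  graphics::plot(t, x$shortwave, type = "l", xlab = "day",
                 ylab = "W/m2", main = "shortwave")
  graphics::matplot(t, x$boundary_conc[, c("cdoc_ss", "ncdoc3", "rpoc", "iss")],
                    type = "l", lty = 1, xlab = "day", ylab = "g/m3",
                    main = "boundary concentrations (log)", log = "y")
  invisible(x)
}

#' @export
print.chain_suite <- function(x, ...) {
  cat("<chain_suite>", length(x), "scenarios:",
      paste(names(x), collapse = ", "), "\n")
  last <- utils::tail(x[[1]]$interfaces, 1)
  doc_pools <- c("cdoc_m", "cdoc_w", "cdoc_ss", "ncdoc1", "ncdoc2", "ncdoc3")
  df <- data.frame(
    scenario = names(x),
    doc_GgC = vapply(x, function(r)
      integrate_flux(r, last, constituents = doc_pools), 0),
    poc_GgC = vapply(x, function(r)
      integrate_flux(r, last, constituents = c("lpoc", "rpoc")), 0),
    row.names = NULL)
  print(df, digits = 4)
  invisible(x)
}
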
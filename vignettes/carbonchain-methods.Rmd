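---
title: "Methods: a box-chain model of organic carbon transformation from river to ocean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a box-chain model of organic carbon transformation from river to ocean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonchain)
```

## The problem

Large high-latitude rivers deliver dissolved and particulate organic carbon
(DOC and POC) to the coastal ocean in strongly seasonal pulses. Between the
river gauge and the open ocean, that carbon is transformed: chromophoric
(light-absorbing) DOC is photodegraded, heterotrophic microbes remineralize
the labile fractions, POC sinks and is resuspended, dissolved matter can
flocculate into particles as salinity rises, and phytoplankton add fresh
marine carbon. The net flux and its composition at the shelf therefore
differ substantially from what the river exports.

`carbonchain` is a desk-scale simulator of this chain of processes. It
replaces three-dimensional hydrodynamics with a one-dimensional chain of
well-mixed boxes (river inflow, delta, delta mouth(s), plume, coastal
ocean), each with vertical layers, connected by first-order upwind advection
of the river discharge. Everything else — the reaction network, the
hyperspectral light model, the photochemistry, the scenario suite, the
budget accounting — is carried in full. The intent is not to reproduce any
specific coastal system's fluxes (those require resolved circulation and
measured forcing) but to expose the process formulations and their sign
structure in a form that is fast, transparent, and conservative to machine
precision.

## State variables and the reaction network

Twelve constituents are transported in every layer of every box
(`chain_constituents()`), all in g m^-3:

* three chromophoric DOC classes (CDOC): marine (`cdoc_m`), winter riverine
  (`cdoc_w`), and spring/summer riverine (`cdoc_ss`). CDOC is carbon mass
  that absorbs light and is photoreactive;
* three non-chromophoric DOC classes (`ncdoc1`-`ncdoc3`): optically inert
  DOC split by biological lability (labile, semi-labile, refractory);
* labile and refractory POC (`lpoc`, `rpoc`);
* inorganic suspended sediment (`iss`);
* two phytoplankton groups as carbon (`b1`, `b2`);
* dissolved inorganic nitrogen (`din`, g N m^-3).

The kinetic processes, all evaluated as pure functions in the
`carbon_kinetics` layer:

* **Microbial degradation**: first-order loss `kappa_c theta_c(T) [DOC]`
  per DOC class, with class rates 0.025 / 0.01 / 0.001 d^-1 for labile /
  semi-labile / refractory carbon. This is a terminal sink (ledger CO2);
  multi-step humification is not modelled. Nitrogen is returned to DIN at a
  fixed Redfield C:N.
* **Hydrolysis**: POC to DOC at 0.03 (labile) and 0.006 (refractory) d^-1,
  i.e. half-lives of about 23 and 116 days at the reference temperature.
* **Flocculation**: a salinity bell curve
  `kappa_f = kappa_fmax exp(-kappa_c1 (S - S_max)^2)` below the optimum
  salinity `S_max = 1` and `kappa_fmax exp(-kappa_c2 (S_max - S)^2)` at or
  above it, with shape parameters 5.0 and 0.25. The baseline rate is zero;
  the flocculation scenario sets `kappa_fmax = 0.1` d^-1. Only the riverine
  CDOC classes flocculate, into refractory POC.
* **Settling**: POC sinks at constant 1.0 / 0.4 m d^-1; inorganic sediment
  uses a saturating (Michaelis-Menten-like) velocity
  `w = w_max [ISS]/([ISS] + k_ISS)` with `w_max = 2` m d^-1 and
  `k_ISS = 51` g m^-3, so dilute water settles slowly and the sediment-laden
  river quickly.
* **Resuspension**: zero below a critical bottom stress of 0.005 Pa and
  linear above it (1e-5 g m^-2 s^-1 Pa^-1), drawn from a finite benthic
  pool (initialized at 10 kg m^-2, 95 % inorganic) and partitioned 95 %
  ISS / 5 % POC.
* **Phytoplankton**: growth limited by the minimum of light and nitrogen
  saturation, exudation of a fixed 0.2 fraction of growth into marine CDOC,
  and an implicit second-order grazing loss `nu_B theta_B B^2`
  (1.5 m^3 (g C)^-1 d^-1) of which 10 % / 50 % become labile / refractory
  POC.

### Choices the parameter table does not fix

Several routing decisions are required that the published parameter set
leaves open. They are package defaults, all overridable through
`kinetic_params()`:

* the three temperature functions share `exp(0.069 (T - 20))` (a Q10 of
  about 2), because no separate coefficients are published;
* the DOC-class-to-rate mapping treats winter riverine CDOC as the most
  biologically refractory (labile: marine CDOC and NCDOC1; semi-labile:
  spring/summer CDOC and NCDOC2; refractory: winter CDOC and NCDOC3) —
  winter base-flow DOC in Arctic rivers is old, soil-derived material;
* hydrolysate is routed to non-chromophoric pools (labile POC to NCDOC1,
  refractory POC to NCDOC3), assuming enzymatic breakdown products have
  lost most of their colour;
* the 40 % of grazing losses that do not become POC are split equally
  between labile NCDOC (sloppy feeding / excretion) and immediate
  remineralization (respiration), which keeps the carbon audit closed;
* DIN couples to all organic transformations at the fixed molar Redfield
  ratio 106:16.

## The light field

Light drives photochemistry and phytoplankton growth, and is attenuated by
the things being simulated, so it is recomputed every step on an 84-band
grid (285-700 nm at 5 nm). The surface spectrum distributes the UV-visible
fraction (0.43) of broadband shortwave irradiance over the grid with
normalized black-body weights at 5778 K. Total absorption sums pure water,
the three CDOC classes, chlorophyll (phytoplankton carbon over fixed
carbon:chlorophyll ratios of 40.0 and 28.6) and suspended particulate
matter (ISS + both POC classes); backscatter sums water and a spectrally
flat particulate term (0.01 m^2 g^-1). The diffuse attenuation coefficient
uses the published semi-analytical form

    kd = (1 + 0.005 theta_s) a_t + 4.18 (1 - 0.52 exp(-10.8 a_t)) b_b

with the solar zenith angle fixed at 30 degrees by default, and irradiance
is propagated down the layers by Beer-Lambert attenuation. Rate
calculations use mid-layer irradiance rather than interface values.

The mass-specific CDOC spectra are exponential,
`a*(lambda) = a*_300 exp(-S (lambda - 300))`, with slopes 0.018 / 0.016 /
0.022 nm^-1 and 300 nm magnitudes 3.2 / 2.6 / 1.2 m^2 g C^-1 for the
winter, spring/summer and marine classes. The magnitudes place the
absorption-to-carbon ratio in the range observed for riverine DOC (roughly
2-4 m^2 g C^-1 at 300 nm); regionally calibrated spectra can be swapped in
via a CSV (`read_iops()`).

## Photochemistry

Photons absorbed in a layer are apportioned among absorbers by their share
of total absorption; the share landing on each CDOC class drives carbon
transformation through an apparent quantum yield (AQY) spectrum
`AQY(lambda) = scale x phi0 exp(-0.02 (lambda - 290))`, with
`phi0 = 5e-5` mol C (mol photons)^-1 for the riverine classes and one tenth
of that for marine CDOC. Photodegraded carbon is distributed by a
row-stochastic transfer matrix — by default 30 % to marine CDOC, 69 % to
refractory NCDOC and 1 % to CO2 for the riverine classes (99 % / 1 % for
marine CDOC) — so direct photomineralization stays orders of magnitude
below photobleaching, and the dominant photoproduct of riverine CDOC is the
more labile marine class. The `scale` multiplier is the scenario switch: 0
(off), 1 (baseline), 2 (doubled).

The AQY magnitude is deliberately conservative; with the default spectra
the photochemical term is a small perturbation on the seasonal budget
(tenths of a Gg C on a ~1000 Gg C export), which is sufficient for the
sign-structure analyses the package targets. Users studying
photochemistry-dominated regimes should supply measured AQY spectra.

## Numerics and conservation

The stepper is explicit Euler with operator splitting in a fixed order:
advection, optics, photochemistry, kinetics, settling/resuspension. Every
removal is written as a conservative transfer limited to the donor pool
(`min(rate x dt, available)`), so concentrations cannot go negative and
carbon is conserved exactly up to floating-point rounding; a budget ledger
accumulates boundary inflows, lake input, export, deposition,
resuspension, the three CO2 sinks (microbial, photochemical, grazing
respiration) and primary production. `chain_audit()` closes the budget;
full-length default runs close to about 1e-15 relative, far inside the
1e-6 acceptance threshold (the threshold allows for the accumulation of
rounding in much longer or stiffer configurations).

The default step is `dt = 0.01` d. The fastest processes are the advective
exchange of the smallest box (a few percent of its volume per step at peak
discharge) and settling across a layer (about 2 % of a layer per step), so
0.01 d sits comfortably inside both stability and accuracy margins:
single-process runs match closed-form exponentials within 1 % and halving
the step changes the day-90 DOC stock by well under 0.5 % (both are tests).
The advective CFL condition is checked every step and violations abort
naming the limiting box.

Default problem sizes, chosen to keep a full run under about a minute on
one core: 5 boxes x 10 layers x 183 days x 100 steps per day, 84 spectral
bands. The scenario suite runs six such simulations.

## Geometry

The default chain is five boxes — river inflow, delta, delta mouth, plume
(bounded by the 10 m isobath analogue) and coastal ocean — with prescribed
salinities 0, 0, 0.5, 5 and 25. Salinity and temperature are forcing, not
prognostic: a box chain has no buoyancy physics with which to compute them.
Box volumes are sized so that at the seasonal mean discharge the
river-to-mouth transit takes about 3 days and the plume flushes in about 3
weeks, the residence-time scales characteristic of a large Arctic delta
front. A four-mouth preset (`chain_geometry_branched()`) splits the delta
outflow 0.79 / 0.07 / 0.07 / 0.07 across parallel mouth boxes, mirroring a
south-dominated delta distribution network.

## Synthetic forcing

The forcing generator (`synthetic_forcing()`) emulates, without any
external data:

* a **double-pulse freshet hydrograph**: baseflow plus Gaussian pulses with
  a primary peak in early June and a secondary pulse in late August,
  rescaled so the 183-day volume (1 April - 30 September) is 150.5 km^3;
* **rating-curve boundary concentrations**: each constituent follows
  `ln C = a0 + a1 ln(Q/Qbar) + a2 ln(Q/Qbar)^2 + a3 sin(2 pi T) +
  a4 cos(2 pi T)`. Defaults give flushing behaviour (concentration rising
  with discharge) for spring/summer CDOC, particulates and sediment,
  dilution for winter CDOC and DIN, and weak flow dependence for
  non-chromophoric DOC — the qualitative concentration-discharge behaviour
  of large permafrost rivers. The same five-term form can be fitted to
  concentration-discharge pairs (`fit_rating_curve()`), by ordinary least
  squares in log space with a plain exponential back-transform (no smearing
  correction; a bias caveat documented in the function help);
* a **delta lake source** of 0.647 km^3 per year distributed in proportion
  to discharge (0.43 % of the seasonal river volume) with same-day river
  concentrations. The lake adds mass but its volume is not added to the
  downstream discharge — a 0.4 % inconsistency accepted for simplicity;
* seasonal **temperature** (0-18 degrees C) and **shortwave** (50-300
  W m^-2) sinusoids peaking in mid-July, and a spring-neap modulated
  **current speed** (0.08 +/- 0.04 m s^-1) that sets bottom stress through
  a quadratic drag law (c_d = 0.0025);
* ocean-end concentrations constant in time.

What the generator does *not* emulate: tides and storm resuspension events,
cloud variability in irradiance, the co-variance structure of real
concentration-discharge data, sea ice, and inter-annual change. Passing
tests on this forcing therefore demonstrate correctness of the process
formulations and their interactions, not predictive skill for any real
river-ocean system.

## The scenario engine

Six scenarios run on one shared forcing: `Base`, `NoPD` and `2xPD`
(photodegradation off / doubled), `NoSet` (POC sinking velocities zero),
`Floc` (flocculation on at 0.1 d^-1) and `NoMicrobial` (microbial DOC
degradation off). `NoMicrobial` is included as a first-class member of the
suite even though it is bookkept separately from the headline five in some
descriptions of this experimental design. Interface fluxes are accumulated
exactly (daily means of the per-step upwind transfers), integrated to Gg C
over windows (`integrate_flux()`), grouped into the six reported classes
(`composition_fractions()`), smoothed with a centered 10-day moving average
(`moving_average()`; even windows use the standard half-weight end points,
so affine series are unchanged in the interior) and differenced against the
baseline (`compare()`, sign convention scenario minus base). The default
integration window drops the first 45 days as spin-up, following the
convention that the early-season frozen period is initialization.

The suite reproduces the sign structure expected of each switch: more
riverine CDOC escapes the plume without photodegradation and less with it
doubled; switching settling off exports more POC; flocculation moves flux
from the dissolved to the particulate phase; and removing the microbial
sink can only raise the DOC stock. The package deliberately does not claim
the corresponding magnitudes, which depend on resolved circulation and real
forcing.

## CDOM fractionation

The fractionation workflow estimates the class concentrations that the
simulator transports from paired DOC concentration / CDOM absorption
spectra:

1. **Non-chromophoric DOC** is the intercept of the ordinary least squares
   regression of DOC on absorption at 300 nm (`a300` is read off the
   nearest grid band, no interpolation); a negative intercept is clipped to
   zero with a warning.
2. **Seasonal mass-specific spectra** divide each record's absorption
   spectrum by its chromophoric DOC (DOC minus NCDOC) and average per band
   within seasons (winter = November-April; spring = May-June; summer =
   July-October); winter gives the winter-class spectrum, spring and summer
   pool into the spring/summer class.
3. **Unmixing**: each spectrum is decomposed into nonnegative class
   concentrations by nonnegative least squares against the winter,
   spring/summer and marine spectra. Negative residual spectra are
   reported, never clipped.
4. **Lability split**: NCDOC is divided 3 % / 9.7 % / 87.3 % into labile /
   semi-labile / refractory classes, reflecting incubation evidence of low
   overall bioavailability; the split closes exactly (the refractory
   component absorbs the rounding remainder).

### Identifiability of the class split

The winter and spring/summer mass-specific spectra are both decaying
exponentials with slopes only 0.002 nm^-1 apart, so their band-wise
correlation is 0.9985 and the unmixing design has a condition number of
several hundred. The consequence, measured by simulation with the built-in
generator: independent 2 % multiplicative noise per band is amplified to
roughly 30 % (winter) and 10 % (spring/summer) median relative error in the
individual class concentrations, while their *sum* — total riverine
chromophoric DOC — is recovered at about 3 % median error. Noiseless
spectra invert exactly (to 1e-10). This is a property of the unmixing
problem, not of the solver: exponential CDOM shapes of nearby slope are
close to collinear, and no equal-weight least-squares variant can resolve
their split much better. Interpret the per-class winter/spring-summer
partition of noisy field spectra with corresponding caution, or supply
measured seasonal spectra with stronger shape contrast.

By default the workflow makes one regression pass and one unmixing pass.
Whether the original procedure iterates the NCDOC estimate and the spectra
jointly or per record is ambiguous, so an optional
`iterate = TRUE` mode alternates the passes until the NCDOC estimate
changes by less than 1e-6 g C m^-3; neither mode is asserted as canonical.
Per-record NCDOC is re-derived as DOC minus the fitted chromophoric
classes — scaled back where the fit overshoots — so the four components
reconstruct total DOC exactly by construction.

## Known limitations

* No momentum, tides, or stratification: transport is one-way upwind
  advection of the river discharge, and bottom stress is prescribed
  through a current-speed series. Residence times are imposed by geometry,
  not derived.
* Nitrogen is a single DIN pool with fixed stoichiometry; dissolved
  organic nitrogen, ammonium/nitrate partitioning and oxygen are not
  carried.
* No sediment diagenesis: the benthic pool is a passive mass reservoir.
* The default IOP and AQY spectra are literature-shaped but not
  regionally calibrated; both are user-replaceable inputs.
* Explicit Euler favours transparency over stiffness performance; very
  fast user-supplied rates would require a smaller `dt`.

## A minimal run

```{r, eval = FALSE}
library(carbonchain)
run <- run_chain(chain_config(seed = 1))
summary(run)
plot(run)

suite <- run_suite(chain_config(), seed = 1)
print(suite)
```
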
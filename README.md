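# carbonchain

A desk-scale box-chain simulator of organic carbon transformation along a
river–delta–ocean continuum, written for biogeochemical modellers who want
the full reaction network of a coastal organic-carbon model — multi-class
DOC/POC kinetics, hyperspectral light attenuation, photodegradation,
flocculation, settling/resuspension, phytoplankton dynamics — without the
cost and opacity of a 3-D hydrodynamic model.

## The model in brief

Twelve constituents are transported through an ordered chain of layered
boxes (river inflow → delta → mouth(s) → plume → coastal ocean): three
chromophoric DOC classes (marine CDOC_M, winter riverine CDOC_W,
spring/summer riverine CDOC_SS), three non-chromophoric DOC lability
classes (NCDOC_1–3), labile and refractory POC, inorganic suspended
sediment, two phytoplankton groups and dissolved inorganic nitrogen. Per
box and layer the DOC classes evolve as

    d[DOC]/dt = transport + κ_b μ B − κ_c θ_c [DOC] + κ_p θ_p [POC]
                + pdDOC − κ_f(S) [DOC]

i.e. phytoplankton exudation, temperature-modulated microbial degradation
(0.025/0.01/0.001 d⁻¹ by lability class), POC hydrolysis (0.03/0.006 d⁻¹,
half-lives ≈ 23 and 116 d), spectral photodegradation (pdDOC, an
apparent-quantum-yield photon budget over 285–700 nm with the
semi-analytical diffuse attenuation k_d = (1 + 0.005 θ_s) a_t +
4.18 (1 − 0.52 e^(−10.8 a_t)) b_b), and salinity-dependent flocculation
peaking at κ_fmax at S_max = 1. POC additionally sinks (1.0/0.4 m d⁻¹),
sediment settles with a saturating velocity w_max [ISS]/([ISS]+k_ISS), and
both resuspend above a critical bottom stress of 0.005 Pa. Every transfer
is donor-limited and tallied in a budget ledger, so total carbon closes to
machine precision over a full run.

A synthetic-forcing module generates the study conditions: a double-pulse
freshet hydrograph scaled to a 150.5 km³ seasonal volume, rating-curve
boundary concentrations, a 0.647 km³ yr⁻¹ delta-lake source, seasonal
temperature/irradiance and a spring–neap current for bottom stress. A
scenario engine runs Base, NoPD, 2xPD (photodegradation off/doubled),
NoSet (no POC sinking), Floc (flocculation at 0.1 d⁻¹) and NoMicrobial on
identical forcing. A companion workflow fractionates measured CDOM
absorption spectra into the transported CDOC classes (regression-intercept
NCDOC estimate, seasonal mass-specific spectra, nonnegative least-squares
unmixing, 3/9.7/87.3 % lability split).

## Worked example

```r
library(carbonchain)
run <- run_chain(chain_config(seed = 1))   # 183-day baseline, 5 boxes
summary(run)
```

```
Scenario Base, integration window day 46-183
     interface doc_GgC poc_GgC
1  pilot:delta  1018.7  527.18
2  delta:mouth  1021.6  445.46
3  mouth:plume  1021.0  428.02
4  plume:ocean   942.1  223.77
5 ocean:export   310.9   47.91

Composition at ocean:export (fractions):
 cdoc_m  cdoc_w cdoc_ss   ncdoc    lpoc    rpoc
  0.068   0.072   0.332   0.394   0.009   0.125

Ledger (Gg C):
            inflow               lake            outflow      microbial_co2
          1686.411              7.250            396.367            565.885
         photo_co2      predation_co2 primary_production
             0.022             93.032            602.112

Carbon audit relative residual: 1.33e-15
```

Reading the table: about 1020 Gg C of DOC pass the river–delta interfaces
nearly unchanged (passive transit), roughly half the POC is lost between
the mouth and the plume edge (settling inshore of the 10 m-isobath
analogue), and the DOC that reaches the outer interface is progressively
depleted in riverine chromophoric classes and enriched in non-chromophoric
and marine carbon. The ledger accounts for every gram: boundary inflow and
lake input on one side; export, microbial and photochemical CO2, grazing
respiration and primary production on the other, closing to 1e-15.

The scenario suite and flux tools:

```r
suite <- run_suite(chain_config(), seed = 1)
sapply(suite, integrate_flux, interface = "plume:ocean",
       constituents = c("cdoc_w", "cdoc_ss"))   # riverine CDOC, Gg C
#   Base   NoPD   2xPD  NoSet   Floc NoMicrobial
# 651.45 651.84 651.07 651.47 628.84      723.21
```

Photodegradation orders the riverine-CDOC export (NoPD > Base > 2xPD),
settling retains POC (NoSet raises the plume POC flux from 229 to
503 Gg C), flocculation moves carbon from the dissolved to the particulate
phase, and removing the microbial sink raises the DOC stock everywhere.

A thin CLI over the same functions is installed at
`inst/cli/carbonchain.R` (`run`, `suite`, `fluxes`, `fractionate`
subcommands).

## Package layout

- `R/` — spectral optics, carbon kinetics, photochemistry, the box-chain
  stepper and ledger, CDOM fractionation, synthetic forcing, scenario
  engine, configuration/IO.
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/carbonchain-methods.Rmd` — the model description: equations,
  parameter choices and their rationale, numerics, and what the synthetic
  forcing does and does not emulate.
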
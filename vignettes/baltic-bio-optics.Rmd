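---
title: "Seasonal bio-optical models of the Baltic Sea: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal bio-optical models of the Baltic Sea: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baltopt)
```

## The problem

The Baltic Sea is an optically extreme, CDOM-rich, weakly scattering
brackish sea. Chromophoric dissolved organic matter (CDOM) dominates light
absorption at blue wavelengths, the particle population is organic-dominated
and backscatters weakly, and the phytoplankton community flips between a
diatom/dinoflagellate spring bloom (high biomass, strongly pigment-packaged
cells) and a cyanobacteria-rich summer community (lower biomass, roughly
twice the Chla-specific absorption). Standard blue-green ocean-colour
algorithms fail here. `baltopt` provides the building blocks for
Baltic-specific bio-optical work: constituent absorption/scattering models,
their specific inherent optical properties (SIOPs), underwater-light
derivations, a forward reflectance simulator, and a synthetic-data generator
that reproduces the seasonal statistical structure of field campaigns so
that every stage can be exercised and validated without field data.

## Models and procedures

### CDOM absorption

CDOM absorption is modelled as an exponential decay with an offset,

$$a_{CDOM}(\lambda) = a_{CDOM}(\lambda_0)\,e^{-S(\lambda-\lambda_0)} + k,$$

with reference wavelength $\lambda_0 = 412$ nm and the slope $S$ (nm$^{-1}$)
fitted over 400–700 nm. The offset $k$ absorbs residual noise or scattering;
it is unconstrained in sign during fitting but flagged when
$|k| > 0.1$ m$^{-1}$, since realistic baselines are an order of magnitude
smaller (the Baltic mean-spectrum fit gives $S = 0.0177$ nm$^{-1}$,
$k = 0.030$ m$^{-1}$). Fitting uses Levenberg–Marquardt nonlinear least
squares started at $S = 0.018$ nm$^{-1}$ (mid-range of observed slopes),
$k = 0$, and the measured value at $\lambda_0$; noiseless model spectra are
recovered to better than $10^{-5}$ relative error across the observed
parameter space ($S \in [0.01, 0.025]$, $a_{ref} \in [0.2, 3]$,
$k \in [0, 0.05]$).

Three regional models link $a_{CDOM}(412)$ to $S$: linear south of 59°N
($-33.36\,S + 1.16$) and in the Gulf of Finland ($-137.66\,S + 3.60$), and
exponential with an offset in the Gulf of Bothnia
($3.64\times10^{5} e^{-766 S} + 0.38$), whose 0.38 m$^{-1}$ asymptote
represents the background CDOM of that basin. DOC is predicted from
$a_{CDOM}(412)$ by regional linear models; the "other areas" model is
implemented as $DOC = 129.17\,a_{CDOM}(412) + 305.62\ \mu M$, the two
printed coefficients being read as slope and intercept — the intercept is
then consistent with the 305–325 $\mu$M endpoint of CDOM transformation
discussed for both regions. Both readings are noted in the function
documentation.

### Particulate SIOPs and pigment packaging

Bulk IOPs are converted to SIOPs by element-wise division by a constituent
concentration: Chla (mg m$^{-3}$ → m$^2$ mg$^{-1}$), TSM dry weight
(g m$^{-3}$ → m$^2$ g$^{-1}$), or POC. POC is measured in micromolar, which
equals mmol m$^{-3}$ exactly, so POC-specific coefficients come out in
m$^2$ mmol$^{-1}$ with no numeric conversion. Negative values more negative
than $-0.002$ (beyond measurement noise in spectral tails) are rejected.

Pigment packaging — the decline of Chla-specific absorption efficiency with
increasing cellular pigment — is fitted as a power law
$a^*(\lambda) = c\,\mathrm{Chla}^{d}$ by log–log linear regression, with
$d \le 0$ expected. The non-algal particle (NAP) spectral slope uses the
same exponential-plus-offset model as CDOM (seasonal medians 0.0097
nm$^{-1}$ spring, 0.0103 nm$^{-1}$ summer).

### Backscattering from fixed-angle VSF sensors

Fixed-angle volume scattering function (VSF) measurements are converted to
the particulate backscattering coefficient in two modes. The polynomial
mode fits a quadratic in $\mu = \cos\theta$ to $\beta(\theta)$ per
wavelength (at least three angles) and integrates analytically:
$b_b = 2\pi\int_{-1}^{0}\beta(\mu)\,d\mu$. Working in $\mu$ rather than
$\theta$ makes the conversion exact for phase functions constant, linear or
quadratic in $\cos\theta$, which the closed-form tests exploit. The
fixed-angle mode uses $b_b = 2\pi\,\chi\,\beta(\theta_0)$ with
$\chi = 1.1$ at the 117° centroid — the standard single-angle conversion
for BB-type sensors. The backscattering ratio
$\beta_p(\lambda) = b_{bp}(\lambda)/b_p(\lambda)$ is reported per channel
with its spectral mean and slope; composed synthetic spectra keep it within
(0.002, 0.03), bracketing the observed seasonal distributions, with spring
above summer.

### IOP composition and absorption budgets

`compose_iops()` assembles a station's component IOPs: CDOM from the
exponential model, $a_\phi = \mathrm{Chla} \cdot a^*_{\phi,chla}(\lambda)$
(optionally packaging-adjusted), $a_{nap} = \mathrm{TSM} \cdot
a^*_{nap,TSM}(\lambda)$, $b_p = \mathrm{Chla} \cdot b^*_{p,chla}(\lambda)$,
$b_{bp} = \beta_p(\lambda)\,b_p(\lambda)$, plus a bundled pure-water table
(Smith & Baker UV, Pope & Fry visible, Kou NIR knots at 10 nm, linearly
interpolated; Morel $\lambda^{-4.32}$ seawater scattering). Composition is
exactly linear in each concentration when packaging is disabled.
The absorption budget reports, at the 11 OLCI band centres
(400–708.75 nm, nearest-1-nm sampling), each constituent's fraction of
non-water absorption; fractions sum to one by construction and bands darker
than 0.01 m$^{-1}$ are flagged. On synthetic ensembles the median CDOM
share at 412 nm falls in 0.60–0.90 and declines from 400 to 442 nm,
bracketing (not equating — that would need the archived field spectra) the
reported dataset medians.

### Underwater light

Spectral $K_d$ is the negative slope of unweighted ordinary least squares
of $\ln E_d$ on depth (default window 0–15 m; depths below $10^{-6}$ of the
profile maximum excluded). The first optical depth is $z_{90} = 1/K_d$ and
the euphotic depth $z_{eu} = 4.6\,z_{90}$, both exact identities of the
result object. $K_d(\mathrm{PAR})$ converts irradiance to quantum units
($E_d \lambda / h c N_A$, trapezoidal integral over 400–700 nm) per depth
first and then fits the slope over 0–7 m, matching shipboard practice.
Subsurface reflectance extrapolates both irradiance streams to $z = 0^-$
log-linearly and takes their ratio.

The Secchi coupling $K_d(\mathrm{PAR}) = f/Z_{SD}$ is fitted through the
origin on $1/Z_{SD}$. Seasonal coefficients are spring 2.44, summer 1.98,
combined 2.14. The fit's `rmse` is reported in $K_d$ units per the type
contract, with a depth-space RMSE (metres) alongside for comparability with
shipboard precision (0.5 m). Intercept and exponential alternatives are
deliberately out of scope: they improve fits toward clear water without
better overall error.

Vertical biomass profiles are classified by peak depth (< 3 m, 3–10 m,
≥ 10 m) with a no-peak rule at coefficient of variation < 10%. Bin edges
are closed-open with maxima at exactly 10 m assigned to the deep bin; the
classification is scale-invariant.

### Forward reflectance

Full radiative-transfer simulation is replaced by the standard
analytical quadratic kernel for case-2 waters:
$u = b_b/(a+b_b)$, $r_{rs}(0^-) = g_1 u + g_2 u^2$
($g_1 = 0.0949$, $g_2 = 0.0794$ sr$^{-1}$), and the water-to-air transfer
$R_{rs} = 0.52\,r_{rs}/(1 - 1.7\,r_{rs})$. Solar geometry enters only as an
in-water path-length factor $1/\cos\theta_{sw}$ on $g_1$ (Snell-refracted
sun zenith, $n = 1.34$); viewing zenith and azimuth are accepted for grid
layout compatibility but have no radiometric effect — a full BRDF is a
non-goal. $R_{rs}$ is monotonically increasing in $b_b$ and decreasing in
$a$ at every wavelength. Grids over Chla × TSM × $a_{CDOM}(412)$ × sun
zenith are deterministic given the configuration, with $S$ supplied by
algebraic inversion of the regional slope model (clamped to the observed
support 0.008–0.028 nm$^{-1}$), and serialize losslessly to a long-format
CSV with a key:value metadata header.

A model behaviour worth knowing: with any standard pure-water absorption
table, the reflectance peak sits in the 555–605 nm green window only while
CDOM and biomass are jointly at Baltic-typical levels. Because the peak
tracks the argmin of $a_w(\lambda) + a_{CDOM}(\lambda)$ when backscatter is
spectrally flat, cells with $a_{CDOM}(412) \lesssim 0.6$ m$^{-1}$ *and*
Chla near 1 mg m$^{-3}$ peak nearer 540 nm — a combination rarely observed
in the open Baltic, where low CDOM accompanies the saltier, more productive
southern basins. The tests assert the green-peak property for jointly
typical cells and document the blue-shifted corner explicitly.

## The synthetic-data generator

The generator defines the study conditions under which the package is
validated. Its seasonal defaults are pinned:

* **Chla**: lognormal with medians 14.1 (spring) and 4.3 (summer)
  mg m$^{-3}$; log-sd 0.55 and 0.65, matching the breadth of the seasonal
  histograms.
* **POC**: coupled to Chla with seasonal ratios 3.3 (spring) and 6.6
  (summer) $\mu$M per mg m$^{-3}$ — the summer POC:Chla ratio about twice
  spring — with 30% lognormal scatter.
* **TSM**: independent lognormal (median 2.0 g m$^{-3}$) in spring; weakly
  coupled to Chla ($0.5 + 0.18\,\mathrm{Chla}$, 25% scatter) in summer
  only. The ISM fraction is Beta-distributed with mean ~0.25, keeping the
  particle population organic-dominated (median ISM/TSM < 0.5) in both
  seasons.
* **CDOM**: $a_{CDOM}(412)$ from a two-component lognormal mixture with
  modes 0.53 and 0.85 m$^{-1}$ (weights 0.6/0.4, log-sd 0.12); $S$ from the
  regional inverse relation plus Gaussian noise (sd 0.0015 nm$^{-1}$),
  clamped to the observed support; $k \sim N(0.030, 0.005)$ truncated at 0.
* **SIOPs**: seasonal mean spectra (phytoplankton absorption anchored at
  0.020/0.040 m$^2$ mg$^{-1}$ at 440 nm and 0.014/0.021 at 675 nm for
  spring/summer; NAP slope at the seasonal medians; summer scattering with
  its $-0.11\%$ nm$^{-1}$ slope and a small phycoerythrin feature) scaled
  per station by median-one lognormal factors at the observed coefficients
  of variation (26%/28% for Chla-specific pigment absorption). One
  moderation: the summer NAP variability uses CV 0.8 rather than the
  observed 785%, which is driven by a few extreme stations and would yield
  unphysical single-station compositions as a pure multiplicative factor.
* **Profiles**: $K_d$ is derived from composed IOPs through the proxy
  $K_d = \kappa\,(a + b_b)/\cos\theta_{sw}$ with $\kappa = 1.04$ — generator
  glue, documented as such, not a measurement model. Irradiance decays
  exponentially with multiplicative lognormal noise; Secchi depth follows
  the seasonal reciprocal coupling (spring 2.44, summer 1.98) with 10%
  noise, rounded to the 0.5 m precision of shipboard practice; vertical
  Chla/POC profiles draw their peak-depth category from the observed
  seasonal frequencies (spring: 39% near-surface, 17% intermediate, none
  deep, 44% no peak).

Everything is reproducible from a configuration and a seed; changing only
the seed changes draws but not summary statistics beyond sampling error.

What the generator does *not* emulate: spatial autocorrelation along cruise
tracks, ice-season conditions, cyanobacterial surface films, UV chromophore
variability, and particle-size-resolved optics. Passing tests therefore
demonstrate internal consistency and estimator calibration under the
documented statistical structure — not validation against new field data.

## Numerical choices

* Nonlinear fits: `minpack.lm::nlsLM` (Levenberg–Marquardt), up to 200–500
  iterations; exponential-with-offset starts from a log-linear fit with a
  conservative offset seed.
* Quadratures: trapezoidal on native 1-nm grids (PAR); analytic for the
  VSF polynomial in $\cos\theta$.
* Degenerate inputs error early and specifically: all-zero spectra,
  insufficient wavelength coverage (< 20 samples), fewer than 3 usable
  depths, constant regressors, zero normalizer concentrations, negative
  VSF values (clipped with a warning).
* Problem sizes in the test-suite Monte Carlos (100 replicates at the field
  sample sizes n = 38–139; 10,000-station calibration ensembles; 60–200
  station property ensembles) were chosen to keep recovery standard errors
  small relative to the quantities checked.

## Known limitations

* The reflectance kernel is an analytical approximation; grid values are
  not expected to match full radiative-transfer simulations cell-by-cell,
  and near-infrared features of cyanobacterial surface accumulations are
  out of scope.
* Dataset-level budget medians (e.g. the ~76% CDOM share at 412 nm) are
  statistics of measured field spectra; the package brackets them with
  synthetic ensembles rather than reproducing them exactly.
* The salinity couplings (salinity–$a_{CDOM}$, salinity–$f$) are provided
  as fitting machinery only; no reference coefficients are shipped because
  none are published beyond their error statistics.
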
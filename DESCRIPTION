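Package: baltopt
Title: Seasonal Bio-Optical Models of the Baltic Sea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optical-biogeochemical models for the Baltic Sea pelagic in
    support of ocean-colour remote sensing. Implements the exponential
    chromophoric dissolved organic matter (CDOM) absorption model and its
    nonlinear fitting, regional CDOM-slope and DOC relationships,
    specific inherent optical properties (SIOPs) with pigment-packaging
    power models, volume-scattering-function to backscattering conversion
    and the particulate backscattering ratio, component absorption budgets
    at OLCI bands, diffuse attenuation (spectral and PAR), first optical
    and euphotic depths, the reciprocal Secchi-depth coupling, a forward
    simulator of remote-sensing reflectance over concentration and
    geometry grids, and a seasonal synthetic-data generator reproducing
    the statistical structure of spring and summer field campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
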
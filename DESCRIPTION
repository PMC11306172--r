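Package: wiop
Title: Work-Based Intraocular Pressure Estimation from Non-Contact Tonometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reduced-order biomechanical simulation and analysis toolkit for
    non-contact (air-puff) tonometry. Builds an axisymmetric hyperelastic eye
    model (Holzapfel-Gasser-Ogden cornea and limbus, Neo-Hookean sclera) with
    an incompressible fluid cavity at intraocular pressure, recovers the
    zero-pressure configuration, and integrates the structure explicitly under
    either a falling rigid mass or a prescribed air-puff surface pressure.
    Implements the energetic bookkeeping of the intraocular-pressure work and
    the external-load work on the anterior corneal surface, detection of the
    first-applanation and maximum-apex-velocity instants, a sixteen-case
    material/thickness/pressure sweep, quadratic calibrations and their exact
    quartic composition, and the resulting material- and
    thickness-independent work-based intraocular pressure estimator (wIOP)
    driven by the time of maximum corneal-apex velocity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
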
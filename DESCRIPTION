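Package: huxmtc
Title: Huxley-Type Muscle-Tendon Complex Model with Metabolic Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and calibration of an extended two-state Huxley
    cross-bridge muscle-tendon complex model. The contractile element is a
    bond-length distribution of attached cross-bridges integrated along
    characteristics, coupled to quadratic series and parallel elastic
    elements, a fourth-order isometric force-length relationship and
    first-order calcium activation dynamics. Metabolic power is modelled as
    the weighted rate of cross-bridge unbinding (split at a normalized bond
    length of 0.8) plus a calcium-pumping cost proportional to free calcium.
    Includes generators for experimental protocols (stimulus trains,
    sinusoidal work-loop movements, isometric series), a three-stage
    parameter estimation pipeline (static elastic properties,
    rate/activation dynamics, energetic coefficients via pseudo-inverse
    least squares), a cross-validation harness, and a synthetic-fixture
    module that emulates mouse soleus fibre-bundle experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
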
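Package: flowdoe
Title: Automated Design-of-Experiments Optimization and Residence-Time
    Analysis for Continuous-Flow Immobilized-Enzyme Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing and optimizing continuous-flow
    structured-bed enzyme reactors. Implements a two-iteration fractional
    spherical central composite design engine that maximizes space-time
    yield over flowrate, temperature and dilution ratio; residence-time
    distribution analysis of dual-point step-tracer data with inlet
    moment correction and Bodenstein number estimation under the
    open-open axial dispersion model; the standard process metrics of
    flow biocatalysis (conversion, yield, space-time yield, dosing,
    immobilization yield, activity units, inline UV-Vis quantification);
    and a virtual reactor with Michaelis-Menten kinetics on a
    tanks-in-series cascade plus a tracer-step generator, so whole
    optimization campaigns can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
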
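Package: nrpathways
Title: Cost-Effective Reactive Nitrogen Control Pathways for PM2.5 Mitigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying cost-effective reactive-nitrogen (NH3 and NOx)
    emission-control pathways for fine-particulate (PM2.5) mitigation. Provides a
    self-contained synthetic study domain with a simplified secondary-inorganic-aerosol
    equilibrium response to emission controls, GEMM-based exposure-mortality burden
    estimates with Monte Carlo confidence intervals, WHO air-quality-guideline
    attainment metrics, instant-efficiency and ammonia-saturation (G ratio) regime
    diagnostics with tipping points, and gradient-based optimal-pathway analysis on
    the (NH3, NOx) control plane including abatement-cost surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
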
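Package: pancslice
Title: Quantitative Analysis of Long-Term Pancreatic Slice Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative side of long-term organotypic
    pancreatic slice culture. Includes a finite-volume 2D oxygen
    reaction-diffusion model of transwell and gas-permeable (PFC) membrane
    culture geometries with anoxic-volume statistics and oxygen-consumption
    parametric sweeps; evaporation-corrected glucose-consumption and
    lactate-production rate equations with DNA normalisation and an
    ATP-per-glucose efficiency index; perifusion trace analysis
    (stimulation indices and windowed areas under the curve); calcium-imaging
    trace quantification (dF/F, response acceptance criteria and
    beta-cell/acinar classification); longitudinal red/green/yellow
    lineage-tracing image quantification; and seeded synthetic-data
    generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    tibble,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    dplyr
Config/testthat/edition: 3
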
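Package: retinaflim
Title: Phasor FLIM Metabolic Analysis of Retina Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phasor-based analysis of multiphoton fluorescence lifetime
    imaging (FLIM) of retina sections. Transforms time-correlated
    single-photon-counting decay cubes into first-harmonic phasor
    coordinates, estimates bound-NAD(P)H (and free-FAD) percentages along
    a metabolic trajectory on the universal circle, partitions sections
    into eccentricity zones and outer/inner layer regions with fixed-width
    regions of interest, segments melanin, hemoglobin and
    second-harmonic-generation collagen by phasor position, and runs
    paired within-image comparisons. Includes a seeded retina-section
    phantom simulator (layered geometry, vascular plexuses, RPE
    hemoglobin bands, IRF-convolved TCSPC decays with Poisson noise) so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
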
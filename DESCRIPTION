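Package: phenoseason
Title: Autumn Photosynthetic Phenology Extraction and Preseason Climate Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the end of the growing season (EGS) from gridded
    composite vegetation-signal time series (SIF, EVI, NIRv or flux-tower
    GPP) by the dynamic-threshold and derivative methods, maps per-pixel
    linear trends of EGS, and attributes interannual EGS variation to
    preseason minimum temperature, maximum temperature and cumulative
    precipitation through an optimal-window partial-correlation search and
    standardized multiple-regression sensitivities. A seeded synthetic-scene
    generator with planted climate-senescence couplings provides fully
    testable inputs with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
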
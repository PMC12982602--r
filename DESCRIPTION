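Package: droughtlai
Title: Agricultural Drought Impact Mapping from LAI Time Series by Relative Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates leaf-area-index (LAI) relative thresholds and key
    phenological time windows against annual historical drought-area statistics,
    then extracts 500 m severity-coded agricultural drought-impact rasters
    (drought-covered, drought-damaged, crop failure) per crop season and year.
    Includes a seeded synthetic-scene generator (seasonal LAI phenology on an
    8-day composite calendar, crop masks, region partitions and derived
    historical statistics with known ground truth) so the whole pipeline is
    testable end to end, Savitzky-Golay smoothing and nearest-neighbour grid
    alignment, an exhaustive threshold/window grid search scored by Pearson
    correlation and RMSE, severity-coded GeoTIFF output in a fixed file naming
    convention, and validation/recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
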
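Package: dredgetrack
Title: Fishing-Activity Classification from Vessel Tracks and Landings-Value
    Exposure Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes commercial fishing activity from vessel-location
    data. High-resolution (AIS-style) tracks are resampled to a one-minute
    grid, summarized by rolling-window trajectory features, and classified
    into fishing versus transit states with a random decision forest trained
    on observer-verified hauls. Trips without high-resolution coverage fall
    back to speed-cutoff parsing of coarser VMS-style polls, and then to
    per-trip fishing-footprint probability rasters. Landed ex-vessel value is
    distributed over fishing locations and rasterized onto a 500 m grid to
    produce spatial exposure estimates, with zonal summaries over offshore
    wind lease polygons, comparison diagnostics (speed-cutoff baselines,
    footprint regression evaluation, kernel density comparisons, per-trip
    intrusion analysis), and a synthetic fleet generator for end-to-end
    validation without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    graphics,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
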
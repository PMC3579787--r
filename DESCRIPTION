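Package: nemameter
Title: Nematode Morphometry from Brightfield Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated measurement of nematode length, width and volume from
    brightfield microscope images. Worms appear as dark, radially symmetric
    tubes on a bright, unevenly illuminated agar background; the pipeline
    flattens the illumination with rolling-ball background subtraction,
    segments worms by Minimum-algorithm histogram thresholding and connected
    components, reduces each worm to an ordered medial path by topological
    thinning and shortest-branch pruning, samples radii orthogonal to the
    path, and integrates volume as a sum of conical frustums. Includes a
    synthetic phantom generator with analytic ground truth, CSV/overlay
    output for quality review, and the statistical procedures used for
    population comparisons: sample skewness and kurtosis, balanced
    subsampled Bonferroni t-tests, regression-slope comparison, and
    noncentral-t power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    jpeg,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
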
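Package: dotcenter
Title: Dot-Filter and Centerline Detection of Vessel-Attached Lung Nodules in 2D CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects juxtavascular (vessel-attached) pulmonary nodule candidates in
    two-dimensional lung CT slices. A multiscale Hessian-eigenvalue dot filter
    enhances circular, nodule-like structures while suppressing line-like vessels;
    a two-subiteration binary thinning algorithm with spur pruning extracts vessel
    centerlines; and a distance-rule classifier separates true vessel-attached
    nodules from the false positives the dot filter produces at vessel ends and
    crossings, using the perpendicular distance to a locally fitted centerline
    (d1) and the minimum distance to any skeleton pixel (d2) against a 1.5 mm
    threshold. A phantom generator (Gaussian dots and lines, single/Y/X vessel
    models, attached-nodule scenes) provides fully synthetic, reproducible test
    inputs so no clinical data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
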
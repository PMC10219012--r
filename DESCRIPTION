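Package: hingemount
Title: Virtual Hinge-Axis Mounting Values for Orthognathic Surgery Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for arbitrary virtual-articulator mounting in digital
    orthognathic surgery planning. Constructs the axis-orbital plane and an
    arbitrary hinge axis from four lateral-cephalogram landmarks via a
    virtual facebow, extracts the mounting triple (angle alpha between the
    upper occlusal plane and the axis-orbital plane, and the vertical and
    horizontal hinge-axis distances AxV and AxH), clusters surgical cohorts
    into skeletal phenotypes with k-means and an elbow criterion,
    characterises the clusters statistically (chi-square with Cramer's V,
    one-way ANOVA with Tukey HSD, Mann-Whitney U), derives Bonwill-arm and
    Balkwill-angle equivalents against their classical norms, and emits the
    3D rigid transform that mounts an intraoral scan against the virtual
    hinge axis. A synthetic-cohort generator with known ground truth makes
    every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
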
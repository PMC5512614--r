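Package: wormtrace
Title: Quantitative Analysis of Long-Term C. elegans Larval Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying post-embryonic development of Caenorhabditis
    elegans larvae from long-term time-lapse movies acquired in hydrogel
    microchambers. Fits a spline body axis from annotated centre-line points,
    transforms camera coordinates to body coordinates (arc length s along the
    anteroposterior axis, signed dorsoventral distance t) and computationally
    straightens images; represents developmental timelines (hatch plus four
    ecdyses) and stages; computes seam-cell division-timing statistics and a
    lineage-error probability matrix P(l,s) against a reference lineage;
    assembles distal-tip-cell migration trajectories with marker-based offset
    correction, sliding-average smoothing, velocity estimation and
    midline-crossing detection; quantifies oscillatory reporter expression via
    kymographs, regional and whole-animal traces, Otsu-masked nuclear
    intensities, per-stage peak detection and inter-cell correlation. A
    ground-truthed synthetic worm-movie generator makes every analysis path
    testable without microscope data.
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
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
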
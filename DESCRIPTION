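Package: stiflemorph
Title: Mesh-Based Morphometry of Rodent Knee Ligaments and Menisci
Version: 0.1.0
Authors@R:
    person("Olivia", "Reyes", email = "oreyes@example.org", role = c("aut", "cre"))
Description: Tools for slice-based morphometry of segmented rodent stifle
    (knee) soft tissues from triangle meshes. Computes ligament
    cross-sectional-area profiles by principal-axis alignment, incremental
    planar slicing and midsubstance (middle 50 percent) averaging; regional
    meniscus heights and widths from coronal and sagittal slices with ten
    measurement stations per slice; tibial plateau footprint areas from
    single-slice voxel masks or planar traces, used to normalize ligament
    size across species. Includes a seeded synthetic-geometry generator
    (ligament tubes, wedge menisci, plateau masks) with exact ground truth
    for validation, and the accompanying nonparametric statistical battery:
    Kruskal-Wallis with post hoc pairwise tests, aligned rank transform
    factorial ANOVA, Wilcoxon rank-sum, Bland-Altman agreement and
    two-way absolute-agreement ICC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
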
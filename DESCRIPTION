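Package: octmorph
Title: Skeleton-Based Morphometry, Quality Control and Statistics for
    Retinal OCT Layer Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation analysis engine for labeled murine optical
    coherence tomography (OCT) B-scans. Given per-pixel ocular layer masks,
    the package plans and extracts crops perpendicular to the tissue medial
    axis, registers crops to the optic nerve head, skeletonizes each layer
    and computes local thickness and local angle profiles, inflection and
    bifurcation counts, connected-domain summaries and retinal-detachment
    metrics. Rule-based image- and eye-level quality control, deduplication
    of technical replicates, eye- and mouse-level aggregation, nonparametric
    group statistics (Wilcoxon rank-sum with Cliff's delta, Kruskal-Wallis
    with Dunn's post hoc and epsilon-squared, Benjamini-Hochberg FDR), SEM
    volcano tables and hierarchical clustering for focal-lesion discovery
    complete the pipeline. A synthetic retina-phantom generator with known
    ground truth stands in for the instrument and segmentation networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
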
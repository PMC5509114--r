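Package: toothtrace
Title: Outline Morphometrics and Quality Control for Crowdsourced Tooth Tracings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning tracings of bovid tooth occlusal surfaces into
    homologous landmark outlines and classifying them to taxonomic tribe.
    Implements elliptical Fourier analysis of closed outlines with
    canonical-start landmark regeneration, the Riemannian (Procrustes) shape
    distance in Kendall shape space for grading crowd-worker tracings against
    a gold standard, full-Procrustes consensus shape averaging with
    distance-threshold outlier rejection, and random-forest tribe
    classification under leave-one-out cross-validation scored by log-loss.
    A synthetic-data module simulates tribe-structured shape populations and
    crowd-worker tracing noise (correlated outline jitter, gross errors,
    dropout) so the whole pipeline can be exercised and tested without
    photographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    EBImage,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
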
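Package: voletooth
Title: Outline Morphometrics and Species Classification of Arvicoline First Lower Molars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns calibrated images or line drawings of arvicoline (vole and
    lemming) first lower molars (m1) into 200-landmark representations of the
    anterior semiperimeter of the occlusal outline, classifies specimens to
    species with four methods (modified Hausdorff distance against specimens or
    species centroids, Procrustes nearest neighbour, Fisher canonical
    discriminant with Mahalanobis assignment, and one-vs-one linear SVMs under
    an error-correcting output-code scheme), and measures the Van der Meulen
    linear indices (L, W, a, b, c, e) and the La/Li asymmetry automatically,
    with per-segment manual override. A parametric synthetic-molar generator
    provides labelled ground-truth outlines and rendered rasters so the whole
    pipeline is testable without access to a physical collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
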
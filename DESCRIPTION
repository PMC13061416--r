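Package: larvasleep
Title: Behavioral and Cellular Quantification of Drosophila Larval Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying developmental sleep
    in Drosophila. Classifies larval activity from time-lapse video by
    frame-differencing pixel-change scores, calls sleep bouts from runs of
    behavioral quiescence (>= 12 consecutive frames at 0.87 fps), computes
    wake-gated locomotion speed, sleep-deprivation schedules and rebound,
    scores adult sleep from TriKinetics DAM beam-crossing series (> 5 min
    immobility criterion) with light/dark phase splits, quantifies
    nuclear-localization indices of translocation-based calcium reporters
    and dye-based food intake from images, and provides the nonparametric
    group statistics (Mann-Whitney U, Kruskal-Wallis, chi-square,
    Bonferroni) and median/IQR summaries used throughout. A synthetic-data
    generator produces ground-truthed arena videos, DAM series, and cell
    images for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    generics,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
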
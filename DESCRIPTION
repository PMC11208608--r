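Package: sliceglia
Title: Quantification of Microglial Dynamics and Network Activity in Acute Brain Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable reimplementation of the quantification pipelines
    used to characterise microglial phenotype changes and their effect on neuronal
    network activity in acute brain slices. Provides sharp wave-ripple (SWR)
    detection from local field potentials with zero-phase RC filtering, extraction
    and two-cluster (flash/surge) classification of focal extracellular-ATP sensor
    events from two-photon time-lapse movies, microglial process-recruitment
    metrics, slice-depth translocation metrics, and histological microglia-synapse
    and microglia-soma interaction metrics. Every input can be generated
    synthetically with known ground truth, so all stages are testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
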
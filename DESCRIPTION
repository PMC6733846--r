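Package: popclock
Title: Population-Clock Analyses of Somatosensory-Evoked Striatal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing rhythmic somatosensory responses in neural
    populations and timing behavior on a treadmill task. Provides an
    inhomogeneous-Poisson simulator of evoked spiking populations and
    stereotyped treadmill sessions, peri-event histogram construction with
    baseline confidence limits and response-latency classification,
    population-vector construction with PCA state-space trajectories and
    silhouette cluster validation, elapsed-time decoding with one-against-one
    support vector machines and surrogate controls, and trial-level behavioral
    metrics (entrance times, stereotypy indices, phase segmentation, speed
    statistics) together with spike-behavior coupling measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    cluster,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
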
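Package: escapeCircuit
Title: Pathway Convergence, Circuit Electrophysiology Metrics, and
    Synaptic Puncta Counting for the Drosophila Escape Circuit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the Drosophila giant fiber (GF)
    escape circuit. Builds synapse-count-weighted directed connectome
    graphs from exported connectivity tables, computes source-to-target
    shortest pathways with synapse-count tie-breaking, bounded-hop
    pathway censuses, relay-class convergence fractions and direct-input
    censuses; derives circuit read-out metrics from stimulus/response
    event data (short- and long-latency response classification,
    refractory period, following frequency 50%, coefficient of
    variation); quantifies all-or-none habituation (response-probability
    curves over long stimulus trains, consecutive-failure onsets);
    counts round fluorescent puncta in two-channel anisotropic 3-D
    stacks by scale-normalized Laplacian-of-Gaussian detection with Otsu
    background thresholding and membrane-mask colocalization; and
    generates synthetic datasets with planted ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
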
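Package: udsnet
Title: Coupled Mean-Field Networks, Up-Down State Detection, and
    Functional Connectivity Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a pair of unidirectionally coupled
    excitatory-inhibitory-adapting mean-field networks exhibiting Up-Down
    state (UDS) oscillations, spontaneous persistent activity (SPA) and
    spontaneous persistent inactivity (SPI); renders simulated activity as
    realistic paired membrane-potential/LFP surrogate recordings;
    segments recordings into Up and Down states with an explicit-duration
    hidden Markov model; computes persistence, quantized-duration, delay
    and history statistics; and infers the afferent and recurrent
    excitatory weights (W_EXT, W_INT) of each recorded cell by matching
    observed SPA/SPI rates against a simulated parameter-grid library.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
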
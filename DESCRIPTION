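Package: repliprofile
Title: Marker-Frequency Replication Profiling of Circular Bacterial Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker frequency analysis (MFA) of deep-sequencing read
    counts from exponentially growing bacteria, aimed at Escherichia coli
    strains carrying ectopic or dual replication origins. Turns per-bin read
    counts (exponential-phase sample against a stationary-phase control) into
    normalized replication profiles, smooths them with a degree-2 tricube
    LOESS under periodic (circular) boundary conditions with a
    squared-residual outlier rule, locates termination minima, compares them
    with arithmetic midpoints and replichore lengths, scores locally
    steepened gradients at highly transcribed rrn operons, and detects gross
    chromosomal inversions from profile discontinuities. A forward simulator
    of replication-fork kinetics (polar ter/Tus traps, head-on and
    co-directional transcription slow zones, barrier pauses) generates
    replication timing, copy-number tracks, sequencing-count pairs and
    viable-count growth curves with the statistical structure the analysis
    assumes, and a log-linear estimator recovers doubling times from growth
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
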
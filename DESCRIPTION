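Package: wormcross
Title: Crossover Interference, Recombination Domains, and Segregation
    Distortion in Caenorhabditis Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genetic analysis of gonochoristic Caenorhabditis crosses built
    around an advanced-intercross (G4BC2) experimental design. Simulates
    meiosis and multi-generation pedigrees under complete crossover
    interference (or a Poisson null) and tests observed crossover counts
    against the simulated null; builds Marey maps from marker tables and
    estimates tip/arm/center recombination domains by exhaustive continuous
    three-segment least-squares regression; models two-locus maternal-effect
    (Medea) segregation distortion across a sixteen-cross panel and estimates
    locus penetrances with Agresti-Caffo interval propagation; computes
    autosome-X cosegregation (skew) statistics from two-by-two offspring
    counts; and provides genome-composition statistics (windowed GC,
    nested-mask feature GC, telomeric repeat counting, relative synonymous
    codon usage, amino-acid usage). A synthetic-data module generates every
    input the analyses consume, with recorded ground truth, so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
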
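Package: corescan
Title: Core Promoter Element Detection and TSS Dataset Quality Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of core promoter elements (TATA box, initiators,
    downstream elements, pausing-associated motifs) and arbitrary user-defined
    motifs in DNA sequences using GC-normalized log2-likelihood position
    weight matrix scoring on both strands. Supports dependency-aware calling
    of composite elements (downstream elements anchored to an initiator A+1
    at constrained spacing), positional-distribution statistics of detected
    motifs relative to the transcription start site for appraising the
    quality of high-throughput TSS datasets, and a seeded synthetic promoter
    generator for validation. Includes a command-line interface with scan,
    qc and simulate subcommands.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
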
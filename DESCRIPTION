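Package: drpseq
Title: Double-Random-Priming Whole-Transcriptome Sequencing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of double-random-priming (DRP)
    whole-transcriptome amplification libraries, in which every cDNA
    fragment is flanked by a fixed 25-nt MALBAC adapter plus a random
    octamer at both ends. Provides a library simulator with full ground
    truth (log-normal transcript abundances, panhandle-suppressed
    fragment sizes, a per-cycle branching-process PCR duplication model,
    ERCC-style spike-ins), the matching read-processing pipeline
    (Illumina-adapter stripping, forward-adapter gating, dual-mode
    trimming against the reverse adapter or a 120-nt window,
    identical-read collapsing with the octamer as molecular counter,
    octamer removal and a 30-nt length filter), a toy substring
    quantifier producing FPKM without effective-length correction, and
    downstream analytics: saturation curves, gene-biotype composition,
    rRNA base fraction, gene-body coverage, spike-in linearity,
    replicate concordance, detection overlap, dilution-control
    subtraction of differential lists, deterministic complete-linkage
    clustering and microarray probeset collapse rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
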
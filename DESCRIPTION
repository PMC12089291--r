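Package: karyotracer
Title: Karyotype Evolution from Shared Chromosome Fusion Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing ancestral karyotypes and tracing
    chromosomal rearrangements from gene order. Builds collinear synteny
    blocks from homologous gene pairs, paints genomes by protochromosomes,
    detects and classifies chromosome fusions (reciprocal translocation,
    end-to-end joining, nested chromosome fusion), tests fusion-breakpoint
    sharing across genomes with 100-gene windows, roots rearrangement
    directionality with outgroups, infers evolutionary relationships from a
    genomes-by-breakpoints copy-number matrix under a Dollo assumption, and
    phases allopolyploid subgenomes to assign parentage. Includes a karyotype
    evolution simulator with recorded ground-truth histories for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
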
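Package: bcrpipe
Title: B-Cell Receptor Repertoire Simulation, Annotation and Overlap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heavy-chain B-cell receptor (BCR) repertoire analysis
    built around AIRR Rearrangement TSV files: a ground-truth V(D)J
    recombination and somatic-hypermutation simulator for cohort designs with
    isotype bias, skewed clone sizes and spiked public clonotypes; a
    deterministic germline annotator (banded local alignment, CDR3 extraction
    at the conserved Cys-104/Trp-118 anchors, V-region mutation counting);
    clonotyping under CDR3 amino-acid and full VDJ nucleotide definitions with
    read-normalized diversity, IGHV usage and mutation summaries; and
    cross-repertoire comparison (sharing spectra, Jaccard matrices, 3-set Venn
    partitions, plurality consensus of shared CDR3s, and UPGMA repertoire
    similarity trees), orchestrated by a reproducible pipeline with a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
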
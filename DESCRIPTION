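Package: mitotx
Title: Mitochondrial Transcription-Unit Calling and Transcript End Mapping
    for tRNA-Poor Mitogenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the mature mitochondrial transcriptome of organisms whose
    mitogenomes lack the usual tRNA punctuation marks (octocorals carry a
    single tRNA-Met), from an annotated circular mitogenome and strand-aware
    RNA-seq alignments. Calls mono- and polycistronic transcription units from
    intergenic-region-spanning read pairs, discriminates mature polycistrons
    from low-abundance precursor read-through using coverage discontinuity,
    maps transcript 5'/3' ends and untranslated regions from circularized-RT
    and RACE style junction reads, clusters alternative polyadenylation sites,
    classifies antisense long noncoding RNAs, predicts control regions from
    uncovered intergenic regions with stem-loop structures and conserved
    motifs, and quantifies relative transcript abundance from qPCR data with
    an efficiency-corrected randomization test. A fully parameterized
    synthetic-data generator emulates the transcription program of an
    arrangement-A octocoral mitogenome so that every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
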
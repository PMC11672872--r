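Package: lengthome
Title: Transcript Length Dynamics, Isoform Switching and Splice-Mechanism
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the "length-ome" of differentially expressed
    transcripts: volcano filtering of isoform-resolved microarray tables,
    comparison of 5'UTR/CDS/3'UTR length distributions and exon-count spectra
    against a reference exome, detection of condition-to-condition mRNA isoform
    switching from dual gene/isoform identifiers, and algorithmic classification
    of the splicing mechanism behind each length change, including extraction
    and consensus scoring of donor/acceptor splice signals. Ships a synthetic
    genome/annotation/expression-list generator with planted ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, AlternativeSplicing, GeneExpression, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'transcript-models.R'
    'annotation-io.R'
    'deg.R'
    'fixture.R'
    'length-stats.R'
    'lengthome-package.R'
    'mechanisms.R'
    'switching.R'
    'pipeline.R'
    'simulate.R'
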
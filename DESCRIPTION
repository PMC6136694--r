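Package: spo0scan
Title: Genome-Context Prediction of Sporulation-Initiation (Spo0) Pathway
    Components and Architecture in Firmicutes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the components of the bacterial sporulation-initiation
    (Spo0) signal transduction pathway from annotated genomes. Spo0F and Spo0B,
    the phosphorelay intermediates, resist detection by sequence similarity, so
    they are located through conserved gene neighborhoods anchored on marker
    domains (fructose-bisphosphate aldolase, transaldolase and CTP synthase for
    Spo0F; ribosomal proteins L21/L27 and the GTPase ObgE for Spo0B). The
    package also inventories histidine kinases, decides orphan status and
    N-terminal PAS sensor content to nominate candidate sporulation kinases,
    extracts phosphotransfer specificity-residue signatures by anchored local
    alignment (six kinase-side, seven receiver-side positions), calls a
    per-genome pathway architecture (phosphorelay versus direct
    phosphorylation), and summarizes the architecture distribution on a
    species phylogeny with a Fitch parsimony transition count. A synthetic
    genome generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ComparativeGenomics, Annotation, Phylogenetics, Software
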
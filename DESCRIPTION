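Package: pulminer
Title: Mining Polysaccharide Utilization Loci for Novel Carbohydrate Esterases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate carbohydrate-active enzymes in
    annotated (meta)genomic contigs via polysaccharide utilization locus (PUL)
    detection. Detects susD-anchored gene clusters from GFF3 gene models and
    CAZy/Pfam domain-hit tables, infers the glycan target of each locus from
    its glycoside hydrolase and carbohydrate esterase content, and shortlists
    proteins of unknown function (PUFs) for biochemical follow-up. Companion
    modules classify homolog-search hits by PUL genomic context and test
    clade/context concordance on phylogenies, annotate MALDI-TOF peak lists of
    substituted xylooligosaccharides by residue-composition mass decomposition
    (sodium adducts), and fit substrate-inhibition Michaelis-Menten kinetics
    with model comparison against the plain Michaelis-Menten law. A seeded
    synthetic-data module generates complete desk-scale fixtures (contigs with
    planted PULs, before/after esterase spectra, noisy rate curves) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
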
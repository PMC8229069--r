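Package: satprof
Title: Satellite DNA Monomer Alteration Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling single-nucleotide alterations in satellite
    DNA monomer consensus sequences obtained by Sanger sequencing of
    PCR-amplified repeat fragments (the CON1/CON2/COM2 families of the
    Aveneae/Poeae tribe). Per-accession IUPAC-coded consensi are aligned to
    a family reference monomer with an ambiguity-aware semi-global aligner,
    alteration columns are detected in the reference-anchored multiple
    alignment together with their zygosity states (homozygous, two-base
    heterozygous, three-base "triplet"), accessions are partitioned into
    alteration-profile groups, and ultrametric schematic trees are built by
    UPGMA over a column-averaged Jaccard profile distance. A seeded
    synthetic-data generator emulates planted-mutation Sanger consensi and
    ships a fully specified CON2 worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
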
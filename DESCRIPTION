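Package: ceacamr
Title: Evolutionary Analysis of Paired Immune Receptor Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the molecular evolution of paired immune
    receptor gene families such as the amphibian ceacam clusters: Nei-Gojobori
    pathway-averaged dN/dS with cumulative per-codon substitution profiles,
    sliding-window percent identity, detection of gene-conversion tracts as
    runs of codons depleted of synonymous substitutions with a permutation
    null, ITIM/ITSM/ITAM motif scanning, pseudogene calling and gene-model
    rules, distance-based neighbor-joining orthology and subgroup assignment
    with bootstrap support, paired-receptor identification, selection ranking
    and homeologous-locus comparison, plus a forward simulator of tandem
    receptor-gene cluster evolution that emits FASTA/GFF3 inputs with full
    event truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn
SystemRequirements: mafft (for multiple alignment used by bootstrap_support)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
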
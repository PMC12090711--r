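Package: PGscreen
Title: Pangenome Screening for Phenotype-Linked Genes with the Potential-Gene Index
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative pangenome screen linking orthologous gene groups (OGs)
    to a binary strain phenotype. Strains are classified into "active" and
    "silent" groups by a median split of duplicate cytokine measurements
    (e.g. IL-10 / IL-12 induction, pg/mL); every OG is scored with the
    potential-gene (PG) index, a Calinski-Harabasz index computed between the
    phenotype groups on the rows of the OG's amino-acid p-distance matrix and
    scaled by a sequence-distribution factor; candidates are screened by
    top-2% selection, K=2 k-means re-clustering with a recalculated CH index,
    cross-cytokine overlap, rank tests, and a presence/absence marker screen.
    Includes readers for the Roary gene_presence_absence.csv dialect and
    per-OG FASTA files, classical multidimensional scaling of candidate-gene
    distances, and a fully deterministic synthetic pangenome generator with
    planted phenotype-linked alleles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: ComparativeGenomics, Clustering, Classification, Software
RoxygenNote: 7.3.3
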
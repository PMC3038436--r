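Package: orthopipe
Title: Single-Copy Ortholog Supermatrix Phylogenomics from Predicted Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated phylogenomic pipeline that takes unaligned predicted
    proteomes (FASTA) plus all-vs-all similarity search results (BLAST tabular)
    and produces species trees. Stages: sequence quality control and header
    aliasing; construction of a weighted protein similarity graph from e-values;
    Markov clustering (MCL) across a sweep of inflation parameters; selection of
    single-copy ortholog clusters with a most-stringent-first non-redundancy
    filter and a best-hit consistency rule; per-cluster alignment (builtin
    progressive aligner or external-tool adapters); alignment editing (gap-column
    removal and Gblocks-style conserved-block trimming at conservative and
    liberal settings); taxon normalization and concatenation into three
    supermatrices with RAxML-style partition files; amino-acid substitution
    model ranking by AIC under empirical matrices with +G/+F variants; and
    neighbor-joining trees with bootstrap majority-rule consensus and outgroup
    rooting. A synthetic-data generator with planted orthology makes every stage
    testable without external binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    Matrix,
    ape,
    phangorn,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
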
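# orthopipe

Phylogenomic species-tree inference from predicted proteomes, for people who
have a stack of genome annotations and want a defensible multi-gene tree
without hand-curating orthologs. Starting from one protein FASTA per genome
and an all-vs-all similarity search (BLAST 12-column tabular), orthopipe:

1. quality-checks sequences and maps unparseable headers to short unique
   aliases;
2. builds a weighted protein graph from e-values
   (`w(u,v) = max(min(−log10 E, 200))` over both directions) and clusters it
   with a from-scratch sparse Markov clustering (MCL) implementation across
   an inflation sweep (default 1.1–5.0, 13 values);
3. keeps only single-copy clusters (≤ 1 protein per genome, ≥ the chosen
   fraction of taxa present), filtered most-stringent-inflation-first into a
   non-redundant set where every member's per-genome best hit lies inside
   its own cluster;
4. aligns each cluster (builtin progressive aligner, or adapters for
   MUSCLE/MAFFT/CLUSTALW/PROBCONS) and edits the alignments three ways:
   `remgaps` (drop all gap columns), Gblocks-style conserved-block trimming
   with conservative (4 contiguous nonconserved / min block 10) and liberal
   (8 / 5) settings;
5. normalizes every alignment to the common taxon set (`?` for missing
   genomes) and concatenates three supermatrices with RAxML-style partition
   files;
6. ranks amino-acid substitution models (Dayhoff, JTT, WAG, LG, RtREV ×
   {+G, +F}) per alignment by AIC = 2k − 2lnL using a Felsenstein-pruning
   likelihood engine on a fixed NJ base tree, and summarizes best models,
   ranked tables, best-model frequencies, and the one-model choice;
7. infers a neighbor-joining tree per supermatrix from JTT
   maximum-likelihood distances, with column bootstrap and a strict (>50%)
   majority-rule consensus, optionally rooted on an outgroup.

Every run is checkpointed: if interrupted, `resumePipeline()` restarts at
the first uncompleted (or corrupted) step and reproduces the uninterrupted
products byte-for-byte, because all randomness derives from the single
configured seed. A synthetic-data generator with planted single-copy,
lineage-restricted, and paralogous families makes the whole pipeline
testable without downloads or external binaries.

## Worked example

Generate a small planted fixture (4 genomes, 6 single-copy families, 1
paralogous family) and run the full pipeline:

```r
library(orthopipe)

spec <- fixtureSpec(nGenomes = 4, nSingleCopy = 6, nParalog = 1,
                    ancestorLength = 60, seed = 5)
dir <- tempfile("demo")
fx <- generateProteomes(spec, file.path(dir, "proteomes"))
ps <- buildAliasMap(readProteomes(fx$paths))
ps
#> ProteomeSet with 4 genomes, 32 proteins
#>   genome01: 8 proteins
#>   genome02: 8 proteins
#>   genome03: 8 proteins
#>   genome04: 8 proteins

synthHitTable(ps, fx$truth, file.path(dir, "hits.tsv"), spec)
cfg <- runConfig(inputDir = file.path(dir, "proteomes"),
                 hitsFile = file.path(dir, "hits.tsv"),
                 outputDir = file.path(dir, "run"),
                 bootstrapReplicates = 20, minAlignmentLength = 20,
                 seed = 1)
runPipeline(cfg)
```

The run log ends by naming the products — three supermatrices (FASTA +
relaxed PHYLIP + partition summary) and three consensus trees, one per
editing mode. The paralogous family is rejected by the single-copy filter;
the six clean families become partitions:

```
cat run/models/partition_remgaps.txt
#> JTT, c0001 = 1-60
#> LG, c0002 = 61-120
#> JTT, c0003 = 121-180
#> JTT, c0004 = 181-240
#> JTT, c0005 = 241-300
#> JTT, c0006 = 301-360

cat run/trees/nj_consensus_gblocks_liberal.nwk
#> (genome01,genome02,(genome03,genome04)100);
```

The partition lines give each cluster's 1-based column range in the
supermatrix and its best AIC-ranked model; the Newick node label is the
bootstrap percentage of the (genome03, genome04) bipartition — 100% of the
20 replicates here, matching the genome tree the fixture was evolved down.

The same stages are available individually (`runStep("filter", cfg)`, ...)
or from a shell via the thin wrapper:

```sh
exec/orthopipe run --input proteomes/ --hits hits.tsv --out run/ --seed 1
exec/orthopipe resume --out run/
```

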
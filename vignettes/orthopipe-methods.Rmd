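---
title: "orthopipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthopipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

orthopipe turns a set of predicted proteomes (one FASTA per genome) plus an
all-vs-all protein similarity table into species trees, through single-copy
ortholog clusters, edited per-cluster alignments, concatenated supermatrices
with partitioned substitution models, and bootstrapped neighbor-joining
consensus trees. This vignette explains the model and procedure behind each
stage, the parameters that matter, and the design decisions taken where a
choice was genuinely open.

## Sequence QC and aliasing

Predicted proteomes from different sequencing centers carry wildly
inconsistent FASTA headers, so no attempt is made to parse them. Each
surviving sequence instead receives a short unique alias `g<G>_p<N>` (genome
ordinal, per-genome protein ordinal, zero-padded so lexicographic and numeric
order coincide), and a bidirectional map preserves the original headers
exactly.

QC removes, per genome: later copies of a duplicated header (the first
occurrence is kept — the duplicate rule must pick one deterministically),
empty sequences, and sequences containing characters outside the accepted
alphabet. "Accepted" means the 20 standard residues plus the ambiguity and
extended codes `B Z X U J O`; a single terminal `*` (a translated stop) is
tolerated and stripped, while an internal `*` fails the alphabet check and
rejects the sequence. Proteomes are commonly distributed with terminal stops
but an internal stop usually flags a broken gene model, which is why we
reject rather than truncate. Lowercase residues are uppercased before the
check.

## The similarity graph

The input is 12-column BLAST tabular output (`outfmt 6`) from any all-vs-all
protein search run at an e-value cutoff of 0.1. `blastCommand()` shows the
conventions an external search should use (soft filtering of low-complexity
regions during seeding only, reported subjects capped at the number of
genomes); the parser does not depend on them.

Markov clustering needs a similarity, not an e-value. The transform used is

    w(u, v) = max over both directions of min(-log10 E, 200)

with `E = 0` mapped to the cap. The capped negative log is standard practice
when feeding BLAST e-values to MCL; symmetrizing by the maximum keeps a pair
connected when only one direction scored. The cap (200) only matters for
e-values below 1e-200 and keeps weights finite.

Per query and per target genome, the best hit is the subject with the
smallest e-value; ties break by higher bitscore, then by lexicographically
smallest subject alias. All three keys are content-based, so best hits do not
depend on the order of rows in the input file.

## Markov clustering

`mclCluster()` is a from-scratch sparse implementation of MCL: starting from
the column-stochastic matrix (self-loops weighted by each node's maximum
incident edge, 1.0 for isolated nodes), it alternates expansion (matrix
squaring) and inflation (entrywise power `I`, column renormalization),
pruning entries below 1e-8 and renormalizing, until the largest entry change
drops below 1e-6 or 200 iterations pass. Clusters are read off the limit
matrix: nodes retaining diagonal mass are attractors, attractors connected in
the limit structure form attractor systems, and every node joins the system
of its strongest attractor (ties to the lexicographically smallest). Member
lists and cluster order are sorted, making the partition independent of edge
insertion order.

The pruning threshold, tolerance, iteration cap, self-loop rule and
overlap resolution are configuration, chosen to match common MCL practice;
no claim of bit-exact parity with the MCL binary is made — tests assert
parity of cluster composition against a dense brute-force implementation of
the same update rules, on graphs small enough to enumerate.

The inflation parameter controls granularity: low values give few large
clusters, high values many small ones. The default sweep
`1.1 1.2 1.3 1.4 1.5 1.7 2.0 2.5 3.0 3.5 4.0 4.5 5.0` spans lenient to
stringent so that both slow- and fast-evolving families can surface at some
setting.

## Cluster selection and filtering

From each clustering, candidates must be single-copy (at most one protein
per genome), have at least two members (a singleton cannot contribute to an
alignment), and cover at least `minTaxonFraction` of the genomes — e.g. 0.8
allows up to 20% missing taxa per cluster, trading completeness against the
rapid loss of fully represented single-copy clusters as genome count grows.

A candidate must also be best-hit consistent: for every member and every
*other* genome represented in the cluster, the member's best hit into that
genome (when it has one) must itself be a cluster member. One external best
hit rejects the whole cluster, not just the offending member — a cluster
containing a protein whose closest relative lies elsewhere is suspect as a
unit. Two readings of "best hit" were possible; we use per-(query, target
genome) best hits restricted to the genomes in the candidate, which matches
the reciprocal-best-hit tradition and is robust to missing taxa.

The sweep is filtered most-stringent-first: clusterings in decreasing
inflation order; within one clustering, candidates by decreasing size, then
by lexicographically smallest member (an invented but content-based order —
the across-inflation order is the method's requirement, the within-inflation
order just has to be deterministic). A candidate is accepted only if it also
shares no protein with anything already accepted, so each protein is
represented at most once in the final set.

## Alignment and editing

Each accepted cluster is aligned as whole proteins. The builtin aligner is a
plain progressive aligner — neighbor-joining guide tree from 6-mer cosine
distances, profile-profile Needleman–Wunsch with BLOSUM62 sum-of-pairs
column scores and affine gaps (open 10, extend 0.5) — included so the whole
pipeline runs and is testable with no external binaries. It makes no claim
of parity with MUSCLE; `alignerCommand()` builds the invocations for
MUSCLE (`-stable` to keep input order), MAFFT, CLUSTALW and PROBCONS for
users who want them, and the adapter contract (every input sequence present,
rows in input order, ungapping reproduces the input) is what the rest of the
pipeline relies on.

Three edited versions of every alignment are produced:

* **remgaps** — delete every column containing a gap; the strictest edit.
* **gblocks_conservative** — conserved-block trimming with at most 4
  contiguous nonconserved positions and minimum block length 10.
* **gblocks_liberal** — the same with 8 and 5, keeping the most data.

The block trimmer classifies a column as nonconserved when it contains any
gap or its majority residue count is below `floor(n/2) + 1`; deletes
nonconserved runs longer than the allowance; splits at the deletion points;
trims each block to start and end on conserved columns; and drops blocks
shorter than the minimum. The two quoted knobs per setting are honored
exactly; the remaining behavior (the conservation threshold, no-gap rule,
and block-end trimming in place of a flank-percentage criterion) adapts the
original Gblocks defaults, and bit-exact Gblocks parity is explicitly a
non-goal. Note the three modes are not mathematically ordered in output
length — remgaps is *typically* the most destructive, but a pathological
alignment can invert the order, so tests treat the ordering as a tendency,
not a theorem.

## Supermatrices

After editing, alignments shorter than `minAlignmentLength` columns are
dropped. Row names are exchanged from aliases to (sanitized) organism names,
every alignment is normalized to the common taxon list — absent genomes
filled with `?` across the cluster's width — and the normalized alignments
are concatenated in lexicographic cluster-id order (the order had to be
deterministic; nothing else depends on it). Normalization happens *after*
editing, so `?` fill never influences which columns are trimmed. The
partition map records each cluster's 1-based inclusive range and model and
is written in the RAxML protein dialect (`WAG, c0001 = 1-10`), plus FASTA
and relaxed-PHYLIP supermatrix writers. The relaxed-PHYLIP reader/writer is
a deliberate few-line implementation so that `?`-padded matrices round-trip
byte-identically.

## Substitution models and AIC ranking

Five published empirical exchangeability sets (Dayhoff, JTT, WAG, LG,
RtREV) ship as PAML-style lower-triangle text files with provenance headers.
Each defines a reversible CTMC `Q_ij = s_ij π_j`, scaled to one expected
substitution per unit time; transition matrices come from the cached
spectral decomposition of the symmetrized generator. Variants: `+F` replaces
the published frequencies with observed alignment frequencies (19 free
parameters; a pseudocount of 0.5 per residue keeps them strictly positive),
and `+G` adds discrete-gamma rate variation with 4 equal-probability
categories whose rates are the bin means (1 free parameter, the shape).

Likelihoods use Felsenstein pruning with per-node column rescaling; `?`,
`-`, `X` (and other unknowns) are fully ambiguous, `B`, `Z`, `J` partially
ambiguous. Ranking per alignment fixes a base tree — neighbor joining on JTT
ML distances — and holds branch lengths constant across models, optimizing
only the gamma shape (golden-section on [0.05, 50], tolerance 0.01). This is
a deliberate fast approximation in the spirit of quick model screening:
`k` counts only +G (1) and +F (19), AIC = 2k − 2lnL, ties break by model
name. `+I` variants and AICc/BIC ranking are out of scope. Because branch
lengths are not re-optimized per model, ranks on borderline data can differ
from a full optimization.

Four summaries are produced per supermatrix mode: best model per alignment,
the full ranked tables, the frequency with which each model ranked first,
and the partition file with per-cluster model assignments. The single most
frequently top-ranked model (ties to the lexicographically smallest, and
flagged) is the whole-matrix choice.

## Distances, neighbor joining, bootstrap consensus

Pairwise distances are maximum-likelihood under JTT with no rate variation:
the branch length maximizing the two-sequence likelihood, found by
golden-section on [1e-6, 10]. Columns with a gap, `?`, `X` or non-standard
residue in either row are excluded pairwise — complete deletion would
discard nearly everything in a `?`-padded supermatrix. Site-pair counts are
canonicalized to unordered pairs, so reversibility makes the distance
exactly symmetric in floating point. A pair with no comparable columns stops
the analysis with the offending pair named.

`neighborJoining()` implements Saitou–Nei agglomeration with the
Studier–Keppler criterion; ties break on the smallest index pair, negative
branch lengths clamp to zero with the clamped total reported, and additive
matrices are reconstructed exactly (tested against an independent
implementation and on random additive trees).

The bootstrap resamples columns with replacement (seeded), builds one NJ
tree per replicate, and returns the majority-rule consensus: exactly the
bipartitions in strictly more than 50% of replicates, annotated with integer
percentages. "Strictly more" matters: a 50/50 split between two conflicting
resolutions yields neither. The consensus is assembled directly from the
surviving (necessarily compatible) splits, so the threshold semantics are
exact rather than delegated; with an outgroup the tree is rooted on the
outgroup's pendant edge, which cannot change any support value. Trees are
ape `phylo` objects throughout — the field's standard container — with
supports as node labels, serialized to Newick at 6 decimal places.

## Pipeline orchestration

`runPipeline()` executes nine steps — qc, graph, sweep, filter, align, trim,
concat, models, trees — each reading and writing files under the output
directory, so each is equally usable in isolation via `runStep()` or the
`orthopipe` command-line wrapper. The manifest records per-step status,
output paths, content (MD5) fingerprints and the parameters that step
depends on. `resumePipeline()` skips steps that are done with intact
fingerprints and unchanged parameters and re-runs everything downstream of
the first failure, change or corruption; in particular, changing the aligner
invalidates the align step and restarts from there. Every trim mode yields
its own supermatrix, partition file and consensus tree, so a default run
produces three of each.

All randomness flows from the single config seed; each step seeds a
deterministic offset of it at start, which makes a resumed run
byte-identical to an uninterrupted one and the step-by-step composition
byte-identical to `runPipeline()`.

## The synthetic-data generator

`generateProteomes()` plants known orthology so every stage can be tested
against truth: families evolve from a random ancestor (drawn from the JTT
stationary frequencies) down a random coalescent genome tree, rescaled to a
mean root-to-tip depth of 0.5 substitutions/site — enough divergence to be
non-trivial while keeping within-family identities far above the unrelated
baseline. Defaults are 5 genomes, 20 single-copy families, 5 paralogous
families (2 copies per genome, the duplicate diverged by a further 0.03 —
i.e. recent, so its cross-genome best hits are ambiguous between the two
copies and paralogous clusters fail single-copy or best-hit filters rather
than sneaking through), protein length 120. Lineage-restricted families
take a coverage fraction and drop a random genome subset.

`synthHitTable()` emulates the all-vs-all search without running one:
within-family pairs get e-values from a monotone map of percent identity
(100% → the 1e-180 floor; at or below the 25% unrelated baseline → 1.0,
above the parsing cutoff), written in both directions with self-hits;
cross-family pairs are absent except an optional contamination fraction.

What the generator does *not* emulate: indels (families stay colinear, so
planted alignments are gap-free and trimming behavior on gappy data is
exercised by separate randomized tests), domain shuffling, compositional
bias, and realistic e-value statistics. Passing the planted-recovery tests
therefore demonstrates the clustering/filtering logic, not robustness to
every pathology of real proteomes.

## Problem sizes and numerical choices

The test-suite and acceptance computations use desk-scale sizes chosen to
exercise every code path: clustering-recovery fixtures of 5 genomes × 25
families (150 proteins), end-to-end pipeline fixtures of 4 genomes × 7
families with 10–20 bootstrap replicates, oracle comparisons on ≤ 30-node
graphs and ≤ 5-taxon trees where dense/exhaustive enumeration is exact.
Species-tree recovery on random coalescent trees is reported, not asserted:
a coalescent draw can contain an arbitrarily short internal edge, and a
>50% bootstrap consensus on a few hundred columns legitimately fails to
resolve it.

Numerical details worth knowing: pruning rescales per node and column to
avoid underflow; golden-section searches use tolerance 1e-6 (distances) and
1e-2 (gamma shape); MCL comparisons are exact because both implementations
prune and renormalize identically; all tie-breaks anywhere in the package
are content-based (lexicographic or index-ordered), never dependent on hash
or insertion order.

## Known limitations

* Model ranks under the fixed-branch-length approximation can differ from
  full per-model optimization on borderline alignments.
* The builtin aligner is serviceable for well-conserved single-copy
  families, not a replacement for MUSCLE/MAFFT on hard alignments.
* Maximum-likelihood and parsimony tree search are out of scope; the
  package emits RAxML/PhyML command lines for users with those programs.
* Nucleotide input, EST/transcriptome data, and tree-based ortholog
  refinement are out of scope.
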
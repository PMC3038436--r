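#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
NULL

# Residues accepted by sequence QC: the 20 standard amino acids plus the
# ambiguity/extended one-letter codes. `*` is handled separately (terminal only).
.AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V")
.AA_EXTENDED <- c(.AA_STANDARD, "B","Z","X","U","J","O")

.QC_REASONS <- c("duplicate_header", "non_iupac_characters", "empty_sequence")

.TRIM_MODES <- c("remgaps", "gblocks_conservative", "gblocks_liberal")

#' ProteomeSet: per-genome protein collections with alias map and QC report
#'
#' Holds the QC-surviving protein sequences of a set of genomes, the
#' bidirectional map between original FASTA headers and short unique aliases,
#' and the QC rejection report. Construct with [readProteomes()] and assign
#' aliases with [buildAliasMap()].
#'
#' @slot genomes ordered character vector of genome identifiers.
#' @slot proteins [Biostrings::AAStringSet] of all sequences, named by alias
#'   once [buildAliasMap()] has run (provisional `genome|header` names before).
#' @slot aliasMap `DataFrame` with columns `alias`, `genome_id`,
#'   `original_header`, one row per protein, parallel to `proteins`.
#' @slot qcReport `data.frame` with columns `genome_id`, `header`, `reason`.
#' @exportClass ProteomeSet
setClass("ProteomeSet",
  representation(genomes = "character",
                 proteins = "AAStringSet",
                 aliasMap = "DataFrame",
                 qcReport = "data.frame"))

setValidity("ProteomeSet", function(object) {
  msg <- character()
  am <- object@aliasMap
  if (nrow(am) != length(object@proteins))
    msg <- c(msg, "aliasMap must have one row per protein")
  if (nrow(am) > 0) {
    if (anyDuplicated(am$alias))
      msg <- c(msg, "aliases must be unique")
    if (!all(am$genome_id %in% object@genomes))
      msg <- c(msg, "every record's genome_id must appear in genomes")
    key <- paste(am$genome_id, am$original_header, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated original_header within a genome")
  }
  if (nrow(object@qcReport) > 0 &&
      !all(object@qcReport$reason %in% .QC_REASONS))
    msg <- c(msg, "qcReport reasons must come from the fixed enumeration")
  if (length(msg)) msg else TRUE
})

#' SimilarityGraph: weighted directed protein graph from e-values
#'
#' Nodes are all QC-surviving protein aliases (isolated nodes permitted);
#' directed edges carry the minimal e-value and its bitscore for each
#' (query, subject) pair at or below the configured cutoff; `bestHits` indexes,
#' for each query and each target genome, the subject with the smallest
#' e-value (ties: highest bitscore, then lexicographically smallest alias).
#'
#' @slot nodes character vector of aliases.
#' @slot edges `data.frame` with columns `query`, `subject`, `pident`,
#'   `length`, `evalue`, `bitscore`.
#' @slot bestHits `data.frame` with columns `query`, `genome`, `subject`,
#'   `evalue`, `bitscore`.
#' @slot cutoff numeric e-value cutoff the edges were filtered at.
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
  representation(nodes = "character",
                 edges = "data.frame",
                 bestHits = "data.frame",
                 cutoff = "numeric"))

setValidity("SimilarityGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(e$evalue > object@cutoff))
      msg <- c(msg, "edge e-values must not exceed the cutoff")
    if (any(e$query == e$subject))
      msg <- c(msg, "self-hits must be excluded")
    if (!all(c(e$query, e$subject) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Clustering: one MCL partition of the protein graph
#'
#' @slot inflation numeric inflation parameter used.
#' @slot clusters list of character vectors, a partition of the node set.
#' @slot iterations integer number of expansion/inflation iterations run.
#' @slot converged logical, whether the iteration reached the tolerance.
#' @exportClass Clustering
setClass("Clustering",
  representation(inflation = "numeric",
                 clusters = "list",
                 iterations = "integer",
                 converged = "logical"))

setValidity("Clustering", function(object) {
  members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(members))
    return("clusters must be disjoint")
  if (any(lengths(object@clusters) == 0))
    return("clusters must be non-empty")
  TRUE
})

#' ClusterSet: accepted single-copy ortholog clusters plus rejection log
#'
#' Produced by [filterSweep()]. Each accepted cluster is a list with elements
#' `members` (aliases), `inflation`, `taxa` (genome ids) and `taxonFraction`;
#' accepted clusters are pairwise disjoint.
#'
#' @slot accepted list of candidate-cluster lists.
#' @slot rejectionLog `data.frame` with columns `inflation`, `members`
#'   (members collapsed with `,`), `reason`.
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(accepted = "list", rejectionLog = "data.frame"))

setValidity("ClusterSet", function(object) {
  members <- unlist(lapply(object@accepted, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(members))
    return("no protein may appear in two accepted clusters")
  TRUE
})

#' ClusterAlignment: a gapped alignment of one ortholog cluster
#'
#' @slot clusterId character identifier.
#' @slot aln character matrix, one row per sequence (rownames are aliases or
#'   genome ids after name substitution), one column per alignment position;
#'   gap character `-`, missing data `?`.
#' @exportClass ClusterAlignment
setClass("ClusterAlignment",
  representation(clusterId = "character", aln = "matrix"))

setValidity("ClusterAlignment", function(object) {
  a <- object@aln
  if (!is.character(a))
    return("aln must be a character matrix")
  if (nrow(a) > 0 && is.null(rownames(a)))
    return("aln rows must be named")
  if (anyDuplicated(rownames(a)))
    return("row names must be unique")
  if (nrow(a) > 0 && any(nchar(a) != 1))
    return("aln cells must be single characters")
  TRUE
})

#' SuperAlignment: concatenated, taxon-normalized supermatrix
#'
#' @slot taxa ordered character vector of genome ids.
#' @slot matrix named character vector, one residue string per taxon
#'   (names = taxa, all equal length; missing data `?`).
#' @slot partitions `data.frame` with columns `cluster_id`, `start`, `end`,
#'   `model` (1-based inclusive coordinates tiling the matrix).
#' @slot mode one of `remgaps`, `gblocks_conservative`, `gblocks_liberal`.
#' @exportClass SuperAlignment
setClass("SuperAlignment",
  representation(taxa = "character",
                 matrix = "character",
                 partitions = "data.frame",
                 mode = "character"))

setValidity("SuperAlignment", function(object) {
  msg <- character()
  if (!identical(names(object@matrix), object@taxa))
    msg <- c(msg, "matrix rows must be named by taxa, in order")
  w <- unique(nchar(object@matrix))
  if (length(w) > 1)
    msg <- c(msg, "all rows must have equal length")
  p <- object@partitions
  if (nrow(p) > 0) {
    if (p$start[1] != 1 || any(p$end < p$start) ||
        (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)] + 1)))
      msg <- c(msg, "partitions must tile [1, L] contiguously")
    if (length(w) == 1 && p$end[nrow(p)] != w)
      msg <- c(msg, "partitions must end at the alignment width")
  }
  if (!object@mode %in% .TRIM_MODES)
    msg <- c(msg, "unknown mode")
  if (length(msg)) msg else TRUE
})

#' SubstitutionModel: empirical amino-acid substitution model
#'
#' A general time-reversible CTMC over the 20 amino acids built from a
#' published exchangeability matrix and stationary frequencies, optionally with
#' observed (+F) frequencies and discrete-gamma (+G, 4 categories) rate
#' variation. The rate matrix is scaled to one expected substitution per unit
#' time; the spectral decomposition is cached for fast transition matrices.
#'
#' @slot name base matrix name (`Dayhoff`, `JTT`, `WAG`, `LG`, `RtREV`).
#' @slot exchangeabilities symmetric non-negative 20x20 matrix.
#' @slot frequencies stationary frequencies (length 20, sums to 1).
#' @slot plusF logical: frequencies taken from the data.
#' @slot alpha numeric(0) for no rate variation, else the gamma shape.
#' @slot freeParams integer count of free parameters (for AIC).
#' @slot eig list: cached symmetric eigen decomposition of the rate matrix.
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
  representation(name = "character",
                 exchangeabilities = "matrix",
                 frequencies = "numeric",
                 plusF = "logical",
                 alpha = "numeric",
                 freeParams = "integer",
                 eig = "list"))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  S <- object@exchangeabilities
  if (!all(dim(S) == c(20L, 20L)) || max(abs(S - t(S))) > 1e-8 || any(S < 0))
    msg <- c(msg, "exchangeabilities must be a symmetric non-negative 20x20 matrix")
  if (abs(sum(object@frequencies) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1")
  if (length(object@alpha) == 1 && object@alpha <= 0)
    msg <- c(msg, "gamma shape must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteomeSet", function(object) {
  cat("ProteomeSet with", length(object@genomes), "genomes,",
      length(object@proteins), "proteins\n")
  for (g in object@genomes)
    cat("  ", g, ": ",
        sum(object@aliasMap$genome_id == g), " proteins\n", sep = "")
  if (nrow(object@qcReport) > 0)
    cat("  QC rejected:", nrow(object@qcReport), "entries\n")
  if (nrow(object@aliasMap) == 0 || !length(object@proteins) ||
      is.null(names(object@proteins)))
    cat("  (aliases not yet assigned)\n")
})

setMethod("show", "SimilarityGraph", function(object) {
  cat("SimilarityGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "directed edges (e-value cutoff ",
      format(object@cutoff), ")\n")
})

setMethod("show", "Clustering", function(object) {
  cat("Clustering at inflation", object@inflation, ":",
      length(object@clusters), "clusters over",
      sum(lengths(object@clusters)), "nodes;",
      object@iterations, "iterations,",
      if (object@converged) "converged" else "not converged", "\n")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@accepted), "accepted clusters,",
      nrow(object@rejectionLog), "rejections\n")
})

setMethod("show", "ClusterAlignment", function(object) {
  cat("ClusterAlignment", object@clusterId, ":", nrow(object@aln),
      "sequences x", ncol(object@aln), "columns\n")
})

setMethod("show", "SuperAlignment", function(object) {
  cat("SuperAlignment (", object@mode, "): ", length(object@taxa),
      " taxa x ", if (length(object@matrix)) nchar(object@matrix[1]) else 0L,
      " columns, ", nrow(object@partitions), " partitions\n", sep = "")
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel", modelLabel(object), "(", object@freeParams,
      "free parameters )\n")
})
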
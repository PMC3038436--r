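#' Select single-copy candidate clusters from one clustering
#'
#' A candidate must contain at most one protein per genome, at least two
#' members, and cover at least `minTaxonFraction` of the genomes. Clusters
#' failing either rule are logged with a reason (`not_single_copy`,
#' `below_taxon_fraction`); singletons are discarded silently as they cannot
#' contribute to an alignment.
#'
#' @param clustering a [Clustering-class].
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @param minTaxonFraction minimum fraction of genomes present per cluster,
#'   in (0, 1].
#' @return list with `accepted` (list of candidate clusters: `members`,
#'   `inflation`, `taxa`, `taxonFraction`) and `rejected` (`data.frame` of
#'   `inflation`, `members`, `reason`).
#' @export
selectSingleCopy <- function(clustering, proteomes, minTaxonFraction) {
  stopifnot(minTaxonFraction > 0, minTaxonFraction <= 1)
  nGenomes <- length(proteomes@genomes)
  acc <- list()
  rejM <- rejR <- character(0)
  for (cl in clustering@clusters) {
    if (length(cl) < 2) next
    gen <- aliasToGenome(proteomes, cl)
    if (anyDuplicated(gen)) {
      rejM <- c(rejM, paste(cl, collapse = ","))
      rejR <- c(rejR, "not_single_copy")
      next
    }
    frac <- length(gen) / nGenomes
    if (frac < minTaxonFraction) {
      rejM <- c(rejM, paste(cl, collapse = ","))
      rejR <- c(rejR, "below_taxon_fraction")
      next
    }
    acc[[length(acc) + 1L]] <- list(members = sort(cl),
                                    inflation = clustering@inflation,
                                    taxa = sort(gen),
                                    taxonFraction = frac)
  }
  list(accepted = acc,
       rejected = data.frame(
         inflation = rep(clustering@inflation, length(rejM)),
         members = rejM, reason = rejR, stringsAsFactors = FALSE))
}

#' Best-hit consistency of a candidate cluster
#'
#' TRUE iff, for every member and every other genome represented in the
#' cluster, the member's best hit into that genome (when one exists) is
#' itself a cluster member. Members with no hit into a genome do not violate
#' the rule. A cluster whose member has its best hit outside the cluster is
#' rejected wholesale.
#'
#' @param cluster candidate cluster list (as from [selectSingleCopy()]).
#' @param graph a [SimilarityGraph-class] with best hits populated.
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @return logical flag.
#' @export
bestHitConsistent <- function(cluster, graph, proteomes) {
  members <- cluster$members
  gen <- aliasToGenome(proteomes, members)
  b <- graph@bestHits
  rel <- b[b$query %in% members & b$genome %in% cluster$taxa, , drop = FALSE]
  if (nrow(rel) == 0) return(TRUE)
  qgen <- gen[match(rel$query, members)]
  rel <- rel[rel$genome != qgen, , drop = FALSE]
  all(rel$subject %in% members)
}

.clusterKey <- function(members) paste(sort(members), collapse = ",")

#' Most-stringent-first non-redundancy filtering across an inflation sweep
#'
#' Clusterings are processed in decreasing order of inflation (most stringent
#' first); within a clustering, candidates are processed by decreasing size,
#' ties by the lexicographically smallest member alias. A candidate is
#' accepted iff it passes [selectSingleCopy()] and [bestHitConsistent()] and
#' shares no protein with an already-accepted cluster, so every protein is
#' represented at most once in the final set.
#'
#' @param clusterings list of [Clustering-class] over a sweep.
#' @param graph a [SimilarityGraph-class].
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @param minTaxonFraction minimum fraction of genomes per cluster.
#' @return a [ClusterSet-class] with the accepted clusters (each tagged with
#'   the inflation it came from) and the full rejection log.
#' @export
filterSweep <- function(clusterings, graph, proteomes, minTaxonFraction) {
  if (length(clusterings) == 0) stop("empty inflation sweep")
  infl <- vapply(clusterings, function(x) x@inflation, 0)
  ord <- order(-infl)
  acceptedList <- list()
  used <- character(0)
  logs <- list()
  for (ci in ord) {
    sel <- selectSingleCopy(clusterings[[ci]], proteomes, minTaxonFraction)
    logs[[length(logs) + 1L]] <- sel$rejected
    cand <- sel$accepted
    if (length(cand) == 0) next
    sizes <- vapply(cand, function(x) length(x$members), 0L)
    firsts <- vapply(cand, function(x) x$members[1], "")
    for (k in order(-sizes, firsts)) {
      cc <- cand[[k]]
      if (any(cc$members %in% used)) {
        logs[[length(logs) + 1L]] <- data.frame(
          inflation = cc$inflation,
          members = paste(cc$members, collapse = ","),
          reason = "overlaps_accepted", stringsAsFactors = FALSE)
        next
      }
      if (!bestHitConsistent(cc, graph, proteomes)) {
        logs[[length(logs) + 1L]] <- data.frame(
          inflation = cc$inflation,
          members = paste(cc$members, collapse = ","),
          reason = "best_hit_violation", stringsAsFactors = FALSE)
        next
      }
      acceptedList[[length(acceptedList) + 1L]] <- cc
      used <- c(used, cc$members)
    }
  }
  log <- do.call(rbind, c(logs, list(data.frame(
    inflation = numeric(0), members = character(0), reason = character(0),
    stringsAsFactors = FALSE))))
  rownames(log) <- NULL
  new("ClusterSet", accepted = acceptedList, rejectionLog = log)
}

#' Stable cluster identifiers for an accepted ClusterSet
#'
#' Clusters are ordered by decreasing inflation then lexicographically by
#' smallest member alias (the acceptance order) and numbered `c0001`,
#' `c0002`, ... so identifiers are deterministic.
#'
#' @param clusterSet a [ClusterSet-class].
#' @return the ClusterSet with an `id` element added to each cluster.
#' @export
assignClusterIds <- function(clusterSet) {
  acc <- clusterSet@accepted
  if (length(acc) == 0) return(clusterSet)
  w <- nchar(as.character(length(acc)))
  w <- max(w, 4L)
  for (i in seq_along(acc))
    acc[[i]]$id <- sprintf("c%0*d", w, i)
  clusterSet@accepted <- acc
  clusterSet
}

#' Write / read the accepted-cluster table and rejection log as TSV
#'
#' The cluster table has one row per member protein with columns
#' `cluster_id`, `inflation`, `genome_id`, `alias`, `original_header`.
#'
#' @param clusterSet a [ClusterSet-class] with ids assigned.
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @param path output file.
#' @export
writeClusterTable <- function(clusterSet, proteomes, path) {
  acc <- clusterSet@accepted
  rows <- lapply(acc, function(cc) {
    data.frame(cluster_id = cc$id, inflation = cc$inflation,
               genome_id = aliasToGenome(proteomes, cc$members),
               alias = cc$members,
               original_header = aliasToHeader(proteomes, cc$members),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(data.frame(
    cluster_id = character(0), inflation = numeric(0),
    genome_id = character(0), alias = character(0),
    original_header = character(0), stringsAsFactors = FALSE))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterTable
#' @export
readClusterTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

#' @rdname writeClusterTable
#' @export
writeRejectionLog <- function(clusterSet, path) {
  write.table(clusterSet@rejectionLog, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
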
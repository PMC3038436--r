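#' Re-key alignment rows from protein aliases to genome (organism) names
#'
#' Mapped alias names are exchanged for the (sanitized) organism names so
#' that per-cluster alignments can be normalized to a common taxon set.
#'
#' @param aln a [ClusterAlignment-class] with alias rownames.
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @return the alignment with genome-id rownames.
#' @export
aliasesToGenomes <- function(aln, proteomes) {
  m <- aln@aln
  rownames(m) <- aliasToGenome(proteomes, rownames(m))
  if (anyDuplicated(rownames(m)))
    stop("cluster ", aln@clusterId, " has two proteins from one genome")
  new("ClusterAlignment", clusterId = aln@clusterId, aln = m)
}

#' Normalize an alignment to a common taxon set
#'
#' The output has exactly the given taxa, in the given order; genomes absent
#' from the cluster are filled with `?` across the full alignment width, and
#' rows that are present are copied byte-identically.
#'
#' @param aln a [ClusterAlignment-class] keyed by genome id (see
#'   [aliasesToGenomes()]).
#' @param taxa ordered character vector of genome ids.
#' @return the normalized [ClusterAlignment-class].
#' @export
normalizeAlignment <- function(aln, taxa) {
  m <- aln@aln
  if (anyDuplicated(rownames(m)))
    stop("duplicate genome in alignment ", aln@clusterId)
  if (!all(rownames(m) %in% taxa))
    stop("alignment ", aln@clusterId, " contains taxa outside the target set")
  out <- matrix("?", length(taxa), ncol(m), dimnames = list(taxa, NULL))
  out[rownames(m), ] <- m
  new("ClusterAlignment", clusterId = aln@clusterId, aln = out)
}

#' Concatenate normalized alignments into a super alignment
#'
#' Alignments are ordered deterministically by cluster id; each taxon's row
#' is the concatenation of its per-cluster rows and the partition map records
#' each cluster's 1-based inclusive coordinate range together with its
#' assigned substitution model.
#'
#' @param alns list of [ClusterAlignment-class], all normalized to `taxa`.
#' @param taxaOrder ordered character vector of genome ids.
#' @param models named character vector mapping cluster id to model name
#'   (optional; unassigned clusters get `NA`).
#' @param mode supermatrix mode label (one of the three trim modes).
#' @return a [SuperAlignment-class].
#' @export
concatenateAlignments <- function(alns, taxaOrder, models = NULL,
                                  mode = "remgaps") {
  if (length(alns) == 0) stop("no alignments to concatenate")
  ids <- vapply(alns, function(a) a@clusterId, "")
  if (anyDuplicated(ids)) stop("duplicate cluster ids")
  alns <- alns[order(ids)]
  ids <- ids[order(ids)]
  for (a in alns)
    if (!identical(rownames(a@aln), taxaOrder))
      stop("alignment ", a@clusterId, " is not normalized to the taxon order")
  widths <- vapply(alns, function(a) ncol(a@aln), 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(taxaOrder, function(g) {
    paste(vapply(alns, function(a) paste(a@aln[g, ], collapse = ""), ""),
          collapse = "")
  }, "")
  part <- data.frame(cluster_id = ids, start = starts, end = ends,
                     model = if (is.null(models)) NA_character_
                             else unname(models[ids]),
                     stringsAsFactors = FALSE)
  new("SuperAlignment", taxa = taxaOrder, matrix = rows,
      partitions = part, mode = mode)
}

#' Assign substitution models to the partitions of a super alignment
#'
#' @param sa a [SuperAlignment-class].
#' @param models named character vector, cluster id -> model name.
#' @return the updated [SuperAlignment-class].
#' @export
setPartitionModels <- function(sa, models) {
  sa@partitions$model <- unname(models[sa@partitions$cluster_id])
  sa
}

#' Write / read a RAxML-style protein partition file
#'
#' One line per partition: `<MODEL>, <cluster_id> = <start>-<end>`.
#' `readPartitionFile()` parses it back losslessly.
#'
#' @param partitions partition `data.frame` (or a [SuperAlignment-class]).
#' @param path output file.
#' @export
writePartitionFile <- function(partitions, path) {
  if (is(partitions, "SuperAlignment")) partitions <- partitions@partitions
  lines <- sprintf("%s, %s = %d-%d",
                   ifelse(is.na(partitions$model), "AUTO", partitions$model),
                   partitions$cluster_id, partitions$start, partitions$end)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePartitionFile
#' @return `readPartitionFile`: `data.frame` with columns `cluster_id`,
#'   `start`, `end`, `model`.
#' @export
readPartitionFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines,
    regexec("^\\s*(\\S+)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
            lines))
  bad <- which(lengths(m) != 5L)
  if (length(bad)) stop("malformed partition line ", bad[1], " in ", path)
  data.frame(cluster_id = vapply(m, `[`, "", 3L),
             start = as.integer(vapply(m, `[`, "", 4L)),
             end = as.integer(vapply(m, `[`, "", 5L)),
             model = vapply(m, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Write / read a super alignment
#'
#' @param sa a [SuperAlignment-class].
#' @param path output file.
#' @param format `"fasta"` or `"relaxed_phylip"`.
#' @export
writeSuperAlignment <- function(sa, path,
                                format = c("fasta", "relaxed_phylip")) {
  writeAlignmentFile(sa@matrix, path, match.arg(format))
}

#' @rdname writeSuperAlignment
#' @param partitionPath optional partition file (as from
#'   [writePartitionFile()]) to restore the partition map.
#' @param mode mode label for the restored object.
#' @export
readSuperAlignment <- function(path, format = c("fasta", "relaxed_phylip"),
                               partitionPath = NULL, mode = "remgaps") {
  m <- readAlignmentFile(path, match.arg(format))
  part <- if (!is.null(partitionPath)) readPartitionFile(partitionPath)
          else data.frame(cluster_id = character(0), start = integer(0),
                          end = integer(0), model = character(0),
                          stringsAsFactors = FALSE)
  new("SuperAlignment", taxa = rownames(m),
      matrix = .alignmentStrings(m), partitions = part, mode = mode)
}

#' TSV summary of a partition map
#'
#' @param sa a [SuperAlignment-class].
#' @param path output file.
#' @export
writePartitionSummary <- function(sa, path) {
  p <- sa@partitions
  p$width <- p$end - p$start + 1L
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
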
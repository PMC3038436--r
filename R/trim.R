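#' Remove every gap-containing column (remgaps)
#'
#' The strictest of the three alignment edits: the output consists of exactly
#' the input columns that contain no gap character, in their original order.
#'
#' @param aln a [ClusterAlignment-class].
#' @return the trimmed [ClusterAlignment-class] (possibly zero columns).
#' @export
remgaps <- function(aln) {
  m <- aln@aln
  keep <- colSums(m == "-") == 0
  new("ClusterAlignment", clusterId = aln@clusterId,
      aln = m[, keep, drop = FALSE])
}

#' Conserved-block trimming of an alignment (Gblocks-style)
#'
#' Columns are classified as nonconserved when they contain any gap or when
#' their most frequent residue occurs in fewer than `floor(n/2) + 1` rows.
#' Maximal nonconserved runs longer than `maxNonconserved` are deleted; the
#' remaining columns are split into blocks at the deletion points; each block
#' is trimmed so it starts and ends on a conserved column; blocks shorter
#' than `minBlockLength` are deleted; the surviving blocks are concatenated
#' in order. The conservative preset uses (4, 10) and the liberal preset
#' (8, 5). This trimmer adapts the Gblocks defaults for the unquantified
#' knobs (majority conservation threshold, no gaps allowed in conserved
#' columns) and does not aim for bit-exact Gblocks parity.
#'
#' @param aln a [ClusterAlignment-class] with at least 2 rows.
#' @param maxNonconserved maximum allowed length of a contiguous
#'   nonconserved run.
#' @param minBlockLength minimum length of a surviving block.
#' @return the trimmed [ClusterAlignment-class] (possibly zero columns).
#' @export
gblocksLike <- function(aln, maxNonconserved = 4L, minBlockLength = 10L) {
  stopifnot(maxNonconserved >= 1, minBlockLength >= 1)
  m <- aln@aln
  n <- nrow(m)
  if (n < 2) stop("block trimming needs at least 2 rows")
  L <- ncol(m)
  if (L == 0) return(aln)
  conserved <- logical(L)
  thr <- floor(n / 2) + 1
  for (j in seq_len(L)) {
    col <- m[, j]
    if (any(col == "-")) next
    conserved[j] <- max(table(col)) >= thr
  }
  # delete maximal nonconserved runs longer than the allowance
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  deleted <- logical(L)
  for (k in seq_along(r$values))
    if (!r$values[k] && r$lengths[k] > maxNonconserved)
      deleted[starts[k]:ends[k]] <- TRUE
  # blocks = maximal runs of surviving columns between deletion points
  keep <- integer(0)
  surv <- !deleted
  br <- rle(surv)
  bends <- cumsum(br$lengths)
  bstarts <- bends - br$lengths + 1L
  for (k in seq_along(br$values)) {
    if (!br$values[k]) next
    idx <- bstarts[k]:bends[k]
    # trim the block to start and end on conserved columns
    consIdx <- which(conserved[idx])
    if (length(consIdx) == 0) next
    idx <- idx[consIdx[1]:consIdx[length(consIdx)]]
    if (length(idx) < minBlockLength) next
    keep <- c(keep, idx)
  }
  new("ClusterAlignment", clusterId = aln@clusterId,
      aln = m[, keep, drop = FALSE])
}

#' Apply one of the three alignment-editing modes
#'
#' @param aln a [ClusterAlignment-class].
#' @param mode `remgaps`, `gblocks_conservative` (4 contiguous nonconserved
#'   positions allowed, minimum block length 10) or `gblocks_liberal`
#'   (8 and 5).
#' @return the trimmed [ClusterAlignment-class].
#' @export
trimAlignment <- function(aln, mode = c("remgaps", "gblocks_conservative",
                                        "gblocks_liberal")) {
  mode <- match.arg(mode)
  switch(mode,
    remgaps = remgaps(aln),
    gblocks_conservative = gblocksLike(aln, 4L, 10L),
    gblocks_liberal = gblocksLike(aln, 8L, 5L))
}

#' Filter alignments by minimum length
#'
#' @param alns list of [ClusterAlignment-class].
#' @param minLen minimum number of columns (>= 1).
#' @return the alignments with at least `minLen` columns, order preserved.
#' @export
minLengthFilter <- function(alns, minLen) {
  stopifnot(minLen >= 1)
  alns[vapply(alns, function(a) ncol(a@aln) >= minLen, TRUE)]
}
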
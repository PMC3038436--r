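#' @importFrom Matrix sparseMatrix forceSymmetric
NULL

#' Parse all-vs-all similarity hits in 12-column BLAST tabular format
#'
#' Expects the `outfmt 6` dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Self-hits are dropped,
#' rows above the e-value cutoff are dropped, and duplicate (query, subject)
#' pairs are collapsed to the row with the minimal e-value (ties: highest
#' bitscore).
#'
#' @param path tab-separated hits file.
#' @param cutoffEvalue e-value cutoff; hits above it are discarded.
#' @param proteomes optional [ProteomeSet-class]; when given, query/subject
#'   identifiers are checked against the alias map.
#' @return `data.frame` with columns `query`, `subject`, `pident`, `length`,
#'   `evalue`, `bitscore`.
#' @export
parseTabularHits <- function(path, cutoffEvalue = 1e-1, proteomes = NULL) {
  if (!file.exists(path)) stop("cannot read hits file: ", path)
  empty <- data.frame(query = character(0), subject = character(0),
                      pident = numeric(0), length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed hit row (expected 12 tab-separated columns) at line ",
         bad[1], " of ", path)
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(query = m[, 1], subject = m[, 2],
                     pident = as.numeric(m[, 3]),
                     length = as.integer(m[, 4]),
                     evalue = as.numeric(m[, 11]),
                     bitscore = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  if (anyNA(hits$evalue) || anyNA(hits$bitscore))
    stop("malformed numeric field in ", path)
  if (!is.null(proteomes)) {
    known <- proteomes@aliasMap$alias
    unk <- setdiff(unique(c(hits$query, hits$subject)), known)
    if (length(unk))
      stop("hit identifiers not present in the alias map: ",
           paste(utils::head(unk, 5), collapse = ", "))
  }
  hits <- hits[hits$query != hits$subject & hits$evalue <= cutoffEvalue, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  # collapse duplicate ordered pairs to the best row
  o <- order(hits$query, hits$subject, hits$evalue, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(paste(hits$query, hits$subject, sep = "\r"))
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build the protein similarity graph and per-genome best-hit index
#'
#' Nodes are all QC-surviving proteins (isolated nodes permitted). For every
#' query and every target genome, the best hit is the subject with the lowest
#' e-value, ties broken by highest bitscore then lexicographically smallest
#' subject alias — an order-independent rule.
#'
#' @param hits `data.frame` from [parseTabularHits()].
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @param cutoffEvalue cutoff recorded on the graph (edges are assumed
#'   pre-filtered).
#' @return a [SimilarityGraph-class].
#' @export
buildGraph <- function(hits, proteomes, cutoffEvalue = 1e-1) {
  stopifnot(hasAliases(proteomes))
  nodes <- proteomes@aliasMap$alias
  sgen <- aliasToGenome(proteomes, hits$subject)
  if (nrow(hits) > 0) {
    o <- order(hits$query, sgen, hits$evalue, -hits$bitscore, hits$subject)
    h <- hits[o, , drop = FALSE]
    sg <- sgen[o]
    keep <- !duplicated(paste(h$query, sg, sep = "\r"))
    best <- data.frame(query = h$query[keep], genome = sg[keep],
                       subject = h$subject[keep], evalue = h$evalue[keep],
                       bitscore = h$bitscore[keep], stringsAsFactors = FALSE)
  } else {
    best <- data.frame(query = character(0), genome = character(0),
                       subject = character(0), evalue = numeric(0),
                       bitscore = numeric(0), stringsAsFactors = FALSE)
  }
  new("SimilarityGraph", nodes = nodes, edges = hits, bestHits = best,
      cutoff = cutoffEvalue)
}

#' Look up the best hit of a query in a target genome
#'
#' @param graph a [SimilarityGraph-class].
#' @param query query alias.
#' @param genome target genome id.
#' @return the subject alias, or `NA` if the query has no hit in that genome.
#' @export
bestHit <- function(graph, query, genome) {
  b <- graph@bestHits
  i <- which(b$query == query & b$genome == genome)
  if (length(i) == 0) NA_character_ else b$subject[i]
}

#' Symmetric edge weights from e-values
#'
#' Each directed e-value is transformed as `min(-log10(evalue), cap)` (an
#' e-value of exactly 0 maps to the cap) and the two directions of a pair are
#' symmetrized by taking the maximum. Zero-weight transforms (e-values of 1)
#' are lifted to a small positive floor so every surviving edge has positive
#' weight.
#'
#' @param graph a [SimilarityGraph-class].
#' @param cap upper bound on `-log10(evalue)`.
#' @return a symmetric sparse [Matrix::Matrix] with dimnames = nodes.
#' @export
edgeWeights <- function(graph, cap = 200) {
  nodes <- graph@nodes
  n <- length(nodes)
  e <- graph@edges
  if (nrow(e) == 0)
    return(forceSymmetric(sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0), dims = c(n, n),
                                       dimnames = list(nodes, nodes))))
  w <- pmin(-log10(e$evalue), cap)
  w[e$evalue == 0] <- cap
  w <- pmax(w, 1e-6)
  qi <- match(e$query, nodes)
  si <- match(e$subject, nodes)
  # symmetrize by maximum over both directions
  i <- c(qi, si)
  j <- c(si, qi)
  x <- c(w, w)
  key <- paste(pmin(i, j), pmax(i, j), sep = "_")
  agg <- tapply(x, key, max)
  ij <- do.call(rbind, strsplit(names(agg), "_", fixed = TRUE))
  ii <- as.integer(ij[, 1]); jj <- as.integer(ij[, 2])
  M <- sparseMatrix(i = c(ii, jj[jj != ii]), j = c(jj, ii[jj != ii]),
                    x = c(as.numeric(agg), as.numeric(agg)[jj != ii]),
                    dims = c(n, n), dimnames = list(nodes, nodes))
  forceSymmetric(M)
}

#' Construct the command line for an external all-vs-all protein search
#'
#' Adapter only: builds the argument vector for a BLAST+ `blastp` run with
#' the pipeline's search conventions — e-value cutoff 1e-1, soft filtering of
#' low-complexity regions (SEG during seeding only), and the reported subject
#' count limited to the number of organisms analysed. The command is returned,
#' never executed, so it can be inspected or dispatched by the caller.
#'
#' @param queryFasta,subjectDb input FASTA and database path.
#' @param outPath destination for the 12-column tabular report.
#' @param nOrganisms number of genomes in the analysis (caps reported hits).
#' @param evalue e-value cutoff.
#' @return character vector: program followed by arguments.
#' @export
blastCommand <- function(queryFasta, subjectDb, outPath, nOrganisms,
                         evalue = 1e-1) {
  c("blastp",
    "-query", queryFasta,
    "-db", subjectDb,
    "-out", outPath,
    "-outfmt", "6",
    "-evalue", format(evalue),
    "-seg", "yes",
    "-soft_masking", "true",
    "-max_target_seqs", as.character(nOrganisms))
}
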
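#' Maximum-likelihood distance between two aligned sequences
#'
#' Finds the branch length t maximizing the sum over shared columns of
#' `log(pi_a * P_ab(t))` by golden-section search on [1e-6, 10]. Columns where
#' either sequence has a gap, `?`, `X` or any non-standard residue are
#' excluded pairwise. Site-pair counts are canonicalized to unordered pairs,
#' so the distance is exactly symmetric by reversibility.
#'
#' @param x,y residue strings or character vectors of equal length.
#' @param model a [SubstitutionModel-class] (rate variation is ignored here:
#'   distances assume no variation among sites).
#' @return the ML distance (substitutions per site).
#' @export
mlDistance <- function(x, y, model) {
  if (length(x) == 1) x <- strsplit(x, "")[[1]]
  if (length(y) == 1) y <- strsplit(y, "")[[1]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  a <- match(x, .AA_STANDARD)
  b <- match(y, .AA_STANDARD)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("no comparable columns between the two sequences")
  lo <- pmin(a[ok], b[ok])
  hi <- pmax(a[ok], b[ok])
  key <- (lo - 1L) * 20L + hi
  tab <- table(key)
  ki <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  ai <- (ki - 1L) %/% 20L + 1L
  bi <- (ki - 1L) %% 20L + 1L
  freq <- model@frequencies
  f <- function(t) {
    P <- transitionMatrix(model, t)
    sum(cnt * log(freq[ai] * P[cbind(ai, bi)]))
  }
  .goldenMax(f, 1e-6, 10, tol = 1e-6, maxIter = 200L)$max
}

#' Pairwise ML distance matrix of an alignment
#'
#' Pairwise deletion of incomparable columns; a pair with no comparable
#' columns at all aborts with an error naming the offending pair (possible
#' under heavy missing data).
#'
#' @param aln alignment (any representation accepted by [logLikelihood()]).
#' @param model a [SubstitutionModel-class]; default JTT.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
mlDistanceMatrix <- function(aln, model = substitutionModel("JTT")) {
  m <- .asModelMatrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(mlDistance(m[i, ], m[j, ], model),
                  error = function(e)
                    stop("no comparable columns between '", rownames(m)[i],
                         "' and '", rownames(m)[j], "'", call. = FALSE))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor joining
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Ties in Q
#' are broken by the smallest (i, j) index pair in the current node order
#' (original taxa first, merged nodes appended), so the result is
#' deterministic. Negative branch lengths are clamped to zero and the total
#' clamped amount is reported as attribute `clamped`. On additive matrices
#' the generating topology and branch lengths are recovered.
#'
#' @param dm symmetric distance matrix with dimnames (or `dist`).
#' @return an unrooted [ape::phylo] with branch lengths.
#' @export
neighborJoining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must have taxon names")
  labels <- rownames(dm)
  D <- unname(dm)
  # active nodes represented by their newick fragments
  frag <- as.list(labels)
  clamped <- 0
  fmt <- function(x) sprintf("%.10g", x)
  while (length(frag) > 3) {
    nAct <- length(frag)
    r <- rowSums(D)
    Q <- (nAct - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nAct - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped - li; li <- 0 }
    if (lj < 0) { clamped <- clamped - lj; lj <- 0 }
    newFrag <- paste0("(", frag[[i]], ":", fmt(li), ",",
                      frag[[j]], ":", fmt(lj), ")")
    others <- setdiff(seq_len(nAct), c(i, j))
    newD <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newD), c(newD, 0))
    frag <- c(frag[others], newFrag)
  }
  # terminal 3-star: closed-form branch lengths
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c("lx", "ly", "lz")) {
    val <- get(v)
    if (val < 0) { clamped <- clamped - val; assign(v, 0) }
  }
  nwk <- paste0("(", frag[[1]], ":", fmt(lx), ",", frag[[2]], ":", fmt(ly),
                ",", frag[[3]], ":", fmt(lz), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Base tree for model evaluation
#'
#' Neighbor-joining tree from JTT ML distances; a two-row alignment yields
#' the trivial two-leaf tree with the ML distance split evenly.
#'
#' @param aln alignment.
#' @param model distance model, default JTT.
#' @return an [ape::phylo].
#' @export
baseTreeNJ <- function(aln, model = substitutionModel("JTT")) {
  m <- .asModelMatrix(aln)
  if (nrow(m) == 2) {
    d <- mlDistance(m[1, ], m[2, ], model)
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         rownames(m)[1], d / 2,
                                         rownames(m)[2], d / 2)))
  }
  neighborJoining(mlDistanceMatrix(m, model))
}

# bipartitions of an unrooted tree as canonical leaf sets: for each internal
# edge, the tip set below it, complemented if it contains the reference leaf
.treeSplits <- function(tree, ref) {
  tr <- reorder(tree, "postorder")
  nTip <- length(tr$tip.label)
  allTips <- sort(tr$tip.label)
  desc <- vector("list", nTip + tr$Nnode)
  for (i in seq_len(nTip)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= nTip) next
    s <- sort(desc[[ch]])
    if (ref %in% s) s <- setdiff(allTips, s)
    if (length(s) < 2 || length(s) > nTip - 2) next
    out[[length(out) + 1L]] <- s
  }
  out
}

# assemble a consensus tree from compatible splits (canonical sides not
# containing `ref`); returns a newick string with integer supports
.consensusNewick <- function(taxaAll, splits, support, ref, rootOnRef) {
  rest <- setdiff(sort(taxaAll), ref)
  if (length(splits)) {
    o <- order(-lengths(splits))
    splits <- splits[o]
    support <- support[o]
  }
  nSplit <- length(splits)
  parent <- integer(nSplit)   # 0 = top
  for (k in seq_len(nSplit)) {
    parent[k] <- 0L
    if (k > 1) for (p in (k - 1):1)
      if (all(splits[[k]] %in% splits[[p]])) { parent[k] <- p; break }
  }
  leafParent <- vapply(rest, function(tip) {
    cand <- which(vapply(splits, function(s) tip %in% s, TRUE))
    if (length(cand) == 0) 0L else cand[which.min(lengths(splits)[cand])]
  }, 0L)
  emit <- function(k) {
    childSplits <- which(parent == k)
    childLeaves <- names(leafParent)[leafParent == k]
    parts <- c(lapply(childSplits, function(cs)
                 list(key = min(splits[[cs]]), txt = emit(cs))),
               lapply(childLeaves, function(tip)
                 list(key = tip, txt = tip)))
    parts <- parts[order(vapply(parts, `[[`, "", "key"))]
    inner <- paste(vapply(parts, `[[`, "", "txt"), collapse = ",")
    if (k == 0L) inner
    else paste0("(", inner, ")", support[k])
  }
  top <- emit(0L)
  if (rootOnRef)
    paste0("(", ref, ",(", top, "));")
  else
    paste0("(", ref, ",", top, ");")
}

#' Bootstrap + majority-rule consensus NJ tree
#'
#' Resamples alignment columns with replacement per replicate (reproducibly
#' seeded), builds a neighbor-joining tree from model-based ML distances per
#' replicate, and returns the majority-rule consensus: exactly the
#' bipartitions present in strictly more than 50% of the replicate trees,
#' each annotated with its percentage (integer) as a node label. With an
#' outgroup, the consensus is rooted on the outgroup's pendant edge; supports
#' are unaffected by the rooting.
#'
#' @param aln a [SuperAlignment-class] or alignment matrix.
#' @param model distance model, default JTT (no rate variation).
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed for the column resampling.
#' @param outgroup optional genome id to root on.
#' @return an [ape::phylo] without branch lengths; node labels are bootstrap
#'   percentages; attribute `replicateTrees` holds the per-replicate trees.
#' @export
bootstrapConsensus <- function(aln, model = substitutionModel("JTT"),
                               replicates = 100L, seed = 1L,
                               outgroup = NULL) {
  stopifnot(replicates >= 1)
  m <- .asModelMatrix(aln)
  taxaAll <- rownames(m)
  if (!is.null(outgroup) && !outgroup %in% taxaAll)
    stop("outgroup '", outgroup, "' is not among the taxa")
  set.seed(seed)
  L <- ncol(m)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    trees[[r]] <- neighborJoining(mlDistanceMatrix(m[, cols, drop = FALSE],
                                                   model))
  }
  consensusTree(trees, outgroup = outgroup, taxaAll = taxaAll,
                replicateTrees = trees)
}

#' Majority-rule consensus of a set of trees
#'
#' Contains exactly the bipartitions present in strictly more than half of
#' the input trees, annotated with integer percentages.
#'
#' @param trees list of [ape::phylo] on the same taxa.
#' @param outgroup optional taxon to root on.
#' @param taxaAll taxon set (defaults to the first tree's tips).
#' @param replicateTrees optional list stored on the result.
#' @return an [ape::phylo]; node labels are percentages.
#' @export
consensusTree <- function(trees, outgroup = NULL, taxaAll = NULL,
                          replicateTrees = NULL) {
  if (is.null(taxaAll)) taxaAll <- sort(trees[[1]]$tip.label)
  ref <- if (!is.null(outgroup)) outgroup else sort(taxaAll)[1]
  counts <- new.env(parent = emptyenv())
  sets <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (s in .treeSplits(tr, ref)) {
      key <- paste(s, collapse = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      sets[[key]] <- s
    }
  }
  keys <- ls(counts)
  n <- length(trees)
  fr <- vapply(keys, function(k) counts[[k]] / n, 0)
  keep <- fr > 0.5
  splits <- lapply(keys[keep], function(k) sets[[k]])
  support <- as.integer(round(100 * fr[keep]))
  nwk <- .consensusNewick(taxaAll, splits, support, ref,
                          rootOnRef = !is.null(outgroup))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "rooted") <- !is.null(outgroup)
  if (!is.null(replicateTrees)) attr(tree, "replicateTrees") <- replicateTrees
  tree
}

#' Newick round-trip helpers
#'
#' Branch lengths are written with 6 decimal places; node labels (bootstrap
#' supports) are preserved.
#'
#' @param tree an [ape::phylo].
#' @param path output file.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  ape::read.tree(path)
}

#' Command lines for external phylogenetic programs
#'
#' Adapter stubs for users with RAxML or PhyML installed: constructs the
#' invocation for a partitioned protein analysis of a supermatrix. Never
#' executed by this package.
#'
#' @param program `raxml` or `phyml`.
#' @param alignmentPath PHYLIP supermatrix path.
#' @param partitionPath RAxML-style partition file (raxml only).
#' @param model model name for the whole matrix (phyml only).
#' @param outgroup optional outgroup id.
#' @param bootstrap bootstrap replicates.
#' @return character vector: program followed by arguments.
#' @export
phyloCommand <- function(program = c("raxml", "phyml"), alignmentPath,
                         partitionPath = NULL, model = "JTT",
                         outgroup = NULL, bootstrap = 100L) {
  program <- match.arg(program)
  if (program == "raxml") {
    cmd <- c("raxmlHPC", "-s", alignmentPath, "-n", "run1",
             "-m", "PROTGAMMAWAG", "-p", "12345",
             "-x", "12345", "-#", as.character(bootstrap))
    if (!is.null(partitionPath)) cmd <- c(cmd, "-q", partitionPath)
    if (!is.null(outgroup)) cmd <- c(cmd, "-o", outgroup)
    cmd
  } else {
    cmd <- c("phyml", "--input", alignmentPath, "-d", "aa",
             "--model", model, "-b", as.character(bootstrap))
    cmd
  }
}
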
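#' @importFrom Matrix Diagonal colSums drop0
NULL

#' Initialize the column-stochastic matrix for Markov clustering
#'
#' Standard MCL initialization: each node receives a self-loop weighted by its
#' maximum incident edge weight (1.0 for isolated nodes), then columns are
#' normalized to sum to one.
#'
#' @param weights symmetric positive sparse weight matrix (as from
#'   [edgeWeights()]).
#' @param nodes node order; defaults to the matrix dimnames.
#' @return a sparse column-stochastic matrix with dimnames = nodes.
#' @export
mclInitMatrix <- function(weights, nodes = rownames(weights)) {
  M <- methods::as(methods::as(weights, "generalMatrix"), "CsparseMatrix")
  n <- nrow(M)
  loop <- numeric(n)
  for (j in seq_len(n)) {
    col <- M[, j]
    loop[j] <- if (any(col > 0)) max(col) else 1.0
  }
  M <- M + Diagonal(n, loop)
  cs <- colSums(M)
  M <- M %*% Diagonal(n, 1 / cs)
  dimnames(M) <- list(nodes, nodes)
  M
}

.colNormalize <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  M %*% Diagonal(ncol(M), 1 / cs)
}

#' Markov clustering of a column-stochastic matrix
#'
#' Iterates expansion (matrix self-multiplication) and inflation (entrywise
#' power followed by column renormalization), pruning entries below
#' `pruneThreshold` and renormalizing, until the largest absolute entry change
#' falls below `tol` or `maxIter` is reached. Clusters are read off the limit
#' matrix: attractors (nodes retaining mass on their own diagonal) are grouped
#' into attractor systems via the nonzero structure among them, and every node
#' is assigned to the system of its strongest attractor (largest limit-matrix
#' entry; ties go to the lexicographically smallest attractor). Cluster member
#' lists and cluster order are sorted, so the result is independent of edge
#' insertion order.
#'
#' @param M column-stochastic sparse matrix from [mclInitMatrix()].
#' @param inflation inflation parameter, must exceed 1.
#' @param pruneThreshold entries below this are dropped each iteration.
#' @param tol convergence tolerance on the max absolute entry change.
#' @param maxIter iteration cap.
#' @return a [Clustering-class].
#' @export
mclCluster <- function(M, inflation, pruneThreshold = 1e-8, tol = 1e-6,
                       maxIter = 200L) {
  if (inflation <= 1)
    stop("inflation parameter must be > 1")
  nodes <- rownames(M)
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    Mexp <- M %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^inflation
    Minf <- .colNormalize(Minf)
    Minf@x[Minf@x < pruneThreshold] <- 0
    Minf <- drop0(Minf)
    Minf <- .colNormalize(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) { converged <- TRUE; break }
  }
  cl <- .mclInterpret(M, nodes)
  new("Clustering", inflation = inflation, clusters = cl,
      iterations = it, converged = converged)
}

# Read clusters off the (near-)limit matrix. M is column-stochastic: M[i, j]
# is the mass node j sends to node i.
.mclInterpret <- function(M, nodes) {
  n <- length(nodes)
  d <- Matrix::diag(M)
  attractors <- which(d > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: connected components of the nonzero structure among
  # attractors (either direction)
  sub <- M[attractors, attractors, drop = FALSE]
  adj <- (sub + Matrix::t(sub)) > 0
  comp <- .components(adj)
  # assign every node to the system of its strongest attractor
  assign <- integer(n)
  for (j in seq_len(n)) {
    mass <- M[attractors, j]
    if (all(mass == 0)) {
      # no attractor support (degenerate); node is its own singleton
      assign[j] <- 0L
      next
    }
    best <- which(mass == max(mass))
    if (length(best) > 1)
      best <- best[order(nodes[attractors[best]])[1]]
    assign[j] <- comp[best]
  }
  out <- list()
  for (k in sort(unique(assign[assign > 0L])))
    out[[length(out) + 1L]] <- sort(nodes[assign == k])
  for (j in which(assign == 0L))
    out[[length(out) + 1L]] <- nodes[j]
  out[order(vapply(out, `[`, "", 1L))]
}

# connected components of a logical adjacency matrix (dense or sparse)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] | adj[, v])
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Run Markov clustering across a sweep of inflation parameters
#'
#' The default sweep spans lenient (1.1, few large clusters) to stringent
#' (5.0, many small clusters) settings, accommodating both slow- and
#' fast-evolving gene families.
#'
#' @param weights symmetric weight matrix from [edgeWeights()].
#' @param nodes node order.
#' @param inflations inflation parameters, each > 1.
#' @param ... passed to [mclCluster()].
#' @return list of [Clustering-class], one per inflation, in the given order.
#' @export
inflationSweep <- function(weights, nodes = rownames(weights),
                           inflations = c(1.1, 1.2, 1.3, 1.4, 1.5, 1.7, 2.0,
                                          2.5, 3.0, 3.5, 4.0, 4.5, 5.0),
                           ...) {
  if (length(inflations) == 0) stop("inflation sweep must be non-empty")
  if (any(inflations <= 1)) stop("inflation parameters must be > 1")
  M0 <- mclInitMatrix(weights, nodes)
  lapply(inflations, function(I) mclCluster(M0, I, ...))
}

#' Write / read clusters in MCL's native dump style
#'
#' One cluster per line, members tab-separated.
#'
#' @param clustering a [Clustering-class] (or plain list of clusters).
#' @param path output file.
#' @export
writeMclClusters <- function(clustering, path) {
  cl <- if (is(clustering, "Clustering")) clustering@clusters else clustering
  writeLines(vapply(cl, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' @rdname writeMclClusters
#' @return `readMclClusters`: list of character vectors.
#' @export
readMclClusters <- function(path) {
  lines <- readLines(path)
  strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
}
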
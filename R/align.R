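#' @importFrom stats as.dist reorder
NULL

# BLOSUM62 lookup with extended residues mapped to their closest standard
# residue for scoring purposes only (U->C, J->L, O->K).
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      B <- env$BLOSUM62
      B <- B[.AA_STANDARD, .AA_STANDARD]
      cache <<- B
    }
    cache
  }
})

.scoringIndex <- function(ch) {
  ch[ch == "U"] <- "C"; ch[ch == "J"] <- "L"; ch[ch == "O"] <- "K"
  i <- match(ch, .AA_STANDARD)
  i  # NA for gaps/ambiguity: contributes zero to profile frequencies
}

# residue frequency profile of an alignment block: 20 x ncol, gap/ambiguous
# positions contribute no mass (they score 0 against everything)
.profileFreq <- function(m) {
  L <- ncol(m)
  F <- matrix(0, 20L, L)
  idx <- .scoringIndex(m)
  dim(idx) <- dim(m)
  for (j in seq_len(L)) {
    v <- idx[, j]
    v <- v[!is.na(v)]
    if (length(v))
      F[, j] <- tabulate(v, 20L) / nrow(m)
  }
  F
}

# Affine-gap global alignment over a precomputed column-pair score matrix.
# Three-state model (match M, gap-in-B X consuming rows of A, gap-in-A Y);
# no direct X<->Y transitions. Returns the aligned column index paths
# (0 = gap). Deterministic tie-break: M over X over Y.
.affinePath <- function(S, gapOpen, gapExt) {
  La <- nrow(S); Lb <- ncol(S)
  NEG <- -1e30
  M <- matrix(NEG, La + 1L, Lb + 1L)
  X <- matrix(NEG, La + 1L, Lb + 1L)
  Y <- matrix(NEG, La + 1L, Lb + 1L)
  M[1, 1] <- 0
  if (La > 0) X[2:(La + 1L), 1] <- -gapOpen - gapExt * (0:(La - 1L))
  if (Lb > 0) Y[1, 2:(Lb + 1L)] <- -gapOpen - gapExt * (0:(Lb - 1L))
  for (i in seq_len(La)) {
    prevM <- M[i, ]; prevX <- X[i, ]; prevY <- Y[i, ]
    diagBest <- pmax(prevM, prevX, prevY)
    Mrow <- c(NEG, S[i, ] + diagBest[seq_len(Lb)])
    Xrow <- pmax(prevM - gapOpen, prevX - gapExt)
    Xrow[1] <- X[i + 1L, 1]
    # Y along the row via running max of M[i+1, k] + gapExt * k
    Yrow <- rep(NEG, Lb + 1L)
    run <- NEG
    for (j in seq_len(Lb)) {
      run <- max(run, Mrow[j] + gapExt * (j - 1L))
      Yrow[j + 1L] <- run - gapOpen - gapExt * (j - 1L)
    }
    M[i + 1L, ] <- Mrow
    X[i + 1L, ] <- Xrow
    Y[i + 1L, ] <- Yrow
  }
  # traceback
  pathA <- integer(0); pathB <- integer(0)
  i <- La; j <- Lb
  vals <- c(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L])
  state <- which.max(vals)
  while (i > 0 || j > 0) {
    if (state == 1L) {
      pathA <- c(i, pathA); pathB <- c(j, pathB)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      pathA <- c(i, pathA); pathB <- c(0L, pathB)
      fromM <- M[i, j + 1L] - gapOpen
      fromX <- X[i, j + 1L] - gapExt
      state <- if (fromM >= fromX) 1L else 2L
      i <- i - 1L
    } else {
      pathA <- c(0L, pathA); pathB <- c(j, pathB)
      fromM <- M[i + 1L, j] - gapOpen
      fromY <- Y[i + 1L, j] - gapExt
      state <- if (fromM >= fromY) 1L else 3L
      j <- j - 1L
    }
    if (i == 0 && state == 1L && j > 0) state <- 3L
    if (j == 0 && state == 1L && i > 0) state <- 2L
  }
  list(a = pathA, b = pathB)
}

.mergeProfiles <- function(A, B, gapOpen, gapExt) {
  FA <- .profileFreq(A)
  FB <- .profileFreq(B)
  S <- t(FA) %*% .blosum62() %*% FB
  p <- .affinePath(S, gapOpen, gapExt)
  L <- length(p$a)
  out <- matrix("-", nrow(A) + nrow(B), L)
  rownames(out) <- c(rownames(A), rownames(B))
  out[seq_len(nrow(A)), p$a > 0] <- A[, p$a[p$a > 0], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), p$b > 0] <- B[, p$b[p$b > 0], drop = FALSE]
  out
}

# 6-mer cosine distances used for the guide tree (k shrinks for very short
# sequences). 1 - cosine similarity of k-mer count vectors.
.kmerDistance <- function(seqs, k = 6L) {
  k <- max(1L, min(k, min(nchar(seqs))))
  counts <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    table(kmers)
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- counts[[i]]; b <- counts[[j]]
    shared <- intersect(names(a), names(b))
    num <- sum(as.numeric(a[shared]) * as.numeric(b[shared]))
    den <- sqrt(sum(as.numeric(a)^2)) * sqrt(sum(as.numeric(b)^2))
    D[i, j] <- D[j, i] <- 1 - num / den
  }
  D
}

#' Align the sequences of one cluster
#'
#' The builtin aligner is a progressive aligner: a neighbor-joining guide
#' tree is computed from 6-mer cosine distances, then profiles are merged up
#' the tree with BLOSUM62 sum-of-pairs column scores under affine gap
#' penalties (open 10, extend 0.5). Rows of the result are returned in input
#' order and ungapping any row reproduces its input sequence exactly. The
#' builtin aligner makes no claim of parity with external programs; use
#' [alignerCommand()] to drive MUSCLE/MAFFT/CLUSTALW/PROBCONS instead.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet] of at
#'   least 2 unaligned sequences.
#' @param clusterId identifier stored on the result.
#' @param aligner currently only `"builtin"` is executed in-process.
#' @param gapOpen,gapExt affine gap penalties.
#' @return a [ClusterAlignment-class].
#' @export
alignCluster <- function(sequences, clusterId = "cluster",
                         aligner = "builtin", gapOpen = 10, gapExt = 0.5) {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  if (length(sequences) < 2) stop("need at least 2 sequences to align")
  if (aligner != "builtin")
    stop("aligner '", aligner, "' is an external adapter; build its command ",
         "with alignerCommand() and import the result")
  inputOrder <- names(sequences)
  profiles <- lapply(seq_along(sequences), function(i) {
    m <- matrix(strsplit(sequences[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(sequences)[i]
    m
  })
  names(profiles) <- names(sequences)
  if (length(sequences) == 2) {
    merged <- .mergeProfiles(profiles[[1]], profiles[[2]], gapOpen, gapExt)
  } else {
    D <- .kmerDistance(sequences)
    guide <- neighborJoining(D)
    merged <- .progressiveMerge(guide, profiles, gapOpen, gapExt)
  }
  merged <- merged[inputOrder, , drop = FALSE]
  new("ClusterAlignment", clusterId = clusterId, aln = merged)
}

# merge profiles following the (arbitrarily rooted) guide tree in postorder
.progressiveMerge <- function(guide, profiles, gapOpen, gapExt) {
  tr <- reorder(guide, "postorder")
  nTip <- length(tr$tip.label)
  store <- vector("list", nTip + tr$Nnode)
  for (i in seq_len(nTip)) store[[i]] <- profiles[[tr$tip.label[i]]]
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    if (is.null(store[[parent]])) {
      store[[parent]] <- store[[child]]
    } else {
      store[[parent]] <- .mergeProfiles(store[[parent]], store[[child]],
                                        gapOpen, gapExt)
    }
  }
  store[[nTip + 1L]]
}

#' Command lines for external alignment programs
#'
#' Adapter contract only: returns the argument vector to run the named
#' aligner on a FASTA input with each program's default settings (MUSCLE
#' additionally keeps the input sequence order via `-stable`). The command is
#' not executed; callers run it themselves and read the FASTA result back
#' with [readAlignmentFile()].
#'
#' @param aligner one of `muscle`, `mafft`, `clustalw`, `probcons`.
#' @param inputFasta unaligned FASTA path.
#' @param outputPath destination for the aligned FASTA (for programs that
#'   write to stdout the caller redirects).
#' @return character vector: program followed by arguments.
#' @export
alignerCommand <- function(aligner = c("muscle", "mafft", "clustalw",
                                       "probcons"),
                           inputFasta, outputPath) {
  aligner <- match.arg(aligner)
  switch(aligner,
    muscle = c("muscle", "-in", inputFasta, "-out", outputPath, "-stable"),
    mafft = c("mafft", "--anysymbol", inputFasta),
    clustalw = c("clustalw", paste0("-INFILE=", inputFasta),
                 "-OUTPUT=FASTA", paste0("-OUTFILE=", outputPath)),
    probcons = c("probcons", inputFasta))
}

#' Check that an external aligner is available
#'
#' @param aligner adapter id.
#' @return invisibly TRUE, or a configuration error naming the adapter.
#' @export
checkAligner <- function(aligner) {
  if (aligner == "builtin") return(invisible(TRUE))
  prog <- alignerCommand(aligner, "x", "y")[1]
  if (Sys.which(prog) == "")
    stop("aligner adapter '", aligner, "' requires the executable '", prog,
         "' which was not found on PATH")
  invisible(TRUE)
}
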
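#' @importFrom phangorn discrete.gamma
#' @importFrom stats optimize
NULL

.MODEL_NAMES <- c("Dayhoff", "JTT", "LG", "RtREV", "WAG")

.modelDataCache <- new.env(parent = emptyenv())

# parse a PAML-style lower-triangle exchangeability file shipped with the
# package (19 rows of 1..19 values, blank line, 20 stationary frequencies)
.loadModelData <- function(name) {
  key <- tolower(name)
  if (!is.null(.modelDataCache[[key]])) return(.modelDataCache[[key]])
  path <- system.file("extdata", "models", paste0(key, ".dat"),
                      package = "orthopipe", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("unknown substitution model: ", name)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(lines, function(l)
    scan(text = l, what = numeric(), quiet = TRUE))
  if (length(vals) != 20L)
    stop("malformed model file: ", path)
  S <- matrix(0, 20, 20, dimnames = list(.AA_STANDARD, .AA_STANDARD))
  for (i in 2:20) S[i, seq_len(i - 1L)] <- vals[[i - 1L]]
  S <- S + t(S)
  freq <- vals[[20]]
  freq <- freq / sum(freq)
  out <- list(S = S, freq = freq)
  .modelDataCache[[key]] <- out
  out
}

# spectral decomposition of the reversible rate matrix, scaled to one
# expected substitution per unit time
.modelEigen <- function(S, freq) {
  Q <- S * rep(freq, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  sq <- sqrt(freq)
  A <- Q * (sq / rep(sq, each = 20))   # A_ij = sqrt(pi_i)/sqrt(pi_j) * Q_ij
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / sq,          # D^{-1/2} V
       left = t(e$vectors * sq),        # V' D^{1/2}
       Q = Q)
}

#' Construct an empirical amino-acid substitution model
#'
#' Builds a reversible CTMC from one of the shipped published exchangeability
#' sets, optionally replacing the published stationary frequencies with
#' observed ones (+F) and adding discrete-gamma rate variation over 4
#' equal-probability categories (+G). Free-parameter counts used for AIC:
#' base empirical model 0, +G adds 1, +F adds 19.
#'
#' @param name one of `Dayhoff`, `JTT`, `LG`, `RtREV`, `WAG`.
#' @param frequencies optional length-20 stationary frequency vector
#'   (amino-acid order ARNDCQEGHILKMFPSTWYV); supplying one sets +F.
#' @param alpha optional gamma shape (> 0); supplying one sets +G.
#' @return a [SubstitutionModel-class].
#' @export
substitutionModel <- function(name, frequencies = NULL, alpha = numeric(0)) {
  name <- match.arg(name, .MODEL_NAMES)
  dat <- .loadModelData(name)
  plusF <- !is.null(frequencies)
  freq <- if (plusF) frequencies / sum(frequencies) else dat$freq
  if (length(freq) != 20 || any(freq <= 0))
    stop("frequencies must be 20 positive values")
  k <- 0L + (plusF) * 19L + (length(alpha) == 1) * 1L
  new("SubstitutionModel", name = name, exchangeabilities = dat$S,
      frequencies = freq, plusF = plusF, alpha = as.numeric(alpha),
      freeParams = as.integer(k), eig = .modelEigen(dat$S, freq))
}

#' Label of a model variant (e.g. `WAG+G+F`)
#' @param model a [SubstitutionModel-class].
#' @return character label.
#' @export
modelLabel <- function(model) {
  paste0(model@name,
         if (length(model@alpha)) "+G" else "",
         if (model@plusF) "+F" else "")
}

#' Transition probability matrix of a substitution model
#'
#' `P(t) = exp(Q t r)` computed from the cached spectral decomposition.
#' Rows sum to one; `t = 0` gives the identity.
#'
#' @param model a [SubstitutionModel-class].
#' @param t branch length (expected substitutions per site), >= 0.
#' @param rate optional rate multiplier (gamma category rate).
#' @return a 20x20 stochastic matrix.
#' @export
transitionMatrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  e <- model@eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  P[P < 0] <- 0
  dimnames(P) <- list(.AA_STANDARD, .AA_STANDARD)
  P
}

#' Discrete-gamma category rates
#'
#' Four equal-probability categories with rates equal to the mean of each
#' quantile bin of a Gamma(shape, rate = shape) distribution.
#'
#' @param alpha gamma shape parameter, > 0.
#' @param k number of categories.
#' @return numeric vector of category rates (mean 1).
#' @export
gammaRates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("gamma shape must be positive")
  as.numeric(discrete.gamma(alpha, k))
}

# tip conditional-likelihood encoding: 20-row indicator per residue with
# partial ambiguity for B (N/D), Z (E/Q) and J (I/L); `?`, `-`, `X` and other
# unknowns are fully ambiguous
.tipEncoding <- local({
  enc <- NULL
  function() {
    if (!is.null(enc)) return(enc)
    codes <- c(.AA_STANDARD, "B", "Z", "J", "X", "U", "O", "?", "-", "*")
    E <- matrix(0, 20, length(codes), dimnames = list(.AA_STANDARD, codes))
    for (a in .AA_STANDARD) E[a, a] <- 1
    E[c("N", "D"), "B"] <- 1
    E[c("E", "Q"), "Z"] <- 1
    E[c("I", "L"), "J"] <- 1
    E[, c("X", "U", "O", "?", "-", "*")] <- 1
    enc <<- E
    E
  }
})

.asModelMatrix <- function(aln) {
  if (is(aln, "ClusterAlignment")) return(aln@aln)
  if (is(aln, "SuperAlignment")) return(alignmentMatrix(aln))
  .asAlignmentMatrix(aln)
}

# compress alignment columns into unique site patterns
.sitePatterns <- function(m) {
  pats <- apply(m, 2, paste, collapse = "")
  u <- unique(pats)
  list(index = match(pats, u),
       cols = m[, match(u, pats), drop = FALSE],
       weight = as.numeric(table(factor(pats, levels = u))))
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Sums over columns the log of the pruning-algorithm column likelihood under
#' the model; with +G the column likelihood is averaged over the 4 discrete
#' gamma categories. `?`, `-` and `X` are treated as fully ambiguous states.
#' The result is invariant to the rooting of the tree (pulley principle).
#'
#' @param aln a [ClusterAlignment-class], [SuperAlignment-class], character
#'   matrix or named character vector; rows must cover the tree's tips.
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [SubstitutionModel-class].
#' @return the log-likelihood (numeric scalar).
#' @export
logLikelihood <- function(aln, tree, model) {
  m <- .asModelMatrix(aln)
  if (!all(tree$tip.label %in% rownames(m)))
    stop("alignment is missing tree leaves: ",
         paste(setdiff(tree$tip.label, rownames(m)), collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  sp <- .sitePatterns(m)
  rates <- if (length(model@alpha)) gammaRates(model@alpha, 4L) else 1
  ll <- .pruningLogLik(sp$cols, tree, model, rates)
  sum(ll * sp$weight)
}

# per-pattern log-likelihood, averaged over rate categories in linear space
.pruningLogLik <- function(cols, tree, model, rates) {
  tr <- reorder(tree, "postorder")
  nTip <- length(tr$tip.label)
  nPat <- ncol(cols)
  E <- .tipEncoding()
  ch <- cols
  ch[!ch %in% colnames(E)] <- "?"
  tipL <- lapply(seq_len(nTip), function(i) E[, ch[i, ], drop = FALSE])
  perCat <- matrix(0, length(rates), nPat)
  for (ci in seq_along(rates)) {
    Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
      transitionMatrix(model, tr$edge.length[e], rates[ci]))
    L <- vector("list", nTip + tr$Nnode)
    logscale <- vector("list", nTip + tr$Nnode)
    for (i in seq_len(nTip)) { L[[i]] <- tipL[[i]]; logscale[[i]] <- numeric(nPat) }
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      contrib <- Ps[[e]] %*% L[[child]]
      if (is.null(L[[parent]])) {
        L[[parent]] <- contrib
        logscale[[parent]] <- logscale[[child]]
      } else {
        L[[parent]] <- L[[parent]] * contrib
        logscale[[parent]] <- logscale[[parent]] + logscale[[child]]
        mx <- apply(L[[parent]], 2, max)
        mx[mx == 0] <- 1
        L[[parent]] <- L[[parent]] / rep(mx, each = 20)
        logscale[[parent]] <- logscale[[parent]] + log(mx)
      }
    }
    root <- nTip + 1L
    perCat[ci, ] <- log(colSums(model@frequencies * L[[root]])) +
      logscale[[root]]
  }
  if (length(rates) == 1) return(perCat[1, ])
  # average over equal-probability categories, stably in log space
  mx <- apply(perCat, 2, max)
  mx + log(colMeans(exp(sweep(perCat, 2, mx))))
}

#' Observed amino-acid frequencies of an alignment
#'
#' Counts of the 20 standard residues with a small pseudocount so every
#' frequency is strictly positive (required for a reversible model).
#'
#' @param aln alignment in any representation accepted by [logLikelihood()].
#' @param pseudocount added to each residue count.
#' @return length-20 frequency vector in ARNDCQEGHILKMFPSTWYV order.
#' @export
observedFrequencies <- function(aln, pseudocount = 0.5) {
  m <- .asModelMatrix(aln)
  counts <- table(factor(m, levels = .AA_STANDARD))
  f <- as.numeric(counts) + pseudocount
  f / sum(f)
}

# golden-section maximization on [lo, hi]
.goldenMax <- function(f, lo, hi, tol = 1e-4, maxIter = 100L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  it <- 0L
  while (b - a > tol && it < maxIter) {
    it <- it + 1L
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  if (f1 >= f2) list(max = x1, value = f1) else list(max = x2, value = f2)
}

#' Rank substitution-model variants on one alignment by AIC
#'
#' Evaluates each empirical matrix in `modelNames` with the variants none,
#' +G, +F and +G+F on a fixed base tree (by default a neighbor-joining tree
#' from JTT maximum-likelihood distances). Branch lengths are held constant
#' across models (the fast-optimization approximation); the only freely
#' optimized parameter is the gamma shape, by golden-section search on
#' [0.05, 50]. AIC = 2k - 2 lnL with k counting +G (1) and +F (19) only.
#'
#' @param aln alignment (any representation accepted by [logLikelihood()]).
#' @param baseTree optional [ape::phylo]; computed from the alignment when
#'   missing.
#' @param modelNames empirical matrices to evaluate.
#' @param variants subset of `c("", "+G", "+F", "+G+F")`.
#' @return `data.frame` with columns `model`, `lnL`, `k`, `aic`, `alpha`,
#'   sorted by ascending AIC (ties by model name).
#' @export
rankModels <- function(aln, baseTree = NULL,
                       modelNames = .MODEL_NAMES,
                       variants = c("", "+G", "+F", "+G+F")) {
  m <- .asModelMatrix(aln)
  if (is.null(baseTree))
    baseTree <- baseTreeNJ(m)
  obsFreq <- observedFrequencies(m)
  rows <- list()
  for (name in modelNames) for (v in variants) {
    useF <- grepl("F", v, fixed = TRUE)
    useG <- grepl("G", v, fixed = TRUE)
    freq <- if (useF) obsFreq else NULL
    if (useG) {
      obj <- function(a)
        logLikelihood(m, baseTree, substitutionModel(name, freq, a))
      opt <- .goldenMax(obj, 0.05, 50, tol = 1e-2)
      mod <- substitutionModel(name, freq, opt$max)
      lnL <- opt$value
      alpha <- opt$max
    } else {
      mod <- substitutionModel(name, freq)
      lnL <- logLikelihood(m, baseTree, mod)
      alpha <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = modelLabel(mod), lnL = lnL, k = mod@freeParams,
      aic = 2 * mod@freeParams - 2 * lnL, alpha = alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aic, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize per-alignment model rankings
#'
#' Produces the four standard outputs: (1) the best model per alignment;
#' (2) the full ranked table per alignment; (3) the frequency with which
#' each model ranked first; (4) a cluster -> model assignment for the
#' partition map. The single most frequently top-ranked model (ties broken
#' by lexicographically smallest name, with the tie recorded) is reported
#' for whole-matrix analyses.
#'
#' @param rankings named list of `data.frame`s from [rankModels()], one per
#'   alignment (names are alignment / cluster ids).
#' @return list with `best` (data.frame `alignment`, `model`, `lnL`, `aic`),
#'   `ranked` (row-bound table with an `alignment` column), `frequency`
#'   (data.frame `model`, `n`), `assignment` (named character vector) and
#'   `oneModel` (character scalar, attribute `tie` flags a broken tie).
#' @export
summarizeModels <- function(rankings) {
  stopifnot(length(rankings) >= 1, !is.null(names(rankings)))
  best <- do.call(rbind, lapply(names(rankings), function(id) {
    r <- rankings[[id]]
    data.frame(alignment = id, model = r$model[1], lnL = r$lnL[1],
               aic = r$aic[1], stringsAsFactors = FALSE)
  }))
  ranked <- do.call(rbind, lapply(names(rankings), function(id) {
    r <- rankings[[id]]
    cbind(data.frame(alignment = id, rank = seq_len(nrow(r)),
                     stringsAsFactors = FALSE), r)
  }))
  tab <- table(best$model)
  freq <- data.frame(model = names(tab), n = as.integer(tab),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$n, freq$model), , drop = FALSE]
  rownames(freq) <- NULL
  tie <- sum(freq$n == freq$n[1]) > 1
  oneModel <- freq$model[1]
  attr(oneModel, "tie") <- tie
  assignment <- stats::setNames(best$model, best$alignment)
  list(best = best, ranked = ranked, frequency = freq,
       assignment = assignment, oneModel = oneModel)
}
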
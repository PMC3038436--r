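# Independent brute-force oracles used to cross-check the implementations.
# These deliberately share no code with the package internals beyond the
# published update rules they re-state.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")

# ---- dense Markov clustering oracle (base-R matrices throughout) ----
denseMclOracle <- function(W, inflation, prune = 1e-8, tol = 1e-6,
                           maxIter = 200) {
  nodes <- rownames(W)
  n <- nrow(W)
  M <- W
  for (j in seq_len(n)) {
    col <- M[, j]
    M[j, j] <- if (any(col > 0)) max(col) else 1
  }
  M <- sweep(M, 2, colSums(M), "/")
  it <- 0
  repeat {
    it <- it + 1
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < prune] <- 0
    cs <- colSums(M2); cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    d <- max(abs(M2 - M)); M <- M2
    if (d < tol || it >= maxIter) break
  }
  att <- which(diag(M) > 0)
  if (!length(att)) att <- seq_len(n)
  sub <- M[att, att, drop = FALSE]
  adj <- (sub + t(sub)) > 0
  comp <- integer(length(att)); cur <- 0
  for (s in seq_along(att)) {
    if (comp[s] > 0) next
    cur <- cur + 1; q <- s; comp[s] <- cur
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] | adj[, v]); nb <- nb[comp[nb] == 0]
      comp[nb] <- cur; q <- c(q, nb)
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) {
    mass <- M[att, j]
    if (all(mass == 0)) { assign[j] <- 0; next }
    b <- which(mass == max(mass))
    if (length(b) > 1) b <- b[order(nodes[att[b]])[1]]
    assign[j] <- comp[b]
  }
  out <- list()
  for (k in sort(unique(assign[assign > 0])))
    out[[length(out) + 1]] <- sort(nodes[assign == k])
  for (j in which(assign == 0))
    out[[length(out) + 1]] <- nodes[j]
  out[order(sapply(out, `[`, 1))]
}

randomWeightGraph <- function(n, nEdge = sample(n:(3 * n), 1)) {
  nodes <- sprintf("n%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nEdge)) {
    ij <- sample(n, 2)
    w <- round(runif(1, 0.5, 60), 3)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- w
  }
  W
}

# ---- plain Needleman-Wunsch with affine gaps (cell-by-cell recursion) ----
nwOracleScore <- function(x, y, score, gapOpen = 10, gapExt = 0.5) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  La <- length(a); Lb <- length(b)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, La + 1, Lb + 1)
  M[1, 1] <- 0
  for (i in seq_len(La)) X[i + 1, 1] <- -gapOpen - gapExt * (i - 1)
  for (j in seq_len(Lb)) Y[1, j + 1] <- -gapOpen - gapExt * (j - 1)
  for (i in seq_len(La)) for (j in seq_len(Lb)) {
    M[i + 1, j + 1] <- score[a[i], b[j]] + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen, X[i, j + 1] - gapExt)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen, Y[i + 1, j] - gapExt)
  }
  max(M[La + 1, Lb + 1], X[La + 1, Lb + 1], Y[La + 1, Lb + 1])
}

alignmentScore <- function(m, score, gapOpen = 10, gapExt = 0.5) {
  # score of a 2-row pairwise alignment under the same affine model
  s <- 0
  gapRun <- 0L
  for (j in seq_len(ncol(m))) {
    a <- m[1, j]; b <- m[2, j]
    if (a == "-" || b == "-") {
      gapRun <- gapRun + 1L
      s <- s - if (gapRun == 1L) gapOpen else gapExt
    } else {
      gapRun <- 0L
      s <- s + score[a, b]
    }
  }
  s
}

# ---- independent Gblocks-style trimming oracle (plain scan) ----
trimOracle <- function(m, maxNC, minBlock) {
  n <- nrow(m); L <- ncol(m)
  cons <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    if (any(col == "-")) return(FALSE)
    max(table(col)) >= floor(n / 2) + 1
  }, TRUE)
  # mark nonconserved runs longer than maxNC for deletion
  del <- rep(FALSE, L)
  j <- 1
  while (j <= L) {
    if (!cons[j]) {
      k <- j
      while (k < L && !cons[k + 1]) k <- k + 1
      if (k - j + 1 > maxNC) del[j:k] <- TRUE
      j <- k + 1
    } else j <- j + 1
  }
  keep <- integer(0)
  j <- 1
  while (j <= L) {
    if (!del[j]) {
      k <- j
      while (k < L && !del[k + 1]) k <- k + 1
      idx <- j:k
      ci <- which(cons[idx])
      if (length(ci)) {
        idx <- idx[ci[1]:ci[length(ci)]]
        if (length(idx) >= minBlock) keep <- c(keep, idx)
      }
      j <- k + 1
    } else j <- j + 1
  }
  m[, keep, drop = FALSE]
}

randomAlignment <- function(nrow = sample(3:8, 1), ncol = sample(20:80, 1),
                            gapProb = 0.1, conservedProb = 0.4) {
  m <- matrix("", nrow, ncol)
  for (j in seq_len(ncol)) {
    if (runif(1) < conservedProb) {
      m[, j] <- sample(AA20, 1)
    } else {
      m[, j] <- sample(AA20, nrow, TRUE)
      gaps <- runif(nrow) < gapProb
      m[gaps, j] <- "-"
    }
  }
  rownames(m) <- sprintf("t%02d", seq_len(nrow))
  m
}

# ---- exhaustive ancestral-state-sum likelihood oracle (5 taxa) ----
# tree ((A:ta,B:tb):tu,(C:tc,D:td):tv,E:te); with internal nodes R, U, V
exhaustiveLnL5 <- function(m, bl, model) {
  pi <- model@frequencies
  P_RU <- transitionMatrix(model, bl["u"])
  P_RV <- transitionMatrix(model, bl["v"])
  P_UA <- transitionMatrix(model, bl["a"])
  P_UB <- transitionMatrix(model, bl["b"])
  P_VC <- transitionMatrix(model, bl["c"])
  P_VD <- transitionMatrix(model, bl["d"])
  P_RE <- transitionMatrix(model, bl["e"])
  grid <- expand.grid(r = 1:20, u = 1:20, v = 1:20)
  base <- pi[grid$r] * P_RU[cbind(grid$r, grid$u)] *
    P_RV[cbind(grid$r, grid$v)]
  total <- 0
  for (col in seq_len(ncol(m))) {
    a <- match(m["A", col], AA20); b <- match(m["B", col], AA20)
    cc <- match(m["C", col], AA20); d <- match(m["D", col], AA20)
    e <- match(m["E", col], AA20)
    lik <- base * P_UA[cbind(grid$u, a)] * P_UB[cbind(grid$u, b)] *
      P_VC[cbind(grid$v, cc)] * P_VD[cbind(grid$v, d)] *
      P_RE[cbind(grid$r, e)]
    total <- total + log(sum(lik))
  }
  total
}

# ---- sequence simulation on a tree (independent of the fixture module) ----
simulateAlignment <- function(tree, model, L) {
  tr <- reorder(tree, "cladewise")
  nTip <- length(tr$tip.label)
  seqs <- vector("list", nTip + tr$Nnode)
  seqs[[nTip + 1]] <- sample(AA20, L, TRUE, prob = model@frequencies)
  for (e in seq_len(nrow(tr$edge))) {
    P <- transitionMatrix(model, tr$edge.length[e])
    idx <- match(seqs[[tr$edge[e, 1]]], AA20)
    seqs[[tr$edge[e, 2]]] <- vapply(idx, function(i)
      sample(AA20, 1, prob = P[i, ]), "")
  }
  m <- do.call(rbind, seqs[seq_len(nTip)])
  rownames(m) <- tr$tip.label
  m
}
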
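jtt <- substitutionModel("JTT")

test_that("transition matrices behave like a scaled reversible CTMC", {
  expect_equal(transitionMatrix(jtt, 0), diag(20), ignore_attr = TRUE)
  expect_error(transitionMatrix(jtt, -0.1), "non-negative")
  P <- transitionMatrix(jtt, 0.5)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # ergodic limit: every row approaches the stationary frequencies
  Pl <- transitionMatrix(jtt, 1000)
  expect_lt(max(abs(sweep(Pl, 2, jtt@frequencies))), 1e-6)
  # detailed balance pi_i P_ij = pi_j P_ji
  set.seed(41)
  for (t in runif(3, 0.05, 2)) {
    Pt <- transitionMatrix(jtt, t)
    M <- jtt@frequencies * Pt
    expect_lt(max(abs(M - t(M))), 1e-8)
  }
  # Chapman-Kolmogorov P(s) P(t) = P(s+t)
  expect_lt(max(abs(transitionMatrix(jtt, 0.3) %*%
                    transitionMatrix(jtt, 0.7) -
                    transitionMatrix(jtt, 1.0))), 1e-8)
})

test_that("all five empirical matrices load with valid frequencies", {
  for (nm in c("Dayhoff", "JTT", "LG", "RtREV", "WAG")) {
    m <- substitutionModel(nm)
    expect_s4_class(m, "SubstitutionModel")
    expect_equal(sum(m@frequencies), 1, tolerance = 1e-9)
    expect_equal(m@freeParams, 0L)
    # rate matrix rows sum to zero and mean rate is one
    Q <- m@eig$Q
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_equal(-sum(m@frequencies * diag(Q)), 1, tolerance = 1e-12)
  }
  expect_error(substitutionModel("NOPE"))
})

test_that("two-taxon likelihood matches the closed form to high precision", {
  set.seed(42)
  s1 <- sample(AA20, 40, TRUE)
  s2 <- sample(AA20, 40, TRUE)
  aln <- c(A = paste(s1, collapse = ""), B = paste(s2, collapse = ""))
  tree <- ape::read.tree(text = "(A:0.12,B:0.33);")
  P <- transitionMatrix(jtt, 0.45)
  a <- match(s1, AA20); b <- match(s2, AA20)
  closed <- sum(log(jtt@frequencies[a] * P[cbind(a, b)]))
  expect_equal(logLikelihood(aln, tree, jtt), closed, tolerance = 1e-9)
})

test_that("fully ambiguous columns contribute zero log-likelihood", {
  tree <- ape::read.tree(text = "(A:0.1,B:0.2);")
  base <- c(A = "MKV", B = "MKV")
  withQ <- c(A = "MKV?", B = "MKV-")
  expect_equal(logLikelihood(withQ, tree, jtt),
               logLikelihood(base, tree, jtt), tolerance = 1e-12)
  allAmb <- c(A = "?", B = "X")
  expect_equal(logLikelihood(allAmb, tree, jtt), 0, tolerance = 1e-12)
})

test_that("likelihood is invariant to re-rooting and leaf order", {
  set.seed(43)
  tree <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.05);")
  m <- matrix(sample(AA20, 4 * 25, TRUE), 4, 25,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  ll <- logLikelihood(m, tree, jtt)
  for (og in c("A", "C", "D")) {
    rt <- ape::root(tree, outgroup = og, resolve.root = TRUE)
    expect_equal(logLikelihood(m, rt, jtt), ll, tolerance = 1e-8)
  }
  expect_equal(logLikelihood(m[sample(4), ], tree, jtt), ll,
               tolerance = 1e-10)
  expect_error(logLikelihood(m[1:3, ], tree, jtt), "missing tree leaves")
})

test_that("pruning equals the exhaustive ancestral-state-sum oracle", {
  set.seed(44)
  bl <- c(a = 0.2, b = 0.3, c = 0.25, d = 0.1, e = 0.35, u = 0.15, v = 0.08)
  tree <- ape::read.tree(text = sprintf(
    "((A:%g,B:%g):%g,(C:%g,D:%g):%g,E:%g);",
    bl["a"], bl["b"], bl["u"], bl["c"], bl["d"], bl["v"], bl["e"]))
  m <- matrix(sample(c(AA20, "?"), 5 * 30, TRUE, prob = c(rep(1, 20), 2)),
              5, 30, dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  # oracle treats ? as marginalized over all states: encode as X row of ones
  mo <- m
  got <- logLikelihood(m, tree, jtt)
  oracleSafe <- m
  oracleSafe[oracleSafe == "?"] <- NA
  # use only fully resolved columns for the closed 20^3 enumeration
  keep <- colSums(is.na(oracleSafe)) == 0
  gotResolved <- logLikelihood(m[, keep, drop = FALSE], tree, jtt)
  want <- exhaustiveLnL5(m[, keep, drop = FALSE], bl, jtt)
  expect_equal(gotResolved, want, tolerance = 1e-6)
  expect_lt(got, 0)
})

test_that("the likelihood agrees with an independent phylogenetics library", {
  set.seed(45)
  tree <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.05);")
  m <- matrix(sample(AA20, 4 * 40, TRUE), 4, 40,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  pd <- phangorn::phyDat(m, type = "AA")
  fit <- phangorn::pml(tree, pd, model = "JTT")
  expect_equal(logLikelihood(m, tree, jtt), as.numeric(fit$logLik),
               tolerance = 1e-4)
})

test_that("discrete gamma converges to the homogeneous model as alpha grows", {
  set.seed(46)
  tree <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.25);")
  m <- matrix(sample(AA20, 3 * 30, TRUE), 3, 30,
              dimnames = list(c("A", "B", "C"), NULL))
  plain <- logLikelihood(m, tree, jtt)
  g <- substitutionModel("JTT", alpha = 1e4)
  expect_equal(logLikelihood(m, tree, g), plain, tolerance = 1e-3)
  expect_equal(mean(gammaRates(0.7)), 1, tolerance = 1e-9)
  expect_error(gammaRates(-1), "positive")
})

test_that("AIC arithmetic and parameter counts are exact", {
  base <- substitutionModel("WAG")
  expect_equal(base@freeParams, 0L)
  expect_equal(substitutionModel("WAG", alpha = 1)@freeParams, 1L)
  expect_equal(substitutionModel("WAG", frequencies = rep(0.05, 20))@freeParams,
               19L)
  expect_equal(substitutionModel("WAG", rep(0.05, 20), 1)@freeParams, 20L)
  # aic = 2k - 2 lnL
  expect_equal(2 * 1L - 2 * (-1234.5), 2471)
})

test_that("model ranking prefers the generating matrix and breaks ties by k", {
  set.seed(47)
  wag <- substitutionModel("WAG")
  tree <- ape::read.tree(
    text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.1,E:0.3);")
  wins <- 0L
  for (r in 1:5) {
    m <- simulateAlignment(tree, wag, 400)
    rk <- rankModels(m, baseTree = tree, modelNames = c("WAG", "Dayhoff"),
                     variants = "")
    expect_equal(rk$aic, 2 * rk$k - 2 * rk$lnL)
    if (rk$model[1] == "WAG") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
  # identical lnL, different k: smaller k ranks first (ties by model name)
  scores <- data.frame(model = c("B+G", "A"), lnL = c(-10, -10),
                       k = c(1L, 0L))
  scores$aic <- 2 * scores$k - 2 * scores$lnL
  o <- order(scores$aic, scores$model)
  expect_equal(scores$model[o][1], "A")
})

test_that("model summaries count top ranks and break frequency ties lexicographically", {
  rk <- function(best) {
    data.frame(model = c(best, "ZZZ"), lnL = c(-10, -20), k = c(0L, 0L),
               aic = c(20, 40), alpha = NA_real_, stringsAsFactors = FALSE)
  }
  sm <- summarizeModels(list(a1 = rk("WAG"), a2 = rk("WAG"), a3 = rk("JTT")))
  expect_equal(sm$frequency$model[1], "WAG")
  expect_equal(sm$frequency$n, c(2L, 1L))
  expect_equal(as.character(sm$oneModel), "WAG")
  expect_false(attr(sm$oneModel, "tie"))
  expect_equal(unname(sm$assignment["a3"]), "JTT")
  # single alignment: its best model is the one-model choice
  sm1 <- summarizeModels(list(only = rk("LG")))
  expect_equal(as.character(sm1$oneModel), "LG")
  # tie: lexicographically smallest wins and the tie is flagged
  smT <- summarizeModels(list(a = rk("WAG"), b = rk("JTT")))
  expect_equal(as.character(smT$oneModel), "JTT")
  expect_true(attr(smT$oneModel, "tie"))
})

test_that("misspecified models score lower likelihood on average", {
  set.seed(48)
  wag <- substitutionModel("WAG")
  day <- substitutionModel("Dayhoff")
  tree <- ape::read.tree(text = "((A:0.3,B:0.2):0.1,C:0.25);")
  diffs <- replicate(5, {
    m <- simulateAlignment(tree, wag, 300)
    logLikelihood(m, tree, wag) - logLikelihood(m, tree, day)
  })
  expect_gt(mean(diffs), 0)
})
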
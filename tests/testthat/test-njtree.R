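jttM <- substitutionModel("JTT")

test_that("ML distances are near zero for identical rows and exactly symmetric", {
  set.seed(51)
  s <- paste(sample(AA20, 100, TRUE), collapse = "")
  expect_lte(mlDistance(s, s, jttM), 1e-4)
  x <- paste(sample(AA20, 200, TRUE), collapse = "")
  y <- paste(sample(AA20, 200, TRUE), collapse = "")
  expect_identical(mlDistance(x, y, jttM), mlDistance(y, x, jttM))
})

test_that("ML distances recover the simulated divergence", {
  set.seed(52)
  tree <- ape::read.tree(text = "(A:0.25,B:0.25);")
  errs <- replicate(10, {
    m <- simulateAlignment(tree, jttM, 1000)
    abs(mlDistance(m[1, ], m[2, ], jttM) - 0.5)
  })
  expect_lt(max(errs), 0.1)
})

test_that("incomparable columns are excluded pairwise, empty overlap errors", {
  expect_equal(mlDistance("MK?L-", "MKV?A", jttM),
               mlDistance("MK", "MK", jttM))
  expect_error(mlDistance("??", "MK", jttM), "comparable")
  m <- matrix(c("M", "?", "?", "K"), 2, 2,
              dimnames = list(c("t1", "t2"), NULL))
  expect_error(mlDistanceMatrix(m, jttM), "t1.*t2")
})

test_that("neighbor joining resolves the additive quartet with exact lengths", {
  D <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(D)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(nrow(tr$edge), 2 * 4 - 3)  # fully resolved unrooted
  # split AB|CD present with internal edge length 2
  splits <- orthopipe:::.treeSplits(tr, "A")
  expect_true(any(vapply(splits, function(s)
    identical(s, c("C", "D")), TRUE)))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sort(internal), 2, tolerance = 1e-12)
  expect_equal(attr(tr, "clamped"), 0)
  expect_error(neighborJoining(D[1:2, 1:2]), "at least 3")
})

test_that("the three-taxon star uses the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighborJoining(D)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("x", "y", "z")], c(x = 1, y = 2, z = 3))
})

test_that("random additive matrices are reconstructed exactly", {
  set.seed(53)
  for (trial in 1:20) {
    t0 <- ape::rtree(8)
    D <- ape::cophenetic.phylo(t0)
    o <- sort(rownames(D))
    tr <- neighborJoining(D[o, o])
    expect_equal(ape::dist.topo(ape::unroot(t0), tr), 0, ignore_attr = TRUE)
    # branch lengths recovered (compare sorted edge length multisets)
    expect_equal(sort(tr$edge.length), sort(ape::unroot(t0)$edge.length),
                 tolerance = 1e-8)
    expect_equal(attr(tr, "clamped"), 0, tolerance = 1e-10)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(54)
  n <- 7
  D <- as.matrix(stats::dist(matrix(runif(n * 4), n)))
  dimnames(D) <- list(letters[1:n], letters[1:n])
  ours <- neighborJoining(D)
  theirs <- ape::nj(D)
  expect_equal(ape::dist.topo(ours, theirs), 0, ignore_attr = TRUE)
})

test_that("negative branch lengths are clamped and the amount reported", {
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 8  # violates additivity
  tr <- neighborJoining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("majority-rule consensus keeps exactly the >50% bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  # a 50/50 split yields no conflicting bipartition (strictly > 50%)
  cons <- consensusTree(list(t1, t2, t1, t2))
  expect_equal(cons$Nnode, 1L)  # star
  # unanimous replicates carry 100% supports
  consU <- consensusTree(list(t1, t1, t1, t1))
  labs <- consU$node.label[consU$node.label != ""]
  expect_true(all(labs == "100"))
  expect_equal(ape::dist.topo(ape::unroot(consU), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  # 3-of-4 majority: split retained at 75
  cons3 <- consensusTree(list(t1, t1, t1, t2))
  expect_true("75" %in% cons3$node.label)
})

test_that("all consensus supports lie in (50, 100] and survive rooting", {
  fx <- plantedFixture("njboot", nGenomes = 6, nSingleCopy = 4,
                       nParalog = 0, ancestorLength = 80, seed = 61)
  truth <- fx$truth
  fam1 <- truth[truth$family_id == truth$family_id[1], ]
  m <- orthopipe:::.asAlignmentMatrix(stats::setNames(
    as.character(proteins(fx$ps)[fam1$alias]), fam1$genome_id))
  un <- bootstrapConsensus(m, jttM, replicates = 20, seed = 9)
  supports <- as.integer(un$node.label[nzchar(un$node.label)])
  expect_true(all(supports > 50 & supports <= 100))
  ro <- bootstrapConsensus(m, jttM, replicates = 20, seed = 9,
                           outgroup = fam1$genome_id[1])
  sro <- as.integer(ro$node.label[nzchar(ro$node.label)])
  expect_setequal(sro, supports)
  expect_error(bootstrapConsensus(m, jttM, replicates = 5, seed = 1,
                                  outgroup = "nope"), "outgroup")
})

test_that("bootstrap consensus is byte-identical under a fixed seed", {
  fx <- plantedFixture("njboot", nGenomes = 6, nSingleCopy = 4,
                       nParalog = 0, ancestorLength = 80, seed = 61)
  truth <- fx$truth
  fam1 <- truth[truth$family_id == truth$family_id[1], ]
  m <- orthopipe:::.asAlignmentMatrix(stats::setNames(
    as.character(proteins(fx$ps)[fam1$alias]), fam1$genome_id))
  f1 <- tempfile(); f2 <- tempfile()
  writeNewickTree(bootstrapConsensus(m, jttM, 15, seed = 7), f1)
  writeNewickTree(bootstrapConsensus(m, jttM, 15, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("Newick writer round trips topology, lengths and supports", {
  txt <- "((A:0.123456,B:0.2):0.05,(C:0.3,D:0.4)88:0.06,E:0.5);"
  tr <- ape::read.tree(text = txt)
  tr$node.label <- c("", "95", "88")
  tf <- tempfile()
  writeNewickTree(tr, tf)
  back <- readNewickTree(tf)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-6)
  expect_identical(back$node.label, tr$node.label)
})

test_that("external phylogenetic program adapters emit partitioned commands", {
  cmd <- phyloCommand("raxml", "super.phy", "part.txt", outgroup = "gX")
  expect_true(all(c("-q", "part.txt", "-o", "gX") %in% cmd))
  cmd2 <- phyloCommand("phyml", "super.phy", model = "WAG")
  expect_equal(cmd2[1], "phyml")
  expect_true("WAG" %in% cmd2)
})
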
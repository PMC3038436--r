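clusteringOf <- function(clusters, inflation = 2) {
  new("Clustering", inflation = inflation, clusters = clusters,
      iterations = 1L, converged = TRUE)
}

test_that("single-copy selection enforces copy number and taxon fraction", {
  fx <- studyFixture()
  ps <- fx$ps
  am <- as.data.frame(aliasMap(ps))
  g1 <- am$alias[am$genome_id == genomes(ps)[1]]
  dup <- clusteringOf(list(g1[1:2]))
  sel <- selectSingleCopy(dup, ps, 0.5)
  expect_length(sel$accepted, 0L)
  expect_equal(sel$rejected$reason, "not_single_copy")
  # 5 genomes, 4 taxa at minimum 0.8: accepted (up to 20% missing data)
  four <- vapply(genomes(ps)[1:4], function(g) am$alias[am$genome_id == g][1], "")
  sel <- selectSingleCopy(clusteringOf(list(unname(four))), ps, 0.8)
  expect_length(sel$accepted, 1L)
  expect_equal(sel$accepted[[1]]$taxonFraction, 0.8)
  # same cluster at minimum 1.0: rejected
  sel <- selectSingleCopy(clusteringOf(list(unname(four))), ps, 1)
  expect_equal(sel$rejected$reason, "below_taxon_fraction")
})

test_that("coverage thresholds pass exactly the sufficiently covered families", {
  fx <- plantedFixture("cov", nGenomes = 5, nSingleCopy = 2,
                       nLineageRestricted = 6,
                       lineageCoverage = c(1, 0.8, 0.4), nParalog = 0,
                       seed = 17)
  truth <- fx$truth
  fams <- split(truth, truth$family_id)
  clusters <- lapply(fams, function(f) f$alias)
  cl <- clusteringOf(unname(clusters))
  sel <- selectSingleCopy(cl, fx$ps, 0.6)
  passFrac <- vapply(fams, function(f) f$coverage[1], 0)
  expect_length(sel$accepted, sum(passFrac >= 0.6))
})

test_that("best-hit consistency accepts internal and rejects external best hits", {
  fx <- studyFixture()
  sc <- fx$truth[fx$truth$class == "single_copy", ]
  famIds <- unique(sc$family_id)
  # planted families pass
  for (fam in famIds[1:5]) {
    mem <- sc[sc$family_id == fam, ]
    cc <- smallCluster(mem$alias, taxa = mem$genome_id)
    expect_true(bestHitConsistent(cc, fx$graph, fx$ps))
  }
  # contaminate: swap one member for the same genome's protein from another
  # family; its best hits point outside the cluster
  memA <- sc[sc$family_id == famIds[1], ]
  memB <- sc[sc$family_id == famIds[2], ]
  swapped <- memA$alias
  swapped[1] <- memB$alias[memB$genome_id == memA$genome_id[1]]
  cc <- smallCluster(swapped, taxa = memA$genome_id)
  expect_false(bestHitConsistent(cc, fx$graph, fx$ps))
})

test_that("members with no hit into a cluster genome do not violate the rule", {
  fx <- studyFixture()
  sc <- fx$truth[fx$truth$class == "single_copy", ]
  mem <- sc[sc$family_id == sc$family_id[1], ]
  # restrict best hits so one member has none into one genome
  g <- fx$graph
  drop <- g@bestHits$query == mem$alias[1] & g@bestHits$genome == mem$genome_id[2]
  g@bestHits <- g@bestHits[!drop, , drop = FALSE]
  cc <- smallCluster(mem$alias, taxa = mem$genome_id)
  expect_true(bestHitConsistent(cc, g, fx$ps))
})

test_that("the sweep filter keeps one copy of a family, from the most stringent inflation", {
  fx <- studyFixture()
  sc <- fx$truth[fx$truth$class == "single_copy", ]
  fam <- split(sc$alias, sc$family_id)
  clA <- clusteringOf(unname(fam), inflation = 5.0)
  clB <- clusteringOf(unname(fam), inflation = 1.5)
  cs <- filterSweep(list(clB, clA), fx$graph, fx$ps, 0.8)
  expect_length(accepted(cs), length(fam))
  expect_true(all(vapply(accepted(cs), `[[`, 0, "inflation") == 5.0))
  expect_equal(sum(rejectionLog(cs)$reason == "overlaps_accepted"),
               length(fam))
})

test_that("a degenerate one-clustering sweep equals direct selection", {
  fx <- studyFixture()
  sc <- fx$truth[fx$truth$class == "single_copy", ]
  fam <- split(sc$alias, sc$family_id)
  cl <- clusteringOf(unname(fam), inflation = 2.0)
  cs <- filterSweep(list(cl), fx$graph, fx$ps, 0.8)
  direct <- selectSingleCopy(cl, fx$ps, 0.8)$accepted
  directKeys <- sort(vapply(direct, function(x)
    paste(x$members, collapse = ","), ""))
  keep <- vapply(direct, function(x)
    bestHitConsistent(x, fx$graph, fx$ps), TRUE)
  expect_equal(acceptedKeys(cs),
               sort(vapply(direct[keep], function(x)
                 paste(x$members, collapse = ","), "")))
  expect_error(filterSweep(list(), fx$graph, fx$ps, 0.8), "empty")
})

test_that("planted families are recovered with high precision and recall", {
  fx <- studyFixture()
  sweep <- studySweep()
  cs <- filterSweep(sweep, fx$graph, fx$ps, 0.8)
  truthKeys <- truthFamilies(fx$truth, "single_copy")
  accKeys <- acceptedKeys(cs)
  tp <- sum(accKeys %in% truthKeys)
  expect_gte(tp / length(accKeys), 0.95)
  expect_gte(tp / length(truthKeys), 0.95)
  # accepted clusters are pairwise disjoint
  members <- unlist(lapply(accepted(cs), `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  # raising the taxon-fraction threshold never accepts more clusters
  cs100 <- filterSweep(sweep, fx$graph, fx$ps, 1.0)
  expect_lte(length(accepted(cs100)), length(accepted(cs)))
  # at fraction 1 every accepted cluster covers all genomes exactly once
  for (cc in accepted(cs100))
    expect_identical(cc$taxa, sort(genomes(fx$ps)))
})

test_that("cluster ids are deterministic and the table round trips", {
  fx <- studyFixture()
  sweep <- studySweep()
  cs <- assignClusterIds(filterSweep(sweep, fx$graph, fx$ps, 0.8))
  ids <- vapply(accepted(cs), `[[`, "", "id")
  expect_identical(ids, sort(ids))
  tf <- tempfile()
  writeClusterTable(cs, fx$ps, tf)
  tab <- readClusterTable(tf)
  expect_setequal(tab$alias, unlist(lapply(accepted(cs), `[[`, "members")))
  expect_identical(tab$original_header,
                   aliasToHeader(fx$ps, tab$alias))
})
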
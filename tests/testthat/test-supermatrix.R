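caG <- function(id, rows) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  new("ClusterAlignment", clusterId = id, aln = m)
}

test_that("normalization fills missing taxa with ? and preserves present rows", {
  a <- caG("c1", c(gA = "MKVL", gB = "MKIL"))
  n <- normalizeAlignment(a, c("gA", "gB", "gC"))
  m <- alignmentMatrix(n)
  expect_identical(rownames(m), c("gA", "gB", "gC"))
  expect_identical(paste(m["gC", ], collapse = ""), "????")
  expect_identical(paste(m["gA", ], collapse = ""), "MKVL")
  # complete alignment: identical content, target order
  b <- caG("c2", c(gB = "MK", gA = "ML"))
  m2 <- alignmentMatrix(normalizeAlignment(b, c("gA", "gB")))
  expect_identical(rownames(m2), c("gA", "gB"))
  expect_identical(paste(m2["gB", ], collapse = ""), "MK")
  # duplicate genome is an error
  dup <- caG("c3", c(gA = "MK", gB = "ML"))
  rownames(dup@aln) <- c("gA", "gA")
  expect_error(normalizeAlignment(dup, c("gA", "gB")), "[Dd]uplicate")
})

test_that("alias rows are exchanged for organism names before normalization", {
  fx <- studyFixture()
  sc <- fx$truth[fx$truth$class == "single_copy", ]
  mem <- sc[sc$family_id == sc$family_id[1], ]
  seqs <- as.character(proteins(fx$ps)[mem$alias])
  a <- caG("c1", seqs)
  g <- aliasesToGenomes(a, fx$ps)
  expect_setequal(rownames(alignmentMatrix(g)), mem$genome_id)
})

test_that("concatenation records contiguous partitions and correct widths", {
  taxa <- c("gA", "gB")
  a1 <- normalizeAlignment(caG("c1", c(gA = strrep("A", 10),
                                       gB = strrep("C", 10))), taxa)
  a2 <- normalizeAlignment(caG("c2", c(gA = strrep("D", 20),
                                       gB = strrep("E", 20))), taxa)
  sa <- concatenateAlignments(list(a2, a1), taxa,
                              models = c(c1 = "JTT", c2 = "WAG"))
  expect_equal(nchar(sa@matrix[["gA"]]), 30L)
  expect_equal(partitions(sa)$cluster_id, c("c1", "c2"))  # lexicographic
  expect_equal(partitions(sa)$start, c(1L, 11L))
  expect_equal(partitions(sa)$end, c(10L, 30L))
  expect_equal(partitions(sa)$model, c("JTT", "WAG"))
  # single alignment: identity concatenation
  s1 <- concatenateAlignments(list(a1), taxa)
  expect_equal(nrow(partitions(s1)), 1L)
  expect_identical(s1@matrix[["gA"]], strrep("A", 10))
  # un-normalized input is rejected
  bad <- caG("c9", c(gB = "MK", gA = "ML"))
  expect_error(concatenateAlignments(list(bad), taxa), "normalized")
})

test_that("concatenation is associative element-wise", {
  taxa <- c("gA", "gB")
  mk <- function(id, w)
    normalizeAlignment(caG(id, stats::setNames(
      c(strrep(sample(LETTERS[1:20], 1), w), strrep("K", w)), taxa)), taxa)
  set.seed(5)
  A <- mk("a", 4); B <- mk("b", 6); C <- mk("c", 3)
  bc <- concatenateAlignments(list(B, C), taxa)
  all3 <- concatenateAlignments(list(A, B, C), taxa)
  joined <- paste0(
    concatenateAlignments(list(A), taxa)@matrix,
    bc@matrix)
  expect_identical(unname(all3@matrix), unname(joined))
})

test_that("missing-data bookkeeping adds up across a fixture supermatrix", {
  fx <- plantedFixture("sm", nGenomes = 4, nSingleCopy = 8,
                       nLineageRestricted = 7, lineageCoverage = c(0.75, 0.5),
                       nParalog = 0, ancestorLength = 40, seed = 23)
  truth <- fx$truth
  taxa <- genomes(fx$ps)
  alns <- list()
  for (fam in unique(truth$family_id)) {
    mem <- truth[truth$family_id == fam, ]
    seqs <- as.character(proteins(fx$ps)[mem$alias])
    names(seqs) <- mem$alias
    a <- new("ClusterAlignment", clusterId = fam,
             aln = orthopipe:::.asAlignmentMatrix(seqs))
    alns[[fam]] <- normalizeAlignment(aliasesToGenomes(a, fx$ps), taxa)
  }
  sa <- concatenateAlignments(alns, taxa)
  p <- partitions(sa)
  L <- nchar(sa@matrix[[1]])
  # partitions tile [1, L]
  expect_equal(p$start[1], 1L)
  expect_equal(p$end[nrow(p)], L)
  expect_true(all(p$start[-1] == p$end[-nrow(p)] + 1L))
  # per-taxon ? count equals the summed widths of its missing clusters
  for (g in taxa) {
    qs <- sum(strsplit(sa@matrix[[g]], "")[[1]] == "?")
    missW <- 0L
    for (fam in unique(truth$family_id)) {
      if (!g %in% truth$genome_id[truth$family_id == fam])
        missW <- missW + (p$end[p$cluster_id == fam] -
                          p$start[p$cluster_id == fam] + 1L)
    }
    expect_equal(qs, missW)
    # the ? fraction of a cluster row matches 1 - coverage overall
  }
  # removing the ? fill reproduces the concatenation of that taxon's rows
  g <- taxa[1]
  own <- paste(vapply(sort(unique(truth$family_id)), function(fam) {
    mem <- truth[truth$family_id == fam & truth$genome_id == g, ]
    if (nrow(mem)) as.character(proteins(fx$ps)[mem$alias]) else ""
  }, ""), collapse = "")
  expect_identical(gsub("\\?", "", sa@matrix[[g]]), own)
})

test_that("partition files round trip in the RAxML dialect", {
  p <- data.frame(cluster_id = c("c1", "c2"), start = c(1L, 11L),
                  end = c(10L, 30L), model = c("JTT", "WAG"),
                  stringsAsFactors = FALSE)
  tf <- tempfile()
  writePartitionFile(p, tf)
  expect_identical(readLines(tf)[1], "JTT, c1 = 1-10")
  expect_identical(readPartitionFile(tf), p)
  writeLines("not a partition line", tf)
  expect_error(readPartitionFile(tf), "malformed")
})

test_that("a many-partition map keeps contiguous ranges through the file", {
  set.seed(6)
  widths <- sample(5:50, 300, TRUE)
  ends <- cumsum(widths)
  p <- data.frame(cluster_id = sprintf("c%04d", seq_along(widths)),
                  start = ends - widths + 1L, end = ends,
                  model = sample(c("JTT", "WAG", "LG"), 300, TRUE),
                  stringsAsFactors = FALSE)
  tf <- tempfile()
  writePartitionFile(p, tf)
  expect_equal(length(readLines(tf)), 300L)
  back <- readPartitionFile(tf)
  expect_identical(back, p)
  expect_true(all(back$start[-1] == back$end[-300] + 1L))
})

test_that("super alignments round trip through FASTA and PHYLIP writers", {
  taxa <- c("gA", "gB", "gC")
  a <- normalizeAlignment(caG("c1", c(gA = "MKVL", gB = "MKIL")), taxa)
  b <- normalizeAlignment(caG("c2", c(gB = "WWQQ", gC = "WWQE")), taxa)
  sa <- concatenateAlignments(list(a, b), taxa,
                              models = c(c1 = "JTT", c2 = "WAG"))
  for (fmt in c("fasta", "relaxed_phylip")) {
    tf <- tempfile(); pf <- tempfile()
    writeSuperAlignment(sa, tf, fmt)
    writePartitionFile(sa, pf)
    back <- readSuperAlignment(tf, fmt, partitionPath = pf, mode = sa@mode)
    expect_identical(back@matrix, sa@matrix)
    expect_identical(back@taxa, sa@taxa)
    expect_identical(back@partitions, sa@partitions)
  }
})
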
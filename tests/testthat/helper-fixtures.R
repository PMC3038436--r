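# Shared fixture construction: generates a planted-orthology data set once
# per test session and caches the derived objects.

.fixtureCache <- new.env(parent = emptyenv())

plantedFixture <- function(key = "default", ...) {
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  spec <- fixtureSpec(...)
  dir <- file.path(tempdir(), paste0("orthopipe_fx_", key))
  unlink(dir, recursive = TRUE)
  fx <- generateProteomes(spec, dir)
  ps <- buildAliasMap(readProteomes(fx$paths))
  hitsPath <- file.path(dir, "hits.tsv")
  expectedHits <- synthHitTable(ps, fx$truth, hitsPath, spec)
  hits <- parseTabularHits(hitsPath, 1e-1, ps)
  graph <- buildGraph(hits, ps)
  out <- list(spec = spec, dir = dir, fx = fx, truth = fx$truth, ps = ps,
              hitsPath = hitsPath, expectedHits = expectedHits,
              hits = hits, graph = graph)
  .fixtureCache[[key]] <- out
  out
}

# the study-condition fixture: 5 genomes, 20 clean single-copy families,
# 5 paralog-contaminated families
studyFixture <- function() {
  plantedFixture("study", nGenomes = 5, nSingleCopy = 20, nParalog = 5,
                 seed = 11)
}

# cached default inflation sweep over the study fixture
studySweep <- function() {
  if (is.null(.fixtureCache[["study_sweep"]])) {
    fx <- studyFixture()
    .fixtureCache[["study_sweep"]] <-
      inflationSweep(edgeWeights(fx$graph))
  }
  .fixtureCache[["study_sweep"]]
}

truthFamilies <- function(truth, classes = "single_copy") {
  fams <- split(truth$alias[truth$class %in% classes],
                truth$family_id[truth$class %in% classes])
  sort(vapply(fams, function(x) paste(sort(x), collapse = ","), ""))
}

acceptedKeys <- function(clusterSet) {
  sort(vapply(accepted(clusterSet),
              function(cc) paste(cc$members, collapse = ","), ""))
}

smallCluster <- function(members, inflation = 2, taxa, fraction = 1) {
  list(members = sort(members), inflation = inflation, taxa = sort(taxa),
       taxonFraction = fraction)
}
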
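# Shared end-to-end pipeline fixture: 4 genomes, 6 clean single-copy
# families, 1 paralogous family; a cached reference run for comparisons.

pipelineInput <- function() {
  if (!is.null(.fixtureCache[["pipe_in"]])) return(.fixtureCache[["pipe_in"]])
  dir <- file.path(tempdir(), "orthopipe_pipe")
  unlink(dir, recursive = TRUE)
  spec <- fixtureSpec(nGenomes = 4, nSingleCopy = 6, nParalog = 1,
                      ancestorLength = 60, seed = 5)
  fx <- generateProteomes(spec, file.path(dir, "input"))
  ps <- buildAliasMap(readProteomes(fx$paths))
  hits <- file.path(dir, "hits.tsv")
  synthHitTable(ps, fx$truth, hits, spec)
  out <- list(dir = dir, inputDir = file.path(dir, "input"),
              hitsFile = hits, truth = fx$truth)
  .fixtureCache[["pipe_in"]] <- out
  out
}

pipeConfig <- function(outputDir, ...) {
  pin <- pipelineInput()
  runConfig(pin$inputDir, pin$hitsFile, outputDir,
            bootstrapReplicates = 10, minAlignmentLength = 20, seed = 3, ...)
}

productFiles <- function(out) {
  sort(c(list.files(file.path(out, "concat"), full.names = TRUE),
         list.files(file.path(out, "models"), full.names = TRUE),
         list.files(file.path(out, "trees"), full.names = TRUE)))
}

productHashes <- function(out) {
  f <- productFiles(out)
  stats::setNames(unname(tools::md5sum(f)), basename(f))
}

referenceRun <- function() {
  if (is.null(.fixtureCache[["pipe_ref"]])) {
    pin <- pipelineInput()
    out <- file.path(pin$dir, "ref")
    runPipeline(pipeConfig(out))
    .fixtureCache[["pipe_ref"]] <- out
  }
  .fixtureCache[["pipe_ref"]]
}
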
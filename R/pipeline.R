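#' @importFrom tools md5sum
#' @importFrom yaml write_yaml read_yaml
NULL

.PIPELINE_STEPS <- c("qc", "graph", "sweep", "filter", "align", "trim",
                     "concat", "models", "trees")

#' Assemble and validate a pipeline run configuration
#'
#' @param inputDir directory of proteome FASTA files (one per genome).
#' @param hitsFile all-vs-all similarity results (12-column tabular).
#' @param outputDir run output directory (created if missing).
#' @param aligner `builtin` or an external adapter id.
#' @param inflations inflation sweep for Markov clustering.
#' @param minTaxonFraction minimum fraction of genomes per cluster.
#' @param minAlignmentLength minimum edited-alignment length (columns).
#' @param trimModes subset of the three alignment-editing modes.
#' @param bootstrapReplicates bootstrap replicates for the NJ consensus.
#' @param outgroup optional genome id used to root the trees.
#' @param cutoffEvalue e-value cutoff for the similarity graph.
#' @param seed master seed; every stochastic step derives its seed from it.
#' @param keepIntermediates keep per-step intermediate files.
#' @return a validated `runConfig` list.
#' @export
runConfig <- function(inputDir, hitsFile, outputDir,
                      aligner = "builtin",
                      inflations = c(1.1, 1.2, 1.3, 1.4, 1.5, 1.7, 2.0, 2.5,
                                     3.0, 3.5, 4.0, 4.5, 5.0),
                      minTaxonFraction = 0.8,
                      minAlignmentLength = 30L,
                      trimModes = .TRIM_MODES,
                      bootstrapReplicates = 100L,
                      outgroup = NULL,
                      cutoffEvalue = 1e-1,
                      seed = 1L,
                      keepIntermediates = TRUE) {
  if (!dir.exists(inputDir)) stop("input directory does not exist: ", inputDir)
  if (!file.exists(hitsFile)) stop("hits file does not exist: ", hitsFile)
  stopifnot(minTaxonFraction > 0, minTaxonFraction <= 1,
            minAlignmentLength >= 1, bootstrapReplicates >= 1,
            all(trimModes %in% .TRIM_MODES), length(trimModes) >= 1,
            all(inflations > 1))
  structure(list(inputDir = inputDir, hitsFile = hitsFile,
                 outputDir = outputDir, aligner = aligner,
                 inflations = inflations,
                 minTaxonFraction = minTaxonFraction,
                 minAlignmentLength = as.integer(minAlignmentLength),
                 trimModes = trimModes,
                 bootstrapReplicates = as.integer(bootstrapReplicates),
                 outgroup = outgroup, cutoffEvalue = cutoffEvalue,
                 seed = as.integer(seed),
                 keepIntermediates = isTRUE(keepIntermediates)),
            class = "runConfig")
}

.manifestPath <- function(outputDir) file.path(outputDir, "manifest.yaml")
.logPath <- function(outputDir) file.path(outputDir, "orthopipe.log")

.appendLog <- function(outputDir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  cat(line, "\n", sep = "", file = .logPath(outputDir), append = TRUE)
  invisible(line)
}

.newManifest <- function(config) {
  steps <- lapply(.PIPELINE_STEPS, function(s)
    list(status = "pending", outputs = list(), md5 = list(), params = ""))
  names(steps) <- .PIPELINE_STEPS
  list(version = 1L,
       config = unclass(config),
       seed = config$seed,
       steps = steps)
}

.writeManifest <- function(manifest, outputDir) {
  write_yaml(manifest, .manifestPath(outputDir))
  invisible(manifest)
}

#' Read a run manifest
#' @param outputDir pipeline output directory.
#' @return the manifest list.
#' @export
readManifest <- function(outputDir) {
  p <- .manifestPath(outputDir)
  if (!file.exists(p)) stop("no manifest found in ", outputDir)
  read_yaml(p)
}

# parameters that invalidate a completed step when changed (e.g. re-running
# with a different aligner restarts from the align step)
.stepParams <- function(step, config) {
  keep <- switch(step,
    qc = list(config$inputDir),
    graph = list(config$hitsFile, config$cutoffEvalue),
    sweep = list(config$inflations),
    filter = list(config$minTaxonFraction),
    align = list(config$aligner),
    trim = list(config$trimModes),
    concat = list(config$trimModes, config$minAlignmentLength),
    models = list(config$trimModes),
    trees = list(config$trimModes, config$bootstrapReplicates,
                 config$outgroup, config$seed))
  paste(deparse(keep), collapse = "")
}

.stepSeed <- function(config, step)
  config$seed + match(step, .PIPELINE_STEPS)

.relOut <- function(outputDir, paths) {
  sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", outputDir), "/?"),
      "", paths)
}

# ---- step implementations: disk in, disk out, return written files ----

.fastaInputs <- function(inputDir) {
  f <- sort(list.files(inputDir, pattern = "\\.(fa|fasta|faa)$",
                       full.names = TRUE))
  if (length(f) == 0) stop("no FASTA files found in ", inputDir)
  names(f) <- .sanitizeGenomeId(
    sub("\\.(fa|fasta|faa)$", "", basename(f)))
  f
}

.loadQC <- function(config) {
  qcDir <- file.path(config$outputDir, "qc")
  if (!file.exists(file.path(qcDir, "alias_map.tsv")))
    stop("expected qc outputs (aliased FASTA + alias_map.tsv) in ", qcDir,
         "; run the qc step first")
  am <- readAliasMap(file.path(qcDir, "alias_map.tsv"))
  gids <- unique(am$genome_id)
  fastas <- stats::setNames(file.path(qcDir, paste0(gids, ".fasta")), gids)
  loadAliasedProteomes(fastas, file.path(qcDir, "alias_map.tsv"),
                       file.path(qcDir, "qc_report.tsv"))
}

.loadGraph <- function(config, proteomes) {
  if (!file.exists(file.path(config$outputDir, "graph", "hits.tsv")))
    stop("expected graph outputs (hits.tsv, 12-column tabular source) in ",
         file.path(config$outputDir, "graph"), "; run the graph step first")
  hits <- read.table(file.path(config$outputDir, "graph", "hits.tsv"),
                     sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  buildGraph(hits, proteomes, config$cutoffEvalue)
}

.step_qc <- function(config) {
  fastas <- .fastaInputs(config$inputDir)
  ps <- buildAliasMap(readProteomes(fastas))
  qcDir <- file.path(config$outputDir, "qc")
  paths <- writeProteomeFasta(ps, qcDir)
  p1 <- writeAliasMap(ps, file.path(qcDir, "alias_map.tsv"))
  p2 <- writeQCReport(ps, file.path(qcDir, "qc_report.tsv"))
  .appendLog(config$outputDir, "qc: ", length(ps@proteins),
             " proteins across ", length(ps@genomes), " genomes; ",
             nrow(ps@qcReport), " rejected")
  c(paths, p1, p2)
}

.step_graph <- function(config) {
  ps <- .loadQC(config)
  hits <- parseTabularHits(config$hitsFile, config$cutoffEvalue, ps)
  graph <- buildGraph(hits, ps, config$cutoffEvalue)
  gDir <- file.path(config$outputDir, "graph")
  dir.create(gDir, recursive = TRUE, showWarnings = FALSE)
  hp <- file.path(gDir, "hits.tsv")
  write.table(hits, hp, sep = "\t", quote = FALSE, row.names = FALSE)
  bp <- file.path(gDir, "best_hits.tsv")
  write.table(graph@bestHits, bp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .appendLog(config$outputDir, "graph: ", nrow(hits), " edges, ",
             nrow(graph@bestHits), " best-hit entries")
  c(hp, bp)
}

.step_sweep <- function(config) {
  ps <- .loadQC(config)
  graph <- .loadGraph(config, ps)
  w <- edgeWeights(graph)
  sweep <- inflationSweep(w, inflations = config$inflations)
  cDir <- file.path(config$outputDir, "clusters")
  dir.create(cDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cl in sweep) {
    p <- file.path(cDir, sprintf("I%s.txt", format(cl@inflation)))
    writeMclClusters(cl, p)
    paths <- c(paths, p)
  }
  .appendLog(config$outputDir, "sweep: ", length(sweep),
             " inflation values, cluster counts ",
             paste(vapply(sweep, function(x) length(x@clusters), 0L),
                   collapse = "/"))
  paths
}

.step_filter <- function(config) {
  ps <- .loadQC(config)
  graph <- .loadGraph(config, ps)
  cDir <- file.path(config$outputDir, "clusters")
  clusterings <- lapply(config$inflations, function(I) {
    cl <- readMclClusters(file.path(cDir, sprintf("I%s.txt", format(I))))
    new("Clustering", inflation = I, clusters = cl, iterations = 0L,
        converged = TRUE)
  })
  cs <- filterSweep(clusterings, graph, ps, config$minTaxonFraction)
  cs <- assignClusterIds(cs)
  fDir <- file.path(config$outputDir, "filter")
  dir.create(fDir, recursive = TRUE, showWarnings = FALSE)
  p1 <- writeClusterTable(cs, ps, file.path(fDir, "accepted_clusters.tsv"))
  p2 <- writeRejectionLog(cs, file.path(fDir, "rejection_log.tsv"))
  .appendLog(config$outputDir, "filter: ", length(cs@accepted),
             " accepted clusters, ", nrow(cs@rejectionLog), " rejections")
  if (length(cs@accepted) == 0)
    stop("no clusters survived single-copy selection and filtering")
  c(p1, p2)
}

.step_align <- function(config) {
  checkAligner(config$aligner)
  ps <- .loadQC(config)
  tab <- readClusterTable(file.path(config$outputDir, "filter",
                                    "accepted_clusters.tsv"))
  aDir <- file.path(config$outputDir, "align")
  dir.create(aDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in unique(tab$cluster_id)) {
    aliases <- tab$alias[tab$cluster_id == id]
    seqs <- as.character(ps@proteins[aliases])
    aln <- alignCluster(seqs, clusterId = id, aligner = config$aligner)
    p <- file.path(aDir, paste0(id, ".fasta"))
    writeAlignmentFile(aln, p, "fasta")
    paths <- c(paths, p)
  }
  .appendLog(config$outputDir, "align: ", length(paths),
             " cluster alignments (aligner=", config$aligner, ")")
  paths
}

.step_trim <- function(config) {
  aDir <- file.path(config$outputDir, "align")
  tDir <- file.path(config$outputDir, "trim")
  dir.create(tDir, recursive = TRUE, showWarnings = FALSE)
  alnFiles <- sort(list.files(aDir, pattern = "\\.fasta$", full.names = TRUE))
  paths <- character(0)
  for (f in alnFiles) {
    id <- sub("\\.fasta$", "", basename(f))
    aln <- new("ClusterAlignment", clusterId = id,
               aln = readAlignmentFile(f, "fasta"))
    for (mode in config$trimModes) {
      out <- trimAlignment(aln, mode)
      p <- file.path(tDir, paste0(id, ".", mode, ".fasta"))
      writeAlignmentFile(out, p, "fasta")
      paths <- c(paths, p)
    }
  }
  .appendLog(config$outputDir, "trim: ", length(alnFiles), " clusters x ",
             length(config$trimModes), " modes")
  paths
}

.loadTrimmed <- function(config, mode) {
  tDir <- file.path(config$outputDir, "trim")
  files <- sort(list.files(tDir, pattern = paste0("\\.", mode, "\\.fasta$"),
                           full.names = TRUE))
  alns <- lapply(files, function(f) {
    id <- sub(paste0("\\.", mode, "\\.fasta$"), "", basename(f))
    new("ClusterAlignment", clusterId = id,
        aln = readAlignmentFile(f, "fasta"))
  })
  minLengthFilter(alns, config$minAlignmentLength)
}

.step_concat <- function(config) {
  ps <- .loadQC(config)
  taxaOrder <- ps@genomes
  cDir <- file.path(config$outputDir, "concat")
  dir.create(cDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (mode in config$trimModes) {
    alns <- .loadTrimmed(config, mode)
    if (length(alns) == 0)
      stop("no ", mode, " alignments passed the minimum length filter (",
           config$minAlignmentLength, " columns)")
    norm <- lapply(alns, function(a)
      normalizeAlignment(aliasesToGenomes(a, ps), taxaOrder))
    sa <- concatenateAlignments(norm, taxaOrder, mode = mode)
    pf <- file.path(cDir, paste0("super_", mode, ".fasta"))
    pp <- file.path(cDir, paste0("super_", mode, ".phy"))
    pt <- file.path(cDir, paste0("partitions_", mode, ".tsv"))
    writeSuperAlignment(sa, pf, "fasta")
    writeSuperAlignment(sa, pp, "relaxed_phylip")
    writePartitionSummary(sa, pt)
    .appendLog(config$outputDir, "concat[", mode, "]: ",
               nrow(sa@partitions), " clusters, ",
               nchar(sa@matrix[1]), " columns")
    paths <- c(paths, pf, pp, pt)
  }
  paths
}

.step_models <- function(config) {
  mDir <- file.path(config$outputDir, "models")
  dir.create(mDir, recursive = TRUE, showWarnings = FALSE)
  cDir <- file.path(config$outputDir, "concat")
  paths <- character(0)
  for (mode in config$trimModes) {
    alns <- .loadTrimmed(config, mode)
    rankings <- stats::setNames(
      lapply(alns, function(a) rankModels(a)),
      vapply(alns, function(a) a@clusterId, ""))
    sm <- summarizeModels(rankings)
    pBest <- file.path(mDir, paste0("best_models_", mode, ".tsv"))
    pRank <- file.path(mDir, paste0("ranked_models_", mode, ".tsv"))
    pFreq <- file.path(mDir, paste0("model_frequency_", mode, ".tsv"))
    pOne <- file.path(mDir, paste0("one_model_", mode, ".txt"))
    write.table(sm$best, pBest, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sm$ranked, pRank, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sm$frequency, pFreq, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(as.character(sm$oneModel), pOne)
    # partition file with per-cluster models, coordinates from the concat step
    part <- read.table(file.path(cDir, paste0("partitions_", mode, ".tsv")),
                       sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    part$model <- unname(sm$assignment[part$cluster_id])
    # strip the +G/+F decorations for the RAxML file's model token
    part$model <- sub("\\+.*$", "", part$model)
    pPart <- file.path(mDir, paste0("partition_", mode, ".txt"))
    writePartitionFile(part, pPart)
    .appendLog(config$outputDir, "models[", mode, "]: one-model choice ",
               as.character(sm$oneModel))
    paths <- c(paths, pBest, pRank, pFreq, pOne, pPart)
  }
  paths
}

.step_trees <- function(config) {
  tDir <- file.path(config$outputDir, "trees")
  dir.create(tDir, recursive = TRUE, showWarnings = FALSE)
  cDir <- file.path(config$outputDir, "concat")
  jtt <- substitutionModel("JTT")
  paths <- character(0)
  for (mode in config$trimModes) {
    sa <- readSuperAlignment(
      file.path(cDir, paste0("super_", mode, ".fasta")), "fasta",
      mode = mode)
    tree <- bootstrapConsensus(sa, model = jtt,
                               replicates = config$bootstrapReplicates,
                               seed = .stepSeed(config, "trees"),
                               outgroup = config$outgroup)
    p <- file.path(tDir, paste0("nj_consensus_", mode, ".nwk"))
    writeNewickTree(tree, p)
    paths <- c(paths, p)
    if (config$keepIntermediates) {
      pr <- file.path(tDir, paste0("replicates_", mode, ".nwk"))
      ape::write.tree(structure(attr(tree, "replicateTrees"),
                                class = "multiPhylo"), file = pr)
      paths <- c(paths, pr)
    }
    .appendLog(config$outputDir, "trees[", mode, "]: consensus written")
  }
  paths
}

.runStepImpl <- function(step, config) {
  fn <- switch(step,
    qc = .step_qc, graph = .step_graph, sweep = .step_sweep,
    filter = .step_filter, align = .step_align, trim = .step_trim,
    concat = .step_concat, models = .step_models, trees = .step_trees,
    stop("unknown pipeline step: '", step, "'"))
  set.seed(.stepSeed(config, step))
  fn(config)
}

.configFromManifest <- function(manifest) {
  cfg <- manifest$config
  cfg$inflations <- as.numeric(unlist(cfg$inflations))
  cfg$trimModes <- as.character(unlist(cfg$trimModes))
  class(cfg) <- "runConfig"
  cfg
}

#' Run a single pipeline step against an output directory
#'
#' Each stage is invocable on its own, provided the expected inputs from the
#' upstream stages exist on disk; outputs are identical to the in-pipeline
#' behavior. The manifest is created or updated.
#'
#' @param step one of qc, graph, sweep, filter, align, trim, concat, models,
#'   trees.
#' @param config a [runConfig()] (or NULL to reuse the manifest's config).
#' @return invisibly, the updated manifest.
#' @export
runStep <- function(step, config = NULL) {
  if (!step %in% .PIPELINE_STEPS)
    stop("unknown pipeline step: '", step, "'; expected one of ",
         paste(.PIPELINE_STEPS, collapse = ", "))
  if (is.null(config)) stop("a runConfig is required")
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (file.exists(.manifestPath(config$outputDir)))
    readManifest(config$outputDir) else .newManifest(config)
  manifest$steps[[step]]$status <- "running"
  .writeManifest(manifest, config$outputDir)
  .appendLog(config$outputDir, "step ", step, " started")
  outputs <- tryCatch(.runStepImpl(step, config), error = function(e) {
    manifest$steps[[step]]$status <- "pending"
    .writeManifest(manifest, config$outputDir)
    .appendLog(config$outputDir, "step ", step, " FAILED: ",
               conditionMessage(e))
    stop("pipeline step '", step, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  rel <- unname(.relOut(config$outputDir, outputs))
  manifest$steps[[step]]$status <- "done"
  manifest$steps[[step]]$outputs <- as.list(rel)
  manifest$steps[[step]]$md5 <-
    as.list(unname(md5sum(file.path(config$outputDir, rel))))
  manifest$steps[[step]]$params <- .stepParams(step, config)
  .writeManifest(manifest, config$outputDir)
  .appendLog(config$outputDir, "step ", step, " done (", length(rel),
             " files)")
  invisible(manifest)
}

#' Run the full pipeline
#'
#' Executes the nine steps in order: qc, graph, sweep, filter, align, trim,
#' concat, models, trees. Every trim mode yields its own supermatrix,
#' partition file and consensus tree. All randomness derives from the config
#' seed, so a repeated run produces byte-identical products. The main log
#' records per-step progress; the manifest records per-step outputs and
#' content fingerprints for [resumePipeline()].
#'
#' @param config a [runConfig()].
#' @param upto optional last step to execute (used to emulate interruption).
#' @return invisibly, the final manifest.
#' @export
runPipeline <- function(config, upto = NULL) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- .newManifest(config)
  .writeManifest(manifest, config$outputDir)
  .appendLog(config$outputDir, "run started (seed ", config$seed, ")")
  steps <- .PIPELINE_STEPS
  if (!is.null(upto)) {
    stopifnot(upto %in% steps)
    steps <- steps[seq_len(match(upto, steps))]
  }
  for (s in steps)
    manifest <- runStep(s, config)
  if (is.null(upto)) {
    prods <- unlist(lapply(c("concat", "trees"),
                           function(s) manifest$steps[[s]]$outputs))
    .appendLog(config$outputDir, "run complete; products: ",
               paste(prods, collapse = ", "))
  }
  invisible(manifest)
}

#' Resume a disrupted run at the first uncompleted step
#'
#' Steps whose status is done and whose recorded output fingerprints still
#' match the files on disk are skipped; execution restarts at the first step
#' that is not done or whose outputs changed, and everything downstream is
#' re-run. With the same seed, the resumed run's final products are
#' byte-identical to an uninterrupted run.
#'
#' @param outputDir pipeline output directory holding a manifest.
#' @param config optional [runConfig()] overriding the recorded one.
#' @return invisibly, the final manifest.
#' @export
resumePipeline <- function(outputDir, config = NULL) {
  manifest <- readManifest(outputDir)
  if (is.null(config)) config <- .configFromManifest(manifest)
  config$outputDir <- outputDir
  firstPending <- NA_integer_
  for (i in seq_along(.PIPELINE_STEPS)) {
    s <- .PIPELINE_STEPS[i]
    st <- manifest$steps[[s]]
    ok <- identical(st$status, "done")
    if (ok && !identical(st$params, .stepParams(s, config))) {
      .appendLog(outputDir, "resume: step ", s,
                 " parameters changed; re-running from here")
      ok <- FALSE
    }
    if (ok) {
      files <- file.path(outputDir, unlist(st$outputs))
      cur <- unname(md5sum(files))
      if (length(files) == 0 ||
          !identical(cur, as.character(unlist(st$md5)))) {
        .appendLog(outputDir, "resume: step ", s,
                   " fingerprints do not match; re-running from here")
        ok <- FALSE
      }
    }
    if (!ok) { firstPending <- i; break }
  }
  if (is.na(firstPending)) {
    .appendLog(outputDir, "resume: nothing to do, run already complete")
    return(invisible(manifest))
  }
  .appendLog(outputDir, "resume: restarting at step ",
             .PIPELINE_STEPS[firstPending])
  for (s in .PIPELINE_STEPS[firstPending:length(.PIPELINE_STEPS)])
    manifest <- runStep(s, config)
  .appendLog(outputDir, "resume complete")
  invisible(manifest)
}
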
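#' Specification for a synthetic multi-genome proteome fixture
#'
#' Describes the planted orthology structure: single-copy families present in
#' every genome, lineage-restricted families present in a fraction of
#' genomes, and paralogous families with within-genome duplicates. Sequences
#' evolve from a random ancestor down a random coalescent genome tree by
#' independent site substitutions under the JTT model (no indels). The whole
#' generation process is a pure function of the seed.
#'
#' @param nGenomes number of genomes.
#' @param nSingleCopy number of clean single-copy families (all genomes).
#' @param nLineageRestricted number of families missing from some genomes.
#' @param lineageCoverage fraction(s) of genomes covered by
#'   lineage-restricted families (recycled).
#' @param nParalog number of families with within-genome duplicates.
#' @param paralogCopies copies per genome in paralogous families.
#' @param ancestorLength length of each family's ancestral protein.
#' @param treeDepth mean root-to-tip distance of the genome tree
#'   (substitutions per site).
#' @param paralogDivergence extra branch length of the within-genome
#'   duplicate (recent duplication when small).
#' @param nCorrupt corrupt FASTA entries appended to the first genome
#'   (cycling duplicate header / bad characters / empty sequence).
#' @param contamination fraction of cross-family pairs given a sub-cutoff
#'   e-value in [synthHitTable()].
#' @param seed integer seed controlling everything.
#' @return a `fixtureSpec` list.
#' @export
fixtureSpec <- function(nGenomes = 5L, nSingleCopy = 20L,
                        nLineageRestricted = 0L, lineageCoverage = 0.6,
                        nParalog = 5L, paralogCopies = 2L,
                        ancestorLength = 120L, treeDepth = 0.5,
                        paralogDivergence = 0.03, nCorrupt = 0L,
                        contamination = 0, seed = 42L) {
  spec <- list(nGenomes = as.integer(nGenomes),
               nSingleCopy = as.integer(nSingleCopy),
               nLineageRestricted = as.integer(nLineageRestricted),
               lineageCoverage = lineageCoverage,
               nParalog = as.integer(nParalog),
               paralogCopies = as.integer(paralogCopies),
               ancestorLength = as.integer(ancestorLength),
               treeDepth = treeDepth,
               paralogDivergence = paralogDivergence,
               nCorrupt = as.integer(nCorrupt),
               contamination = contamination,
               seed = as.integer(seed))
  stopifnot(spec$nGenomes >= 1, spec$ancestorLength >= 1,
            all(spec$lineageCoverage > 0), all(spec$lineageCoverage <= 1))
  class(spec) <- "fixtureSpec"
  spec
}

.sampleResidues <- function(n, freq) {
  sample(.AA_STANDARD, n, replace = TRUE, prob = freq)
}

.evolveSequence <- function(seq, t, model) {
  if (t <= 0) return(seq)
  P <- transitionMatrix(model, t)
  idx <- match(seq, .AA_STANDARD)
  vapply(idx, function(i)
    sample(.AA_STANDARD, 1L, prob = P[i, ]), "")
}

#' Generate a synthetic proteome fixture with planted orthology
#'
#' Writes one FASTA per genome (headers deliberately messy, as from mixed
#' sequencing centers) and returns the truth table mapping every protein to
#' its planted family, together with the genome tree used for evolution.
#' Aliases in the truth table anticipate [buildAliasMap()] on the written
#' files.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory for the FASTA files.
#' @return list with `paths` (named FASTA paths), `truth` (`data.frame`:
#'   `family_id`, `class`, `coverage`, `genome_id`, `alias`, `header`),
#'   `tree` (the genome [ape::phylo]) and `spec`.
#' @export
generateProteomes <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jtt <- substitutionModel("JTT")
  gids <- sprintf("genome%02d", seq_len(spec$nGenomes))
  if (spec$nGenomes >= 2) {
    tree <- ape::rcoal(spec$nGenomes, tip.label = gids)
    depth <- mean(ape::node.depth.edgelength(tree)[seq_len(spec$nGenomes)])
    tree$edge.length <- tree$edge.length / depth * spec$treeDepth
  } else {
    tree <- NULL
  }
  nFam <- spec$nSingleCopy + spec$nLineageRestricted + spec$nParalog
  famIds <- sprintf("fam%03d", seq_len(max(nFam, 1L)))[seq_len(nFam)]
  famClass <- rep(c("single_copy", "lineage_restricted", "paralogous"),
                  c(spec$nSingleCopy, spec$nLineageRestricted, spec$nParalog))
  covs <- rep_len(spec$lineageCoverage,
                  max(spec$nLineageRestricted, 1L))
  # per genome: list of (header, sequence, family) in written order
  perGenome <- stats::setNames(
    rep(list(data.frame(header = character(0), seq = character(0),
                        family = character(0), stringsAsFactors = FALSE)),
        spec$nGenomes), gids)
  truthRows <- list()
  li <- 0L
  for (f in seq_len(nFam)) {
    anc <- .sampleResidues(spec$ancestorLength, jtt@frequencies)
    tips <- if (is.null(tree)) {
      stats::setNames(list(anc), gids)
    } else {
      .evolveDownTree(anc, tree, jtt)
    }
    cls <- famClass[f]
    present <- gids
    coverage <- 1
    if (cls == "lineage_restricted") {
      li <- li + 1L
      coverage <- covs[li]
      k <- max(1L, round(coverage * spec$nGenomes))
      coverage <- k / spec$nGenomes
      present <- sort(sample(gids, k))
    }
    for (g in present) {
      nCopies <- if (cls == "paralogous") spec$paralogCopies else 1L
      base <- tips[[g]]
      for (cp in seq_len(nCopies)) {
        s <- if (cp == 1L) base
             else .evolveSequence(base, spec$paralogDivergence, jtt)
        hdr <- sprintf("%s|%s.%d len=%d %s protein", famIds[f], g, cp,
                       length(s), cls)
        perGenome[[g]] <- rbind(perGenome[[g]], data.frame(
          header = hdr, seq = paste(s, collapse = ""), family = famIds[f],
          stringsAsFactors = FALSE))
      }
    }
    truthRows[[f]] <- data.frame(family_id = famIds[f], class = cls,
                                 coverage = coverage,
                                 stringsAsFactors = FALSE)
  }
  # corrupt entries appended to the first genome (rejected by QC, so they do
  # not shift alias ordinals of the survivors)
  corrupt <- data.frame(header = character(0), seq = character(0),
                        stringsAsFactors = FALSE)
  if (spec$nCorrupt > 0) {
    g1 <- perGenome[[1]]
    kinds <- rep_len(c("duplicate_header", "non_iupac_characters",
                       "empty_sequence"), spec$nCorrupt)
    for (k in seq_len(spec$nCorrupt)) {
      corrupt <- rbind(corrupt, switch(kinds[k],
        duplicate_header = data.frame(header = g1$header[1],
          seq = "MKVLRR", stringsAsFactors = FALSE),
        non_iupac_characters = data.frame(
          header = sprintf("corrupt%d bad residues", k),
          seq = "MKV9LR", stringsAsFactors = FALSE),
        empty_sequence = data.frame(
          header = sprintf("corrupt%d empty", k),
          seq = "", stringsAsFactors = FALSE)))
    }
  }
  # write FASTA and assemble the truth table with anticipated aliases
  paths <- character(0)
  gw <- nchar(as.character(spec$nGenomes))
  pw <- nchar(as.character(max(vapply(perGenome, nrow, 0L))))
  memberRows <- list()
  for (gi in seq_along(gids)) {
    g <- gids[gi]
    tabl <- perGenome[[g]]
    p <- file.path(dir, paste0(g, ".fasta"))
    lines <- character(0)
    for (r in seq_len(nrow(tabl)))
      lines <- c(lines, paste0(">", tabl$header[r]), tabl$seq[r])
    if (gi == 1L && nrow(corrupt) > 0)
      for (r in seq_len(nrow(corrupt)))
        lines <- c(lines, paste0(">", corrupt$header[r]), corrupt$seq[r])
    writeLines(lines, p)
    paths[g] <- p
    if (nrow(tabl) > 0)
      memberRows[[g]] <- data.frame(
        family_id = tabl$family, genome_id = g,
        alias = sprintf("g%0*d_p%0*d", gw, gi, pw, seq_len(nrow(tabl))),
        header = tabl$header, stringsAsFactors = FALSE)
  }
  if (length(memberRows) == 0 || nFam == 0) {
    truth <- data.frame(family_id = character(0), class = character(0),
                        coverage = numeric(0), genome_id = character(0),
                        alias = character(0), header = character(0),
                        stringsAsFactors = FALSE)
  } else {
    members <- do.call(rbind, memberRows)
    rownames(members) <- NULL
    fams <- do.call(rbind, truthRows)
    truth <- merge(members, fams, by = "family_id", sort = FALSE)
    truth <- truth[order(truth$family_id, truth$alias), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(paths = paths, truth = truth, tree = tree, spec = spec)
}

# evolve a residue vector down a genome tree; returns tip sequences by label
.evolveDownTree <- function(anc, tree, model) {
  tr <- reorder(tree, "cladewise")   # root-to-tip edge order
  nTip <- length(tr$tip.label)
  seqs <- vector("list", nTip + tr$Nnode)
  seqs[[nTip + 1L]] <- anc
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    seqs[[ch]] <- .evolveSequence(seqs[[p]], tr$edge.length[e], model)
  }
  stats::setNames(seqs[seq_len(nTip)], tr$tip.label)
}

.percentIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  100 * sum(x == y) / length(x)
}

# monotone identity -> e-value map: 100% identity hits the 1e-180 floor;
# identity at or below the unrelated baseline (25%) maps above the 1e-1
# cutoff
.identityToEvalue <- function(pid, baseline = 25) {
  ifelse(pid <= baseline, 1.0,
         pmax(10^(-180 * (pid - baseline) / (100 - baseline)), 1e-180))
}

#' Synthesize an all-vs-all similarity table for a fixture
#'
#' Emulates the output of an external all-vs-all protein search without
#' running one: within-family pairs (including paralogs) receive e-values
#' from a monotone decreasing function of percent identity, written in both
#' directions plus self-hits; cross-family pairs are absent except for a
#' configurable contamination fraction, which receives a sub-cutoff e-value.
#'
#' @param proteomes [ProteomeSet-class] built from the generated FASTA files
#'   (aliases assigned).
#' @param truth truth table from [generateProteomes()].
#' @param path output file (12-column BLAST tabular dialect).
#' @param spec the [fixtureSpec()] (for the contamination fraction and seed).
#' @return invisibly, the number of rows that survive parsing at the 1e-1
#'   cutoff (self-hits and super-cutoff rows excluded).
#' @export
synthHitTable <- function(proteomes, truth, path, spec) {
  set.seed(spec$seed + 1L)
  seqs <- as.character(proteomes@proteins)
  rows <- character(0)
  surviving <- 0L
  emit <- function(q, s, pid, ev, L) {
    mism <- round(L * (100 - pid) / 100)
    bits <- round(pid * 5, 1)
    sprintf("%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.3g\t%.1f",
            q, s, pid, L, mism, L, L, ev, bits)
  }
  for (fam in unique(truth$family_id)) {
    mem <- truth$alias[truth$family_id == fam]
    for (a in mem) {
      L <- nchar(seqs[[a]])
      rows <- c(rows, emit(a, a, 100, 1e-180, L))  # self-hit, dropped later
      for (b in mem) {
        if (a == b) next
        pid <- .percentIdentity(seqs[[a]], seqs[[b]])
        ev <- .identityToEvalue(pid)
        rows <- c(rows, emit(a, b, pid, ev, L))
        if (ev <= 1e-1) surviving <- surviving + 1L
      }
    }
  }
  if (spec$contamination > 0) {
    aliases <- truth$alias
    fams <- truth$family_id
    nPairs <- ceiling(spec$contamination * length(aliases))
    for (k in seq_len(nPairs)) {
      ij <- sample.int(length(aliases), 2L)
      if (fams[ij[1]] == fams[ij[2]]) next
      a <- aliases[ij[1]]; b <- aliases[ij[2]]
      L <- nchar(seqs[[a]])
      rows <- c(rows, emit(a, b, 40, 1e-5, L), emit(b, a, 40, 1e-5, L))
      surviving <- surviving + 2L
    }
  }
  writeLines(rows, path)
  invisible(surviving)
}
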
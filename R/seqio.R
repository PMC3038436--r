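#' @importFrom Biostrings readBStringSet AAStringSet BStringSet writeXStringSet
#' @importFrom utils read.table write.table
NULL

.sanitizeGenomeId <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Read one proteome FASTA with quality control
#'
#' Entries are screened in file order. An entry is rejected when its header
#' duplicates an earlier entry's header (the first occurrence is kept), when
#' its sequence is empty, or when it contains characters outside the accepted
#' amino-acid alphabet (the 20 standard residues plus `B`, `Z`, `X`, `U`, `J`,
#' `O`; a single terminal `*` is tolerated and stripped). Lowercase residues
#' are uppercased before the check.
#'
#' @param path FASTA file of predicted protein sequences.
#' @param genomeId genome identifier used in the rejection report.
#' @return list with `records` (`data.frame` of `header`, `residues`) and
#'   `rejected` (`data.frame` of `genome_id`, `header`, `reason`).
#' @export
readFastaQC <- function(path, genomeId) {
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path)
  seqs <- readBStringSet(path)
  headers <- names(seqs)
  residues <- toupper(as.character(seqs))
  keepHeader <- character(0)
  recH <- recS <- character(0)
  rejH <- rejR <- character(0)
  okChars <- paste0("^[", paste(.AA_EXTENDED, collapse = ""), "]*$")
  for (i in seq_along(headers)) {
    h <- headers[i]
    s <- residues[i]
    if (h %in% keepHeader) {
      rejH <- c(rejH, h); rejR <- c(rejR, "duplicate_header")
      next
    }
    keepHeader <- c(keepHeader, h)
    s <- sub("\\*$", "", s)
    if (!nzchar(s)) {
      rejH <- c(rejH, h); rejR <- c(rejR, "empty_sequence")
      next
    }
    if (!grepl(okChars, s)) {
      rejH <- c(rejH, h); rejR <- c(rejR, "non_iupac_characters")
      next
    }
    recH <- c(recH, h); recS <- c(recS, s)
  }
  if (length(recH) == 0)
    stop("no sequences survived QC for genome '", genomeId, "'")
  list(
    records = data.frame(header = recH, residues = recS,
                         stringsAsFactors = FALSE),
    rejected = data.frame(genome_id = rep(genomeId, length(rejH)),
                          header = rejH, reason = rejR,
                          stringsAsFactors = FALSE))
}

#' Read a set of proteome FASTA files into a ProteomeSet
#'
#' Applies [readFastaQC()] per genome. Genome identifiers are sanitized to
#' alphanumerics and underscores so they are safe in PHYLIP and Newick output.
#' Aliases are not assigned yet; call [buildAliasMap()] next.
#'
#' @param paths character vector of FASTA paths.
#' @param genomeIds genome identifiers, defaulting to `names(paths)` or the
#'   file base names.
#' @return a [ProteomeSet-class].
#' @export
readProteomes <- function(paths, genomeIds = NULL) {
  if (is.null(genomeIds))
    genomeIds <- if (!is.null(names(paths))) names(paths) else
      sub("\\.(fa|fasta|faa)(\\.gz)?$", "", basename(paths))
  genomeIds <- .sanitizeGenomeId(genomeIds)
  if (anyDuplicated(genomeIds))
    stop("genome identifiers must be unique after sanitization")
  recs <- vector("list", length(paths))
  qcs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    r <- readFastaQC(paths[i], genomeIds[i])
    recs[[i]] <- r$records
    qcs[[i]] <- r$rejected
  }
  headers <- unlist(lapply(recs, `[[`, "header"), use.names = FALSE)
  residues <- unlist(lapply(recs, `[[`, "residues"), use.names = FALSE)
  gids <- rep(genomeIds, vapply(recs, nrow, 1L))
  prov <- paste(gids, headers, sep = "|")
  prot <- AAStringSet(residues)
  names(prot) <- prov
  new("ProteomeSet",
      genomes = genomeIds,
      proteins = prot,
      aliasMap = DataFrame(alias = prov, genome_id = gids,
                           original_header = headers),
      qcReport = do.call(rbind, c(qcs, list(
        data.frame(genome_id = character(0), header = character(0),
                   reason = character(0), stringsAsFactors = FALSE)))))
}

#' Assign short unique aliases to every protein
#'
#' Aliases have the form `g<G>_p<N>` where `G` is the 1-based genome ordinal
#' and `N` the 1-based per-genome sequence ordinal, both zero-padded to a
#' fixed width so lexicographic and numeric orders coincide. The original
#' headers remain recoverable exactly through the alias map.
#'
#' @param proteomes a [ProteomeSet-class] from [readProteomes()].
#' @return the ProteomeSet with aliases assigned.
#' @export
buildAliasMap <- function(proteomes) {
  am <- proteomes@aliasMap
  gidx <- match(am$genome_id, proteomes@genomes)
  pidx <- integer(nrow(am))
  for (g in seq_along(proteomes@genomes))
    pidx[gidx == g] <- seq_len(sum(gidx == g))
  gw <- nchar(as.character(length(proteomes@genomes)))
  pw <- nchar(as.character(max(pidx)))
  alias <- sprintf("g%0*d_p%0*d", gw, gidx, pw, pidx)
  am$alias <- alias
  names(proteomes@proteins) <- alias
  proteomes@aliasMap <- am
  validObject(proteomes)
  proteomes
}

#' Does the ProteomeSet carry assigned aliases?
#' @param proteomes a [ProteomeSet-class].
#' @return logical.
#' @export
hasAliases <- function(proteomes) {
  nrow(proteomes@aliasMap) > 0 &&
    all(grepl("^g[0-9]+_p[0-9]+$", proteomes@aliasMap$alias))
}

#' Translate aliases to original headers and back
#'
#' @param proteomes a [ProteomeSet-class] with aliases assigned.
#' @param alias character vector of aliases.
#' @return `aliasToHeader`: the original headers; `aliasToGenome`: the genome
#'   identifiers; `headerToAlias`: the aliases for headers of one genome.
#' @export
aliasToHeader <- function(proteomes, alias) {
  i <- match(alias, proteomes@aliasMap$alias)
  if (anyNA(i)) stop("unknown alias: ", paste(alias[is.na(i)], collapse = ", "))
  proteomes@aliasMap$original_header[i]
}

#' @rdname aliasToHeader
#' @export
aliasToGenome <- function(proteomes, alias) {
  i <- match(alias, proteomes@aliasMap$alias)
  if (anyNA(i)) stop("unknown alias: ", paste(alias[is.na(i)], collapse = ", "))
  proteomes@aliasMap$genome_id[i]
}

#' @rdname aliasToHeader
#' @param genomeId genome the headers belong to.
#' @param header character vector of original headers.
#' @export
headerToAlias <- function(proteomes, genomeId, header) {
  am <- proteomes@aliasMap
  i <- match(paste(genomeId, header, sep = "\r"),
             paste(am$genome_id, am$original_header, sep = "\r"))
  if (anyNA(i)) stop("unknown header for genome ", genomeId)
  am$alias[i]
}

#' Write and read the alias map and QC report as TSV
#'
#' @param proteomes a [ProteomeSet-class].
#' @param path output file.
#' @export
writeAliasMap <- function(proteomes, path) {
  write.table(as.data.frame(proteomes@aliasMap), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAliasMap
#' @export
readAliasMap <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

#' @rdname writeAliasMap
#' @export
writeQCReport <- function(proteomes, path) {
  write.table(proteomes@qcReport, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write the QC-surviving sequences of each genome as aliased FASTA
#'
#' @param proteomes a [ProteomeSet-class] with aliases.
#' @param dir output directory; one `<genome>.fasta` per genome.
#' @return the written paths, named by genome.
#' @export
writeProteomeFasta <- function(proteomes, dir) {
  stopifnot(hasAliases(proteomes))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (g in proteomes@genomes) {
    sel <- proteomes@aliasMap$genome_id == g
    p <- file.path(dir, paste0(g, ".fasta"))
    writeXStringSet(proteomes@proteins[sel], p, width = 70L)
    paths[g] <- p
  }
  invisible(paths)
}

#' Reload a ProteomeSet from aliased FASTA files plus an alias-map TSV
#'
#' Inverse of [writeProteomeFasta()] + [writeAliasMap()]; used by pipeline
#' steps that restart from on-disk intermediates.
#'
#' @param fastaPaths named character vector (names = genome ids).
#' @param aliasMapPath alias map TSV.
#' @param qcReportPath optional QC report TSV.
#' @return a [ProteomeSet-class].
#' @export
loadAliasedProteomes <- function(fastaPaths, aliasMapPath,
                                 qcReportPath = NULL) {
  am <- readAliasMap(aliasMapPath)
  seqs <- lapply(fastaPaths, readBStringSet)
  prot <- AAStringSet(unlist(lapply(seqs, as.character), use.names = TRUE))
  names(prot) <- unlist(lapply(seqs, names), use.names = FALSE)
  i <- match(am$alias, names(prot))
  if (anyNA(i)) stop("alias map does not match FASTA contents")
  qc <- if (!is.null(qcReportPath) && file.exists(qcReportPath)) {
    q <- read.table(qcReportPath, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
    if (nrow(q)) q else data.frame(genome_id = character(0),
                                   header = character(0),
                                   reason = character(0))
  } else data.frame(genome_id = character(0), header = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  new("ProteomeSet", genomes = names(fastaPaths), proteins = prot[i],
      aliasMap = DataFrame(alias = am$alias, genome_id = am$genome_id,
                           original_header = am$original_header),
      qcReport = qc)
}

.asAlignmentMatrix <- function(aln) {
  if (is(aln, "ClusterAlignment"))
    return(aln@aln)
  if (is.matrix(aln))
    return(aln)
  if (is.character(aln)) {
    if (is.null(names(aln))) stop("alignment rows must be named")
    if (length(unique(nchar(aln))) > 1)
      stop("ragged alignment rows")
    m <- do.call(rbind, lapply(aln, function(s) strsplit(s, "")[[1]]))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("unsupported alignment representation")
}

.alignmentStrings <- function(m) {
  if (ncol(m) == 0) {
    out <- rep("", nrow(m))
  } else {
    out <- apply(m, 1, paste, collapse = "")
  }
  names(out) <- rownames(m)
  out
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' Relaxed PHYLIP means whitespace-delimited names of unrestricted length on
#' a `ntax nchar` header line. Both writers round-trip exactly through
#' [readAlignmentFile()].
#'
#' @param aln a [ClusterAlignment-class], character matrix with rownames, or
#'   named character vector of equal-length rows.
#' @param path output file.
#' @param format `"fasta"` or `"relaxed_phylip"`.
#' @export
writeAlignmentFile <- function(aln, path,
                               format = c("fasta", "relaxed_phylip")) {
  format <- match.arg(format)
  m <- .asAlignmentMatrix(aln)
  if (anyDuplicated(rownames(m))) stop("alignment row names must be unique")
  rows <- .alignmentStrings(m)
  if (format == "fasta") {
    x <- BStringSet(rows)
    writeXStringSet(x, path, width = 70L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(" %d %d", nrow(m), ncol(m)), con)
    nm <- format(names(rows), width = max(nchar(names(rows))))
    writeLines(paste0(nm, "  ", rows), con)
  }
  invisible(path)
}

#' Read an alignment written by [writeAlignmentFile()]
#'
#' @param path input file.
#' @param format `"fasta"` or `"relaxed_phylip"`.
#' @return character matrix with rownames.
#' @export
readAlignmentFile <- function(path, format = c("fasta", "relaxed_phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- readBStringSet(path)
    rows <- as.character(x)
  } else {
    lines <- readLines(path)
    hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
    body <- lines[-1][nzchar(trimws(lines[-1]))]
    if (length(body) != hdr[1]) stop("PHYLIP row count mismatch in ", path)
    parts <- regmatches(body, regexpr("^\\S+", body))
    rows <- trimws(sub("^\\S+\\s+", "", body))
    names(rows) <- parts
    if (any(nchar(rows) != hdr[2])) stop("PHYLIP column count mismatch in ", path)
  }
  .asAlignmentMatrix(rows)
}
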
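#' Accessors for pipeline data objects
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("aliasMap", function(x) standardGeneric("aliasMap"))

#' @rdname accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("inflation", function(x) standardGeneric("inflation"))

#' @rdname accessors
#' @export
setGeneric("accepted", function(x) standardGeneric("accepted"))

#' @rdname accessors
#' @export
setGeneric("rejectionLog", function(x) standardGeneric("rejectionLog"))

#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setMethod("genomes", "ProteomeSet", function(x) x@genomes)

#' @rdname accessors
#' @export
setMethod("proteins", "ProteomeSet", function(x) x@proteins)

#' @rdname accessors
#' @export
setMethod("aliasMap", "ProteomeSet", function(x) x@aliasMap)

#' @rdname accessors
#' @export
setMethod("qcReport", "ProteomeSet", function(x) x@qcReport)

#' @rdname accessors
#' @export
setMethod("clusters", "Clustering", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("inflation", "Clustering", function(x) x@inflation)

#' @rdname accessors
#' @export
setMethod("accepted", "ClusterSet", function(x) x@accepted)

#' @rdname accessors
#' @export
setMethod("rejectionLog", "ClusterSet", function(x) x@rejectionLog)

#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "ClusterAlignment", function(x) x@aln)

#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "SuperAlignment", function(x) {
  if (!length(x@matrix))
    return(matrix(character(0), 0, 0))
  do.call(rbind, lapply(x@matrix, function(s) strsplit(s, "")[[1]]))
})

#' @rdname accessors
#' @export
setMethod("partitions", "SuperAlignment", function(x) x@partitions)

#' @rdname accessors
#' @export
setMethod("taxa", "SuperAlignment", function(x) x@taxa)
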
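#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname accessors
#' @export
setGeneric("geneClass", function(x) standardGeneric("geneClass"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("pvals", function(x) standardGeneric("pvals"))

#' @rdname accessors
#' @export
setGeneric("alphaCutoff", function(x) standardGeneric("alphaCutoff"))

#' @rdname accessors
#' @export
setGeneric("backgroundCells", function(x) standardGeneric("backgroundCells"))

#' @rdname accessors
#' @export
setGeneric("latent", function(x) standardGeneric("latent"))

#' @rdname accessors
#' @export
setGeneric("neighborIndex", function(x) standardGeneric("neighborIndex"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' Accessors for antennaSeq classes
#'
#' Slot accessors: per-cell genotype and library id and per-gene class for
#' \linkS4class{AntennalExperiment}; call/p-value matrices, cutoff and
#' background set for \linkS4class{ReceptorCalls}; latent coordinates,
#' neighbor index matrix and cluster ids for \linkS4class{CellEmbedding}.
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("genotype", "AntennalExperiment",
          function(x) colData(x)$genotype)

#' @rdname accessors
#' @export
setMethod("libraryId", "AntennalExperiment",
          function(x) colData(x)$library_id)

#' @rdname accessors
#' @export
setMethod("geneClass", "AntennalExperiment",
          function(x) stats::setNames(rowData(x)$gene_class, rowData(x)$gene_id))

#' @rdname accessors
#' @export
setMethod("calls", "ReceptorCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("pvals", "ReceptorCalls", function(x) x@pvals)

#' @rdname accessors
#' @export
setMethod("alphaCutoff", "ReceptorCalls", function(x) x@alpha)

#' @rdname accessors
#' @export
setMethod("backgroundCells", "ReceptorCalls", function(x) x@background)

#' @rdname accessors
#' @export
setMethod("latent", "CellEmbedding", function(x) x@latent)

#' @rdname accessors
#' @export
setMethod("neighborIndex", "CellEmbedding", function(x) x@neighbors)

#' @rdname accessors
#' @export
setMethod("clusterIds", "CellEmbedding", function(x) x@clusters)
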
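#' Accessors for pollenTau classes
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x, ...) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setGeneric("sampleTable", function(x, ...) standardGeneric("sampleTable"))

#' @rdname accessors
#' @export
setGeneric("tissueMeans", function(x, ...) standardGeneric("tissueMeans"))

#' @rdname accessors
#' @export
setGeneric("replicateMeans", function(x, ...) standardGeneric("replicateMeans"))

#' @describeIn accessors exonic gene lengths (bp) of a TissueCounts.
#' @export
setMethod("geneLengths", "TissueCounts", function(x, ...) {
  stats::setNames(SummarizedExperiment::rowData(x)$gene_length, rownames(x))
})

#' @describeIn accessors the sample design as a data.frame.
#' @export
setMethod("sampleTable", "SummarizedExperiment", function(x, ...) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @describeIn accessors genes x tissue matrix of mean TPM for one species.
#' @param species species label ("SL" or "SP"); if missing, the named list
#'   over all species is returned.
#' @export
setMethod("tissueMeans", "TpmProfileSet", function(x, species, ...) {
  if (missing(species)) return(x@tissueMeans)
  .assertThat(species %in% x@species,
              paste0("no profiles for species '", species, "'"))
  x@tissueMeans[[species]]
})

#' @describeIn accessors per-replicate mean TPM matrices for one species.
#' @param tissue optional tissue name to extract a single matrix.
#' @export
setMethod("replicateMeans", "TpmProfileSet", function(x, species, tissue, ...) {
  if (missing(species)) return(x@replicateMeans)
  .assertThat(species %in% x@species,
              paste0("no profiles for species '", species, "'"))
  if (missing(tissue)) return(x@replicateMeans[[species]])
  x@replicateMeans[[species]][[tissue]]
})

#' @rdname accessors
#' @export
setGeneric("profileSpecies", function(x) standardGeneric("profileSpecies"))

#' @describeIn accessors species labels present in a TpmProfileSet.
#' @export
setMethod("profileSpecies", "TpmProfileSet", function(x) x@species)

#' @rdname accessors
#' @export
setGeneric("profileGenes", function(x) standardGeneric("profileGenes"))

#' @describeIn accessors gene identifiers of a TpmProfileSet.
#' @export
setMethod("profileGenes", "TpmProfileSet", function(x) x@geneIds)
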
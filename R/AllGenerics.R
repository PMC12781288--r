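#' Accessor generics
#'
#' Small family of accessor generics shared by the volume and map classes:
#' \code{voxelGrid} returns the \linkS4class{VolumeGrid} of an object,
#' \code{volData} its data array, \code{nVoxels} the number of in-mask (or
#' nonzero) voxels, and \code{volKind} the semantic kind tag of a
#' \linkS4class{ScalarVolume}.
#'
#' @param x an object
#' @return \code{voxelGrid}: a \linkS4class{VolumeGrid}; \code{volData}: an
#'   array; \code{nVoxels}: an integer; \code{volKind}: a character scalar.
#' @name accessors
#' @aliases voxelGrid volData nVoxels volKind
#' @examples
#' g <- VolumeGrid(c(4L, 4L, 4L), diag(4))
#' m <- BrainMask(g, array(TRUE, c(4, 4, 4)))
#' nVoxels(m)
NULL

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("volKind", function(x) standardGeneric("volKind"))
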
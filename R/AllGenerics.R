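#' @rdname MatureTRNASet-accessors
#' @export
setGeneric("trnaIds", function(x) standardGeneric("trnaIds"))

#' @rdname MatureTRNASet-accessors
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))

#' @rdname MatureTRNASet-accessors
#' @export
setGeneric("trailerSeqs", function(x) standardGeneric("trailerSeqs"))

#' @rdname MatureTRNASet-accessors
#' @export
setGeneric("frameSeqs", function(x) standardGeneric("frameSeqs"))

#' @rdname MatureTRNASet-accessors
#' @export
setGeneric("matureLengths", function(x) standardGeneric("matureLengths"))

#' @rdname MatureTRNASet-accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' Accessors for MatureTRNASet
#'
#' \code{trnaIds} returns the tRNA identifiers; \code{matureSeqs} the spliced
#' mature sequences (ending in CCA); \code{trailerSeqs} the 50-nt genomic
#' trailers; \code{frameSeqs} the searchable frames (mature + trailer);
#' \code{matureLengths} the mature lengths M (so frames have width M + 50);
#' \code{landmarks} the cloverleaf landmark table.
#'
#' @param x a \linkS4class{MatureTRNASet}.
#' @name MatureTRNASet-accessors
#' @rdname MatureTRNASet-accessors
NULL

#' @rdname MatureTRNASet-accessors
setMethod("trnaIds", "MatureTRNASet", function(x) x@ids)

#' @rdname MatureTRNASet-accessors
setMethod("matureSeqs", "MatureTRNASet", function(x) x@mature)

#' @rdname MatureTRNASet-accessors
setMethod("trailerSeqs", "MatureTRNASet", function(x) x@trailer)

#' @rdname MatureTRNASet-accessors
setMethod("frameSeqs", "MatureTRNASet", function(x) {
  out <- Biostrings::xscat(x@mature, x@trailer)
  names(out) <- x@ids
  out
})

#' @rdname MatureTRNASet-accessors
setMethod("matureLengths", "MatureTRNASet", function(x)
  setNames(Biostrings::width(x@mature), x@ids))

#' @rdname MatureTRNASet-accessors
setMethod("landmarks", "MatureTRNASet", function(x) {
  out <- x@landmarks
  rownames(out) <- x@ids
  out
})
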
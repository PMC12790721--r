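#' The six positional tRF classes
#'
#' Fragment classes recognised by the positional classifier: 5' fragments
#' (TRF5), 3' CCA-anchored fragments (TRF3), 3' trailer fragments of the
#' precursor (TRF1), internal fragments (ITRF), and the two anticodon-cleavage
#' halves (HALF5, HALF3). Placements matching no rule are UNCLASSIFIED.
#'
#' @export
TRF_CLASSES <- c("TRF5", "TRF3", "TRF1", "ITRF", "HALF5", "HALF3")

LANDMARK_COLS <- c("acceptor_start", "acceptor_end", "dloop_start", "dloop_end",
                   "aloop_start", "aloop_end", "tloop_start", "tloop_end")

#' MatureTRNASet: the tRF search space
#'
#' Holds, for each tRNA gene, the spliced mature sequence with CCA appended,
#' the 50 genomic nucleotides immediately 3' of the gene on the sense strand
#' (the trailer), and the cloverleaf landmark intervals used for positional
#' classification. The searchable frame of a tRNA is
#' \code{mature + trailer} (positions 1..M+50, 1-based closed coordinates,
#' where M is the mature length including CCA).
#'
#' @slot ids character vector of tRNA identifiers.
#' @slot mature \link[Biostrings]{DNAStringSet} of spliced mature sequences,
#'   each ending in CCA.
#' @slot trailer \link[Biostrings]{DNAStringSet} of 50-nt genomic trailers.
#' @slot landmarks \link[S4Vectors]{DataFrame} with one row per tRNA and the
#'   integer columns \code{acceptor_start/end}, \code{dloop_start/end},
#'   \code{aloop_start/end}, \code{tloop_start/end} (1-based closed, within
#'   [1, M]); rows may be all-NA for records without assigned landmarks.
#'
#' @export
setClass("MatureTRNASet",
  representation(ids = "character",
                 mature = "DNAStringSet",
                 trailer = "DNAStringSet",
                 landmarks = "DataFrame"))

setValidity("MatureTRNASet", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (length(object@mature) != n || length(object@trailer) != n)
    msg <- c(msg, "ids, mature and trailer must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "tRNA ids must be unique")
  if (n > 0) {
    if (!all(Biostrings::width(object@trailer) == 50L))
      msg <- c(msg, "every trailer must be exactly 50 nt")
    ends <- as.character(Biostrings::subseq(object@mature,
      start = pmax(1L, Biostrings::width(object@mature) - 2L)))
    if (!all(ends == "CCA"))
      msg <- c(msg, "every mature sequence must end in CCA")
  }
  if (nrow(object@landmarks) != n)
    msg <- c(msg, "landmarks must have one row per tRNA")
  if (!all(LANDMARK_COLS %in% colnames(object@landmarks)))
    msg <- c(msg, sprintf("landmarks must contain columns: %s",
                          paste(LANDMARK_COLS, collapse = ", ")))
  if (n > 0 && all(LANDMARK_COLS %in% colnames(object@landmarks))) {
    M <- Biostrings::width(object@mature)
    lm <- object@landmarks
    have <- !is.na(lm$aloop_start)
    if (any(have)) {
      bad <- have & (lm$aloop_start > lm$aloop_end | lm$aloop_start < 1 |
                     lm$tloop_end > M | lm$acceptor_start != 1L)
      bad[is.na(bad)] <- FALSE
      if (any(bad))
        msg <- c(msg, "landmark intervals must be ordered and lie within [1, M]")
    }
  }
  if (length(msg)) msg else TRUE
})

empty_landmarks <- function(n) {
  cols <- rep(list(rep(NA_integer_, n)), length(LANDMARK_COLS))
  names(cols) <- LANDMARK_COLS
  do.call(S4Vectors::DataFrame, cols)
}

#' Construct a MatureTRNASet
#'
#' @param ids character vector of tRNA ids.
#' @param mature DNAStringSet (or character) of mature sequences ending in CCA.
#' @param trailer DNAStringSet (or character) of 50-nt trailers.
#' @param landmarks optional DataFrame of landmark columns; when NULL the
#'   landmark slots are NA until \code{\link{assignLandmarks}} is called.
#' @return a \linkS4class{MatureTRNASet}.
#' @export
MatureTRNASet <- function(ids, mature, trailer, landmarks = NULL) {
  mature <- Biostrings::DNAStringSet(norm_dna(mature))
  trailer <- Biostrings::DNAStringSet(norm_dna(trailer))
  names(mature) <- names(trailer) <- ids
  if (is.null(landmarks)) landmarks <- empty_landmarks(length(ids))
  new("MatureTRNASet", ids = as.character(ids), mature = mature,
      trailer = trailer, landmarks = landmarks)
}

setMethod("length", "MatureTRNASet", function(x) length(x@ids))

setMethod("[", "MatureTRNASet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("MatureTRNASet", ids = x@ids[i], mature = x@mature[i],
      trailer = x@trailer[i], landmarks = x@landmarks[i, , drop = FALSE])
})

setMethod("show", "MatureTRNASet", function(object) {
  n <- length(object)
  cat(sprintf("MatureTRNASet with %d tRNA%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    M <- Biostrings::width(object@mature)
    cat(sprintf("  mature lengths (incl. CCA): %d-%d nt; trailer: 50 nt\n",
                min(M), max(M)))
    cat(sprintf("  landmarks assigned: %d/%d\n",
                sum(!is.na(object@landmarks$aloop_start)), n))
  }
  invisible(object)
})
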
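#' Classify a fragment placement by position in the tRNA frame
#'
#' Assigns one of the six positional tRF classes from the fragment interval
#' (1-based closed frame coordinates), the mature length M (including CCA)
#' and the anticodon-loop interval. The rules are evaluated in fixed order,
#' first match wins:
#' \enumerate{
#'   \item start = 1 and end inside the anticodon loop: HALF5 (5' half);
#'   \item start = 1 and end < M: TRF5;
#'   \item end = M and start inside the anticodon loop: HALF3 (3' half);
#'   \item end = M and start past the anticodon loop: TRF3;
#'   \item start = M + 1 and end <= M + 50: TRF1 (trailer fragment);
#'   \item start > 1 and end < M: ITRF (internal);
#'   \item otherwise UNCLASSIFIED (junction-spanning, trailer-internal
#'     placements not starting at M + 1, and full-length start = 1, end = M).
#' }
#' Halves take precedence over tRF-5/tRF-3 because cleavage terminating in
#' the anticodon loop is the halves' defining feature.
#'
#' @param start,end fragment interval (1-based closed, on frame coordinates).
#' @param M mature length including CCA.
#' @param aloop_start,aloop_end anticodon-loop interval (1-based closed,
#'   within [1, M]); NA marks the record unclassifiable.
#' @return character vector of class labels (vectorised over the inputs).
#' @export
classifyFragment <- function(start, end, M, aloop_start, aloop_end) {
  n <- max(length(start), length(end), length(M))
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  M <- rep_len(as.integer(M), n)
  aloop_start <- rep_len(as.integer(aloop_start), n)
  aloop_end <- rep_len(as.integer(aloop_end), n)
  out <- rep("UNCLASSIFIED", n)
  ok <- !is.na(aloop_start) & !is.na(aloop_end) &
    start >= 1L & end >= start & end <= M + 50L
  r1 <- ok & start == 1L & end >= aloop_start & end <= aloop_end
  r2 <- ok & start == 1L & end < M
  r3 <- ok & end == M & start >= aloop_start & start <= aloop_end
  r4 <- ok & end == M & start > aloop_end
  r5 <- ok & start == M + 1L & end <= M + 50L
  r6 <- ok & start > 1L & end < M
  out[r6] <- "ITRF"
  out[r5] <- "TRF1"
  out[r4] <- "TRF3"
  out[r3] <- "HALF3"
  out[r2] <- "TRF5"
  out[r1] <- "HALF5"
  out
}

#' Classify a table of frame alignments
#'
#' @param alignments data.frame from \code{\link{alignToFrames}}.
#' @param reference a \linkS4class{MatureTRNASet} with landmarks assigned.
#' @return the alignment data.frame with a `class` column added.
#' @export
classifyAlignments <- function(alignments, reference) {
  idx <- match(alignments$trna_id, trnaIds(reference))
  if (anyNA(idx))
    stop("alignments refer to tRNAs absent from the reference", call. = FALSE)
  M <- unname(matureLengths(reference))[idx]
  lm <- reference@landmarks
  alignments$class <- classifyFragment(alignments$start, alignments$end, M,
                                       lm$aloop_start[idx], lm$aloop_end[idx])
  alignments
}

#' Collapse classified alignments into candidate tRFs
#'
#' One candidate tRF per distinct (tRNA, start, end) placement; read-level
#' multimap weights (1 / multimap) are preserved for quantification.
#'
#' @param alignments classified alignment data.frame (see
#'   \code{\link{classifyAlignments}}; the `class` column is added if absent).
#' @param reference a \linkS4class{MatureTRNASet}.
#' @param keep_unclassified keep placements labelled UNCLASSIFIED
#'   (default FALSE).
#' @return list with `trfs` (trf_id, trna_id, start, end, class, sequence,
#'   label) and `assignments` (read_id, trf_id, class, length, weight).
#' @export
collapseToTrfs <- function(alignments, reference, keep_unclassified = FALSE) {
  if (!"class" %in% names(alignments))
    alignments <- classifyAlignments(alignments, reference)
  if (!keep_unclassified)
    alignments <- alignments[alignments$class != "UNCLASSIFIED", , drop = FALSE]
  frames <- frameSeqs(reference)
  key <- paste0(alignments$trna_id, "@", alignments$start, "-", alignments$end)
  first <- !duplicated(key)
  trfs <- data.frame(trf_id = key[first],
                     trna_id = alignments$trna_id[first],
                     start = alignments$start[first],
                     end = alignments$end[first],
                     class = alignments$class[first],
                     stringsAsFactors = FALSE)
  trfs <- trfs[order(trfs$trna_id, trfs$start, trfs$end), , drop = FALSE]
  rownames(trfs) <- NULL
  trfs$sequence <- vapply(seq_len(nrow(trfs)), function(i)
    as.character(Biostrings::subseq(frames[[trfs$trna_id[i]]],
                                    trfs$start[i], trfs$end[i])), character(1))
  len <- nchar(trfs$sequence)
  trfs$label <- ifelse(len >= 12L & len <= 50L,
                       vapply(trfs$sequence, function(s)
                         tryCatch(licensePlate(s), error = function(e) NA_character_),
                         character(1), USE.NAMES = FALSE),
                       NA_character_)
  assignments <- data.frame(read_id = alignments$read_id,
                            trf_id = key,
                            class = alignments$class,
                            length = alignments$end - alignments$start + 1L,
                            weight = 1 / alignments$multimap,
                            stringsAsFactors = FALSE)
  list(trfs = trfs, assignments = assignments)
}

#' Fragment length distribution as percent of assigned tRF reads
#'
#' @param assignments assignment data.frame from \code{\link{collapseToTrfs}}
#'   (columns `class`, `length`, `weight`).
#' @return data.frame (length, percent); percentages over assigned
#'   (non-UNCLASSIFIED) read weight sum to 100.
#' @export
lengthDistribution <- function(assignments) {
  keep <- assignments$class != "UNCLASSIFIED"
  assignments <- assignments[keep, , drop = FALSE]
  if (nrow(assignments) == 0)
    stop("no assigned tRF reads: length distribution is empty", call. = FALSE)
  w <- tapply(assignments$weight, assignments$length, sum)
  out <- data.frame(length = as.integer(names(w)),
                    percent = 100 * as.numeric(w) / sum(w))
  out[order(out$length), , drop = FALSE]
}
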
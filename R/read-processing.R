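#' Trim a 3' sequencing adapter by exact suffix-prefix match
#'
#' If any prefix of the adapter (at least \code{min_overlap} nt) matches a
#' suffix of the read exactly, the read is truncated at the leftmost such
#' match; otherwise the read is returned unchanged.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param adapter adapter sequence (>= 5 nt).
#' @param min_overlap minimum adapter prefix length considered (default 5).
#' @return the reads data.frame with trimmed sequences.
#' @export
trimAdapter <- function(reads, adapter, min_overlap = 5L) {
  adapter <- norm_dna(adapter)
  if (nchar(adapter) < 5L) stop("adapter must be at least 5 nt", call. = FALSE)
  trim_one <- function(seq) {
    L <- nchar(seq)
    if (L < min_overlap) return(seq)
    for (i in seq_len(L - min_overlap + 1L)) {
      k <- min(L - i + 1L, nchar(adapter))
      if (substr(seq, i, i + k - 1L) == substr(adapter, 1L, k))
        return(substr(seq, 1L, i - 1L))
    }
    seq
  }
  reads$sequence <- vapply(norm_dna(reads$sequence), trim_one, character(1),
                           USE.NAMES = FALSE)
  reads
}

#' Retain reads within a length window
#'
#' Small-RNA libraries are restricted to 12-50 nt inserts before any decoy
#' alignment; shorter and longer reads are discarded and counted.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param min_len,max_len inclusive length bounds (defaults 12 and 50).
#' @return the retained reads (input order preserved), with an attribute
#'   `discarded = c(short = , long = )`.
#' @export
lengthFilter <- function(reads, min_len = 12L, max_len = 50L) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- c(short = sum(len < min_len), long = sum(len > max_len))
  out
}

# TRUE for each read that occurs as an exact substring of any decoy sequence
# (or, when rc = TRUE, of any decoy reverse complement).
match_decoy_set <- function(seqs, decoys, rc = TRUE) {
  subjects <- Biostrings::DNAStringSet(decoys)
  if (rc) subjects <- c(subjects, Biostrings::reverseComplement(subjects))
  uniq <- unique(seqs)
  hit <- vapply(uniq, function(s) {
    any(Biostrings::vcountPattern(s, subjects) > 0)
  }, logical(1))
  unname(hit[match(seqs, uniq)])
}

#' Hierarchically remove decoy-matching reads
#'
#' Reads are screened against an ordered series of decoy sequence sets
#' (default order miRNA, rRNA, piRNA); a read is removed by the first set in
#' which it occurs as an exact substring of any decoy sequence (or of its
#' reverse complement when \code{rc = TRUE}). Survivors proceed to frame
#' alignment.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param decoys ordered named list of \link[Biostrings]{DNAStringSet}
#'   (or character vectors) of decoy sequences.
#' @param rc also match decoy reverse complements (default TRUE).
#' @return list with `reads` (survivors), `removed` (named per-set counts)
#'   and `assignments` (data.frame read_id, decoy_set for removed reads).
#' @export
hierarchicalFilter <- function(reads, decoys, rc = TRUE) {
  if (is.null(names(decoys)) || any(!nzchar(names(decoys))))
    stop("decoy sets must be named", call. = FALSE)
  removed <- setNames(integer(length(decoys)), names(decoys))
  assign_set <- rep(NA_character_, nrow(reads))
  alive <- rep(TRUE, nrow(reads))
  seqs <- norm_dna(reads$sequence)
  for (nm in names(decoys)) {
    dec <- decoys[[nm]]
    if (length(dec) == 0) {
      warning("empty decoy set: ", nm)
      next
    }
    if (!any(alive)) break
    hit <- alive
    hit[alive] <- match_decoy_set(seqs[alive], dec, rc = rc)
    removed[nm] <- sum(hit)
    assign_set[hit] <- nm
    alive <- alive & !hit
  }
  out <- reads[alive, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, removed = removed,
       assignments = data.frame(read_id = reads$read_id[!alive],
                                decoy_set = assign_set[!alive],
                                stringsAsFactors = FALSE))
}

#' Place reads into the tRF search frames
#'
#' Finds every occurrence of each read in any tRNA frame (mature + trailer)
#' with at most \code{max_mismatch} mismatches (no indels). Coordinates are
#' 1-based closed on the frame (positions 1..M+50). The per-read placement
#' count is recorded as `multimap`.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param reference a \linkS4class{MatureTRNASet}.
#' @param max_mismatch maximum mismatches (0-2; default 0).
#' @return data.frame (read_id, trna_id, start, end, mismatches, multimap)
#'   with attribute `unaligned`: read ids with no placement.
#' @export
alignToFrames <- function(reads, reference, max_mismatch = 0L) {
  if (length(reference) == 0) stop("reference is empty", call. = FALSE)
  if (max_mismatch > 2L)
    stop("max_mismatch > 2 is not supported at desk scale", call. = FALSE)
  frames <- frameSeqs(reference)
  seqs <- norm_dna(reads$sequence)
  uniq <- unique(seqs)
  hit_one <- function(s) {
    pat <- Biostrings::DNAString(s)
    res <- lapply(seq_along(frames), function(fi) {
      m <- Biostrings::matchPattern(pat, frames[[fi]],
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0) return(NULL)
      mm <- if (max_mismatch == 0L) rep(0L, length(m)) else
        vapply(seq_along(m), function(k)
          Biostrings::neditStartingAt(pat, frames[[fi]],
                                      starting.at = BiocGenerics::start(m)[k]),
          integer(1))
      data.frame(trna_id = names(frames)[fi],
                 start = BiocGenerics::start(m), end = BiocGenerics::end(m),
                 mismatches = as.integer(mm), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  per_uniq <- lapply(uniq, hit_one)
  names(per_uniq) <- uniq
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    h <- per_uniq[[seqs[i]]]
    if (is.null(h)) return(NULL)
    cbind(data.frame(read_id = reads$read_id[i], stringsAsFactors = FALSE),
          h, multimap = nrow(h))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(0), trna_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), multimap = integer(0),
                      stringsAsFactors = FALSE)
  aligned_ids <- unique(out$read_id)
  attr(out, "unaligned") <- setdiff(reads$read_id, aligned_ids)
  rownames(out) <- NULL
  out
}
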
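#' Parse a tRNA gene annotation table
#'
#' Reads a BED-like tab-separated table with columns \code{contig},
#' \code{start}, \code{end} (0-based half-open on the forward strand),
#' \code{strand} (+/-), \code{gene_id}, \code{anticodon} (free text, e.g.
#' "Glu-CTC") and \code{introns}: a comma-separated list of intron intervals
#' \code{start-end} in the same genomic convention, or empty for intronless
#' genes. Intron intervals must be disjoint, sorted, and strictly inside the
#' gene interval.
#'
#' @param path path to the annotation TSV (with header).
#' @return data.frame with one row per gene and a list-column `introns`
#'   holding two-column matrices of intron intervals.
#' @export
parseAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", blank.lines.skip = FALSE)
  need <- c("contig", "start", "end", "strand", "gene_id", "anticodon", "introns")
  if (!all(need %in% names(tab)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  parse_row <- function(i) {
    line <- i + 1L  # header occupies line 1
    s <- suppressWarnings(as.integer(tab$start[i]))
    e <- suppressWarnings(as.integer(tab$end[i]))
    if (is.na(s) || is.na(e) || s >= e)
      stop(sprintf("annotation line %d: invalid gene interval", line), call. = FALSE)
    if (!tab$strand[i] %in% c("+", "-"))
      stop(sprintf("annotation line %d: unknown strand '%s'", line, tab$strand[i]),
           call. = FALSE)
    introns <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
    txt <- trimws(tab$introns[i])
    if (nzchar(txt) && !is.na(txt)) {
      parts <- strsplit(strsplit(txt, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
      iv <- t(vapply(parts, function(p) suppressWarnings(as.integer(p)), integer(2)))
      colnames(iv) <- c("start", "end")
      if (anyNA(iv) || any(iv[, 1] >= iv[, 2]))
        stop(sprintf("annotation line %d: malformed intron interval", line),
             call. = FALSE)
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[, 1] <= s) || any(iv[, 2] >= e))
        stop(sprintf("annotation line %d: intron not strictly inside gene", line),
             call. = FALSE)
      if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop(sprintf("annotation line %d: overlapping intron intervals", line),
             call. = FALSE)
      introns <- iv
    }
    list(start = s, end = e, introns = introns)
  }
  parsed <- lapply(seq_len(nrow(tab)), parse_row)
  data.frame(contig = tab$contig,
             start = vapply(parsed, `[[`, integer(1), "start"),
             end = vapply(parsed, `[[`, integer(1), "end"),
             strand = tab$strand,
             gene_id = tab$gene_id,
             anticodon = tab$anticodon,
             introns = I(lapply(parsed, `[[`, "introns")),
             stringsAsFactors = FALSE)
}

#' Write a tRNA gene annotation table
#'
#' Inverse of \code{\link{parseAnnotations}}.
#'
#' @param annotations annotation data.frame (see \code{\link{parseAnnotations}}).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  introns <- vapply(annotations$introns, function(iv) {
    if (nrow(iv) == 0) "" else
      paste(sprintf("%d-%d", iv[, 1], iv[, 2]), collapse = ",")
  }, character(1))
  out <- data.frame(contig = annotations$contig, start = annotations$start,
                    end = annotations$end, strand = annotations$strand,
                    gene_id = annotations$gene_id,
                    anticodon = annotations$anticodon,
                    introns = introns, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Splice one gene out of the genome: remove introns, orient to the sense
# strand, append CCA; extract the 50-nt sense-strand trailer.
build_one_mature <- function(ann, genome, max_ambiguous = 0.1) {
  contig <- genome[[ann$contig]]
  clen <- length(contig)
  if (ann$start < 0 || ann$end > clen)
    stop(sprintf("reference error for gene %s: gene interval outside contig",
                 ann$gene_id), call. = FALSE)
  gene_fwd <- as.character(Biostrings::subseq(contig, ann$start + 1L, ann$end))
  # splice introns (forward-strand coordinates)
  iv <- ann$introns[[1]]
  if (nrow(iv) > 0) {
    keep <- rep(TRUE, nchar(gene_fwd))
    for (k in seq_len(nrow(iv))) {
      keep[(iv[k, 1] - ann$start + 1L):(iv[k, 2] - ann$start)] <- FALSE
    }
    gene_fwd <- paste(strsplit(gene_fwd, "")[[1]][keep], collapse = "")
  }
  sense <- if (ann$strand == "+") gene_fwd else revcomp(gene_fwd)
  # 50 genomic nt immediately 3' of the gene on the sense strand
  if (ann$strand == "+") {
    if (ann$end + 50L > clen)
      stop(sprintf("reference error for gene %s: fewer than 50 nt downstream",
                   ann$gene_id), call. = FALSE)
    trailer <- as.character(Biostrings::subseq(contig, ann$end + 1L, ann$end + 50L))
  } else {
    if (ann$start - 50L < 0L)
      stop(sprintf("reference error for gene %s: fewer than 50 nt downstream",
                   ann$gene_id), call. = FALSE)
    trailer <- revcomp(as.character(
      Biostrings::subseq(contig, ann$start - 49L, ann$start)))
  }
  mature <- paste0(norm_dna(sense), "CCA")
  frac_amb <- 1 - mean(strsplit(paste0(mature, trailer), "")[[1]] %in% DNA_BASES)
  if (frac_amb > max_ambiguous)
    warning(sprintf("gene %s: %.0f%% ambiguous bases in reference sequence",
                    ann$gene_id, 100 * frac_amb))
  list(mature = mature, trailer = norm_dna(trailer))
}

#' Build the mature-tRNA search space from a genome and annotations
#'
#' For each annotated gene: extract the gene sequence, remove intronic
#' sequence, orient to the sense strand, append CCA, and attach the 50
#' genomic nucleotides immediately 3' of the gene on the sense strand. The
#' resulting frame (mature + trailer) is the space in which tRFs are sought.
#' Cloverleaf landmarks are assigned with \code{\link{assignLandmarks}}.
#'
#' @param annotations annotation data.frame from \code{\link{parseAnnotations}}.
#' @param genome a \link[Biostrings]{DNAStringSet} (or FASTA path) of contigs.
#' @param assign_landmarks logical; assign fixed-offset cloverleaf landmarks
#'   (default TRUE).
#' @return a \linkS4class{MatureTRNASet}.
#' @export
buildMatureSet <- function(annotations, genome, assign_landmarks = TRUE) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  built <- lapply(seq_len(nrow(annotations)), function(i)
    build_one_mature(annotations[i, ], genome))
  set <- MatureTRNASet(ids = annotations$gene_id,
                       mature = vapply(built, `[[`, character(1), "mature"),
                       trailer = vapply(built, `[[`, character(1), "trailer"))
  if (assign_landmarks) set <- assignLandmarks(set)
  set
}

#' Assign cloverleaf landmarks at fixed offsets
#'
#' The class rules need the positions of the structural loops, which sequence
#' alone does not give. A fixed-offset model anchored on the canonical 76-nt
#' tRNA is used: acceptor stem = [1,7], D-loop = [14,21], anticodon loop =
#' [32,38], and the T-loop anchored to the 3' end at [M-22, M-16] so that
#' CCA-proximal geometry is preserved for non-canonical lengths (M is the
#' mature length including CCA). Records shorter than 60 nt cannot carry this
#' geometry.
#'
#' @param x a \linkS4class{MatureTRNASet}.
#' @param on_short one of "error" (default) or "flag": what to do with
#'   records of mature length < 60 nt. "flag" leaves their landmark row NA,
#'   which marks the record unclassifiable.
#' @return `x` with the landmark table filled in.
#' @export
assignLandmarks <- function(x, on_short = c("error", "flag")) {
  on_short <- match.arg(on_short)
  M <- unname(matureLengths(x))
  short <- M < 60L
  if (any(short) && on_short == "error")
    stop("landmark error: mature length < 60 nt for ",
         paste(trnaIds(x)[short], collapse = ", "), call. = FALSE)
  n <- length(x)
  lm <- S4Vectors::DataFrame(
    acceptor_start = rep(1L, n), acceptor_end = rep(7L, n),
    dloop_start = rep(14L, n), dloop_end = rep(21L, n),
    aloop_start = rep(32L, n), aloop_end = rep(38L, n),
    tloop_start = M - 22L, tloop_end = M - 16L)
  for (cn in LANDMARK_COLS) lm[[cn]][short] <- NA_integer_
  x@landmarks <- lm
  validObject(x)
  x
}

#' Write / read a built reference
#'
#' \code{writeReference} writes the frames (mature + trailer) as FASTA plus a
#' sidecar TSV holding the mature length M and the landmark columns;
#' \code{readReference} reads them back and checks integrity (frame width
#' must equal M + 50).
#'
#' @param x a \linkS4class{MatureTRNASet}.
#' @param dir output (input) directory.
#' @return \code{writeReference}: `dir` invisibly; \code{readReference}: a
#'   \linkS4class{MatureTRNASet}.
#' @export
writeReference <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(frameSeqs(x), file.path(dir, "frames.fa"))
  side <- cbind(data.frame(trna_id = trnaIds(x), M = unname(matureLengths(x))),
                as.data.frame(x@landmarks))
  write.table(side, file.path(dir, "reference.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeReference
#' @export
readReference <- function(dir) {
  fa <- file.path(dir, "frames.fa")
  side_path <- file.path(dir, "reference.tsv")
  if (!file.exists(side_path))
    stop("reference sidecar missing: ", side_path, call. = FALSE)
  frames <- Biostrings::readDNAStringSet(fa)
  names(frames) <- sub("\\s.*$", "", names(frames))
  side <- read.delim(side_path, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(sort(names(frames)), sort(side$trna_id)))
    stop("integrity error: FASTA ids and sidecar ids differ", call. = FALSE)
  frames <- frames[side$trna_id]
  if (!all(Biostrings::width(frames) == side$M + 50L))
    stop("integrity error: frame width != M + 50 for ",
         paste(side$trna_id[Biostrings::width(frames) != side$M + 50L],
               collapse = ", "), call. = FALSE)
  lm_cols <- lapply(LANDMARK_COLS, function(cn) as.integer(side[[cn]]))
  names(lm_cols) <- LANDMARK_COLS
  MatureTRNASet(ids = side$trna_id,
                mature = Biostrings::subseq(frames, 1L, side$M),
                trailer = Biostrings::subseq(frames, side$M + 1L),
                landmarks = do.call(S4Vectors::DataFrame, lm_cols))
}
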
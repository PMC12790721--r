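#' @importFrom methods new validObject is setClass setValidity setMethod setGeneric show
#' @importFrom stats p.adjust rnbinom rnorm runif median model.matrix
#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Normalize a character/Biostrings sequence to the DNA alphabet (U -> T).
norm_dna <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(norm_dna(x))))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Write reads to a FASTQ file with constant qualities
#'
#' Base qualities carry no information for synthetic reads, so every base is
#' written as 'I' (Phred 40).
#'
#' @param reads data.frame with columns `read_id` and `sequence`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  qual <- vapply(nchar(reads$sequence), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read small-RNA reads from a FASTQ file
#'
#' @param path FASTQ path.
#' @return data.frame with columns `read_id` and `sequence` (DNA alphabet).
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
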
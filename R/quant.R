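#' Build a tRF x sample count matrix
#'
#' Sums per-read weights (1 / multimap under the fractional multimap policy)
#' into a tRF-by-sample matrix over the time-course design. tRFs absent from
#' a sample get count 0.
#'
#' @param assignment_tables named list (by sample id) of assignment
#'   data.frames from \code{\link{collapseToTrfs}}.
#' @param manifest data.frame with columns `sample_id`, `day`
#'   (in \{0, 7, 14, 21\}) and `replicate`.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   `counts`, colData `day` and `replicate`, and per-sample library sizes
#'   (column sums) in `colData(x)$lib_size`.
#' @export
buildCountMatrix <- function(assignment_tables, manifest) {
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample ids in manifest", call. = FALSE)
  if (!all(manifest$sample_id %in% names(assignment_tables)))
    stop("every manifest sample needs an assignment table", call. = FALSE)
  trf_ids <- sort(unique(unlist(lapply(assignment_tables, `[[`, "trf_id"))))
  counts <- matrix(0, nrow = length(trf_ids), ncol = nrow(manifest),
                   dimnames = list(trf_ids, manifest$sample_id))
  for (sid in manifest$sample_id) {
    at <- assignment_tables[[sid]]
    if (nrow(at) == 0) next
    w <- tapply(at$weight, at$trf_id, sum)
    counts[names(w), sid] <- as.numeric(w)
  }
  cd <- S4Vectors::DataFrame(day = as.integer(manifest$day),
                             replicate = as.integer(manifest$replicate),
                             lib_size = colSums(counts),
                             row.names = manifest$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
}

get_counts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Counts-per-million normalization
#'
#' Scales each sample to counts per million tRF-mapped reads, so every
#' column sums to 1e6. Used for reporting; the differential-expression test
#' uses composition-robust median-of-ratios library sizes internally (see
#' \code{\link{deTest}}).
#'
#' @param x a SummarizedExperiment with a `counts` assay, or a matrix.
#' @return a matrix of CPM values with the same dimnames.
#' @export
cpmNormalize <- function(x) {
  counts <- get_counts(x)
  libs <- colSums(counts)
  if (any(libs <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs <= 0], collapse = ", "), call. = FALSE)
  t(t(counts) / libs) * 1e6
}

# DESeq-style median-of-ratios size factors (the normalization EBSeq's
# MedianNorm uses), scaled to effective library sizes on the scale of the
# observed column sums. Robust to a minority of strongly-changing features,
# which plain column-sum scaling is not. Falls back to column sums when no
# feature is expressed everywhere.
effective_lib_sizes <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (sum(ok) >= 10) {
    s <- apply(counts, 2, function(x) median(exp(log(x[ok]) - lg[ok])))
  } else {
    s <- colSums(counts)
  }
  if (any(!is.finite(s) | s <= 0)) s <- colSums(counts)
  s / exp(mean(log(s))) * mean(colSums(counts))
}
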
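#' Differential expression test between two time points
#'
#' Tests each tRF for a count difference between two days of the time course
#' with a negative-binomial quasi-likelihood F-test (edgeR's
#' \code{glmQLFit}/\code{glmQLFTest}), using DESeq-style median-of-ratios
#' effective library sizes (the normalization EBSeq's MedianNorm performs).
#' The fold change is reported as
#' \code{log2FC = log2((mean CPM_b + 0.5) / (mean CPM_a + 0.5))}, with CPM on
#' the median-of-ratios effective libraries and a 0.5-CPM pseudocount, and
#' FDR is Benjamini-Hochberg across all tRFs in the comparison. A tRF is
#' significant iff |log2FC| > 1 and FDR < 0.05 (strict inequalities), i.e.
#' fold change > 2 or < 0.5 at FDR < 0.05.
#'
#' @param x a SummarizedExperiment from \code{\link{buildCountMatrix}} (or a
#'   count matrix plus `days` vector).
#' @param day_a,day_b the two days to compare (log2FC is day_b over day_a).
#' @param days optional day labels per column when `x` is a plain matrix.
#' @param lfc_threshold,fdr_threshold significance thresholds
#'   (defaults 1 and 0.05).
#' @return data.frame (trf_id, comparison, log2fc, pvalue, fdr, significant).
#' @export
deTest <- function(x, day_a, day_b, days = NULL,
                   lfc_threshold = 1, fdr_threshold = 0.05) {
  counts <- get_counts(x)
  if (is.null(days)) {
    if (!is(x, "SummarizedExperiment"))
      stop("supply `days` when x is a plain matrix", call. = FALSE)
    days <- SummarizedExperiment::colData(x)$day
  }
  ia <- which(days == day_a)
  ib <- which(days == day_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop(sprintf("day %s or %s absent from the design", day_a, day_b),
         call. = FALSE)
  if (length(ia) < 2 || length(ib) < 2)
    stop("at least 2 replicates per day are required", call. = FALSE)
  sub <- counts[, c(ia, ib), drop = FALSE]
  eff_lib <- effective_lib_sizes(sub)
  cpm <- t(t(sub) / eff_lib) * 1e6
  na <- length(ia)
  mean_a <- rowMeans(cpm[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(cpm[, na + seq_along(ib), drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))

  grp <- factor(rep(c("a", "b"), c(length(ia), length(ib))), levels = c("a", "b"))
  design <- stats::model.matrix(~grp)
  d <- edgeR::DGEList(counts = sub, lib.size = eff_lib, group = grp)
  d <- edgeR::estimateDisp(d, design)
  fit <- edgeR::glmQLFit(d, design)
  pvalue <- edgeR::glmQLFTest(fit, coef = 2)$table$PValue
  allzero <- rowSums(sub) == 0
  pvalue[allzero] <- 1
  log2fc[allzero] <- 0
  fdr <- p.adjust(pvalue, method = "BH")
  data.frame(trf_id = rownames(counts),
             comparison = paste0(day_a, "v", day_b),
             log2fc = unname(log2fc), pvalue = unname(pvalue),
             fdr = unname(fdr),
             significant = abs(log2fc) > lfc_threshold & fdr < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a four-day time course for differential tRFs and peak days
#'
#' Runs \code{\link{deTest}} for the consecutive comparisons day 0 vs 7,
#' 7 vs 14 and 14 vs 21, and assigns each tRF its peak day: the argmax over
#' days of mean normalized count (ties resolved to the earliest day and
#' flagged). The "day-7-peaking" set contains tRFs significant in 0v7 with
#' positive log2FC whose peak day is 7.
#'
#' @inheritParams deTest
#' @return list with `results` (named list of deTest data.frames), `peaks`
#'   (data.frame trf_id, peak_day, tie), `day7_ids` and `day7_fraction`.
#' @export
screenTimecourse <- function(x, days = NULL,
                             lfc_threshold = 1, fdr_threshold = 0.05) {
  counts <- get_counts(x)
  if (is.null(days)) days <- SummarizedExperiment::colData(x)$day
  want <- c(0, 7, 14, 21)
  if (!all(want %in% days))
    stop("all four days (0, 7, 14, 21) must be present", call. = FALSE)
  comparisons <- list(c(0, 7), c(7, 14), c(14, 21))
  results <- lapply(comparisons, function(cc)
    deTest(counts, cc[1], cc[2], days = days,
           lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold))
  names(results) <- vapply(comparisons, function(cc)
    paste0(cc[1], "v", cc[2]), character(1))

  eff_lib <- effective_lib_sizes(counts)
  cpm <- t(t(counts) / eff_lib) * 1e6
  day_means <- sapply(want, function(d)
    rowMeans(cpm[, days == d, drop = FALSE]))
  colnames(day_means) <- as.character(want)
  peak_idx <- apply(day_means, 1, which.max)  # ties -> earliest (first max)
  tie <- apply(day_means, 1, function(z) sum(z == max(z)) > 1)
  peaks <- data.frame(trf_id = rownames(counts),
                      peak_day = want[peak_idx], tie = unname(tie),
                      row.names = NULL, stringsAsFactors = FALSE)
  r07 <- results[["0v7"]]
  day7_ids <- r07$trf_id[r07$significant & r07$log2fc > 0 &
                           peaks$peak_day[match(r07$trf_id, peaks$trf_id)] == 7]
  list(results = results, peaks = peaks, day7_ids = day7_ids,
       day7_fraction = length(day7_ids) / nrow(counts))
}
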
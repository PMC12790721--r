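#' Simulate a tRF count time course
#'
#' Draws negative-binomial counts over the day 0/7/14/21 design (or days
#' 0/7 when \code{n_timepoints = 2}) with per-sample library-size factors
#' drawn log-normal around 1 (sdlog 0.2). A \code{peak_frac} subset of tRFs
#' has its mean multiplied by \code{2^effect_log2fc} at day 7 only; the
#' remaining tRFs share one mean across days (null).
#'
#' @param n_trfs number of tRFs to simulate.
#' @param config a \code{\link{simConfig}}.
#' @param trf_ids optional row ids (default trf_0001, ...).
#' @return list with `se` (a \link[SummarizedExperiment]{SummarizedExperiment}
#'   with assay `counts` and colData day/replicate) and `truth` (list with
#'   `planted` ids, `log2fc`: data.frame of true per-comparison log2FC, and
#'   `peak_day`).
#' @export
simulateTimecourseCounts <- function(n_trfs, config, trf_ids = NULL) {
  validateSimConfig(config)
  if (n_trfs < 1) stop("n_trfs must be >= 1", call. = FALSE)
  days <- c(0L, 7L, 14L, 21L)[seq_len(config$n_timepoints)]
  if (is.null(trf_ids)) trf_ids <- sprintf("trf_%04d", seq_len(n_trfs))
  with_seed(config$seed + 3000L, {
    day_col <- rep(days, each = config$reps)
    rep_col <- rep(seq_len(config$reps), times = length(days))
    sample_ids <- sprintf("d%d_r%d", day_col, rep_col)
    lib_factor <- exp(rnorm(length(sample_ids), 0, 0.2))
    n_planted <- round(config$peak_frac * n_trfs)
    planted <- sort(sample(n_trfs, n_planted))
    mu <- matrix(config$mean_count, n_trfs, length(sample_ids))
    if (n_planted > 0)
      mu[planted, day_col == 7L] <-
        mu[planted, day_col == 7L] * 2^config$effect_log2fc
    mu <- t(t(mu) * lib_factor)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
                     n_trfs, length(sample_ids),
                     dimnames = list(trf_ids, sample_ids))
    cd <- S4Vectors::DataFrame(day = day_col, replicate = rep_col,
                               lib_size = colSums(counts),
                               row.names = sample_ids)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), colData = cd)
    comps <- if (length(days) == 4L) c("0v7", "7v14", "14v21") else "0v7"
    true_lfc <- do.call(rbind, lapply(comps, function(cc) {
      lfc <- rep(0, n_trfs)
      if (cc == "0v7") lfc[planted] <- config$effect_log2fc
      if (cc == "7v14") lfc[planted] <- -config$effect_log2fc
      data.frame(trf_id = trf_ids, comparison = cc, true_log2fc = lfc,
                 stringsAsFactors = FALSE)
    }))
    list(se = se,
         truth = list(planted = trf_ids[planted],
                      log2fc = true_lfc,
                      peak_day = setNames(ifelse(seq_len(n_trfs) %in% planted,
                                                 7L, NA_integer_), trf_ids)))
  })
}
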
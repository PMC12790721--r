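#' Demo pipeline configuration
#'
#' A desk-scale configuration exercising every stage: 12 tRNA genes, 4,000
#' reads with 5% contaminants, a four-day count design with 10% planted
#' day-7 peaks at |log2FC| = 2, and a WT/seed-mutated UTR pair carrying the
#' reverse complement of the example tRF-23 sequence.
#'
#' @param seed integer seed propagated to every stage.
#' @return a nested configuration list for \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1L) {
  list(sim = simConfig(seed = seed, n_genes = 12L, depth = 4000L,
                       contaminant_frac = 0.05, peak_frac = 0.1),
       adapter = "AGATCGGAAGAGC",
       min_len = 12L, max_len = 50L,
       max_mismatch = 0L,
       lfc_threshold = 1, fdr_threshold = 0.05,
       scan = list(trf = TRF23_SEQUENCE, utr_len = 300L,
                   mutate_positions = c(2L, 3L, 5L, 7L),
                   min_score = 80, max_energy = -15))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full tRF discovery pipeline on synthetic inputs
#'
#' Orchestrates simulate -> build-ref -> quantify -> classify -> de -> scan
#' as one reproducible run. All randomness derives from the seed inside
#' `config$sim`, so re-running with the same configuration reproduces
#' byte-identical outputs (the report carries no timestamps).
#'
#' @param config configuration list (see \code{\link{demoConfig}}).
#' @param out_dir output directory; created if needed.
#' @return invisibly, a list with `report` (also written as
#'   \code{report.json}), `paths` of the stage outputs, and the in-memory
#'   `reference`, `trfs`, `screen` and `scan` objects.
#' @export
runPipeline <- function(config = demoConfig(), out_dir = tempfile("trfrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgfile <- file.path(out_dir, "config.json")
  strip_class <- function(x) if (is.list(x)) lapply(unclass(x), strip_class) else x
  jsonlite::write_json(strip_class(config), cfgfile,
                       auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfgfile))

  genes <- run_stage("simulate", {
    g <- simulateTrnaGenes(config$sim)
    Biostrings::writeXStringSet(g$genome, file.path(out_dir, "genome.fa"))
    writeAnnotations(g$annotations, file.path(out_dir, "annotations.tsv"))
    g
  })
  decoys <- run_stage("simulate", simulateDecoySets(config$sim))

  reference <- run_stage("build-ref", {
    ann <- parseAnnotations(file.path(out_dir, "annotations.tsv"))
    ref <- buildMatureSet(ann, file.path(out_dir, "genome.fa"))
    writeReference(ref, file.path(out_dir, "reference"))
    ref
  })

  readsim <- run_stage("simulate", {
    rs <- simulateFragmentReads(reference, config$sim, decoys)
    writeFastq(rs$reads, file.path(out_dir, "reads.fastq"))
    rs
  })

  quant <- run_stage("quantify", {
    reads <- readFastq(file.path(out_dir, "reads.fastq"))
    n_input <- nrow(reads)
    reads <- trimAdapter(reads, config$adapter)
    kept <- lengthFilter(reads, config$min_len, config$max_len)
    discarded <- attr(kept, "discarded")
    hf <- hierarchicalFilter(kept, decoys)
    aln <- alignToFrames(hf$reads, reference,
                         max_mismatch = config$max_mismatch)
    unaligned <- attr(aln, "unaligned")
    ledger <- c(input = n_input,
                removed_short = unname(discarded["short"]),
                removed_long = unname(discarded["long"]),
                setNames(as.integer(hf$removed),
                         paste0("removed_", names(hf$removed))),
                unaligned = length(unaligned),
                aligned = length(unique(aln$read_id)))
    write.table(aln, file.path(out_dir, "alignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(alignments = aln, ledger = ledger)
  })

  classified <- run_stage("classify", {
    aln <- classifyAlignments(quant$alignments, reference)
    coll <- collapseToTrfs(aln, reference)
    write.table(coll$trfs, file.path(out_dir, "trfs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    comp <- tapply(coll$assignments$weight, coll$assignments$class, sum)
    ld <- lengthDistribution(coll$assignments)
    write.table(ld, file.path(out_dir, "length_distribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(trfs = coll$trfs, assignments = coll$assignments,
         composition = comp, length_distribution = ld)
  })

  de <- run_stage("de", {
    sim <- simulateTimecourseCounts(nrow(classified$trfs), config$sim,
                                    trf_ids = classified$trfs$trf_id)
    counts <- SummarizedExperiment::assay(sim$se, "counts")
    write.table(data.frame(trf_id = rownames(counts), counts,
                           check.names = FALSE),
                file.path(out_dir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    screen <- screenTimecourse(sim$se,
                               lfc_threshold = config$lfc_threshold,
                               fdr_threshold = config$fdr_threshold)
    for (cc in names(screen$results))
      write.table(screen$results[[cc]],
                  file.path(out_dir, sprintf("de_%s.tsv", cc)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    list(screen = screen, truth = sim$truth)
  })

  scan <- run_stage("scan", {
    sc <- config$scan
    wt <- embedTargetSite(sc$utr_len, sc$trf, seed = config$sim$seed + 4000L)
    mut <- embedTargetSite(sc$utr_len, sc$trf,
                           mutate_positions = sc$mutate_positions,
                           seed = config$sim$seed + 4000L)
    cmp <- compareWtMut(sc$trf, wt$utr, mut$utr,
                        min_score = sc$min_score, max_energy = sc$max_energy)
    cmp
  })

  peak_hist <- table(de$screen$peaks$peak_day)
  report <- list(
    tool = paste0("trfscape ", as.character(utils::packageVersion("trfscape"))),
    seed = config$sim$seed,
    config_hash = config_hash,
    filter_ledger = as.list(quant$ledger),
    class_composition = as.list(round(
      100 * classified$composition / sum(classified$composition), 4)),
    length_distribution = classified$length_distribution,
    n_trfs = nrow(classified$trfs),
    de = list(
      thresholds = sprintf("|log2FC| > %g and FDR < %g",
                           config$lfc_threshold, config$fdr_threshold),
      n_significant = lapply(de$screen$results, function(r) sum(r$significant)),
      peak_day_histogram = as.list(setNames(as.integer(peak_hist),
                                            names(peak_hist))),
      day7_fraction = de$screen$day7_fraction,
      planted_fraction = length(de$truth$planted) / nrow(classified$trfs)),
    scan = list(verdict = scan$verdict, n_wt = scan$n_wt, n_mut = scan$n_mut,
                best_mfe_wt = scan$best_mfe_wt,
                best_mfe_mut = scan$best_mfe_mut))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(report = report, out_dir = out_dir, reference = reference,
                 trfs = classified$trfs, screen = de$screen, scan = scan))
}

#' Render a pipeline report as markdown
#'
#' @param report the `report` element returned by \code{\link{runPipeline}}
#'   (or read back from \code{report.json}).
#' @return a character vector of markdown lines.
#' @export
renderReport <- function(report) {
  need <- c("filter_ledger", "class_composition", "length_distribution",
            "de", "scan")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("report schema mismatch: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  ld <- as.data.frame(report$length_distribution)
  peak <- unlist(report$de$peak_day_histogram)
  modal <- names(peak)[which.max(peak)]
  lines <- c(
    "# tRF pipeline report",
    "",
    "## Read filtering",
    sprintf("- %s: %d", names(report$filter_ledger),
            unlist(report$filter_ledger)),
    "",
    "## Class composition (% of assigned read weight)",
    sprintf("- %s: %.2f%%", names(report$class_composition),
            unlist(report$class_composition)),
    "",
    "## tRF length distribution (% of total tRF reads)",
    "| length (nt) | percent |", "|---|---|",
    sprintf("| %d | %.2f |", ld$length, ld$percent),
    "",
    "## Differential expression",
    sprintf("Screen thresholds: %s.", report$de$thresholds),
    sprintf("- %s: %d significant", names(report$de$n_significant),
            unlist(report$de$n_significant)),
    sprintf("Modal peak day: day %s.", modal),
    sprintf("Day-7-peaking fraction: %.3f (planted %.3f).",
            report$de$day7_fraction, report$de$planted_fraction),
    "",
    "## Target scan",
    sprintf("WT hits: %d; MUT hits: %d; verdict: %s.",
            report$scan$n_wt, report$scan$n_mut, report$scan$verdict))
  lines
}
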
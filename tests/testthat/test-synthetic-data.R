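test_that("gene simulation honours intron probability and splice identity", {
  cfg1 <- simConfig(seed = 11, n_genes = 3, intron_prob = 1.0)
  g1 <- simulateTrnaGenes(cfg1)
  expect_true(all(vapply(g1$annotations$introns, nrow, integer(1)) == 1L))

  cfg0 <- simConfig(seed = 12, n_genes = 5, intron_prob = 0.0)
  g0 <- simulateTrnaGenes(cfg0)
  expect_true(all(vapply(g0$annotations$introns, nrow, integer(1)) == 0L))
  # without introns, the (sense-oriented) gene sequence + CCA is the mature
  for (i in seq_len(5)) {
    ann <- g0$annotations[i, ]
    fwd <- as.character(Biostrings::subseq(g0$genome[[ann$contig]],
                                           ann$start + 1L, ann$end))
    sense <- if (ann$strand == "+") fwd else rc(fwd)
    expect_identical(paste0(sense, "CCA"),
                     as.character(g0$truth$mature[[ann$gene_id]]))
  }
})

test_that("gene simulation is deterministic and mixes both strands", {
  cfg <- simConfig(seed = 13, n_genes = 30)
  a <- simulateTrnaGenes(cfg)
  b <- simulateTrnaGenes(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotations[, c("contig", "start", "end", "strand")],
                   b$annotations[, c("contig", "start", "end", "strand")])
  expect_gt(sum(a$annotations$strand == "-"), 5)
  expect_gt(sum(a$annotations$strand == "+"), 5)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simConfig(intron_prob = 1.5), "intron_prob")
  expect_error(simConfig(n_genes = 0), "n_genes")
  expect_error(simConfig(trailer_len = 40), "trailer_len")
  expect_error(simConfig(nb_dispersion = 0), "nb_dispersion")
  expect_error(simConfig(effect_log2fc = 0.5), "effect_log2fc")
  expect_error(simConfig(class_mix = c(TRF5 = 0.5, TRF3 = 0.6, TRF1 = 0,
                                       ITRF = 0, HALF5 = 0, HALF3 = 0)),
               "class_mix")
})

test_that("fragment reads stay in the configured length window", {
  cfg <- simConfig(seed = 21, n_genes = 8, depth = 10000,
                   contaminant_frac = 0)
  g <- simulateTrnaGenes(cfg)
  ref <- assignLandmarks(MatureTRNASet(names(g$truth$mature),
                                       as.character(g$truth$mature),
                                       vapply(seq_len(8), function(i)
                                         rand_seq(50), character(1))))
  rs <- simulateFragmentReads(ref, cfg)
  len <- nchar(rs$reads$sequence)
  expect_true(all(len >= 16 & len <= 35))
  expect_identical(nrow(rs$reads), 10000L)
})

test_that("every fragment read is an exact frame substring with its true class", {
  cfg <- simConfig(seed = 22, n_genes = 6, depth = 2000, contaminant_frac = 0)
  g <- simulateTrnaGenes(cfg)
  ref <- buildMatureSet(g$annotations, g$genome)
  rs <- simulateFragmentReads(ref, cfg)
  frames <- as.character(frameSeqs(ref))
  M <- matureLengths(ref)
  lm <- landmarks(ref)
  ok_sub <- ok_cls <- logical(nrow(rs$truth))
  for (i in seq_len(nrow(rs$truth))) {
    tr <- rs$truth[i, ]
    ok_sub[i] <- substr(frames[tr$trna_id], tr$start, tr$end) ==
      rs$reads$sequence[i]
    ok_cls[i] <- classifyFragment(tr$start, tr$end, M[tr$trna_id],
                                  lm[tr$trna_id, "aloop_start"],
                                  lm[tr$trna_id, "aloop_end"]) == tr$class
  }
  expect_true(all(ok_sub))
  expect_true(all(ok_cls))
})

test_that("class mix is respected and impossible classes are refused", {
  ref <- make_test_reference()
  # pure tRF-1: every read starts at the first trailer base of its source
  cfg1 <- simConfig(seed = 23, depth = 500, contaminant_frac = 0,
                    class_mix = c(TRF5 = 0, TRF3 = 0, TRF1 = 1,
                                  ITRF = 0, HALF5 = 0, HALF3 = 0))
  rs <- simulateFragmentReads(ref, cfg1)
  M <- matureLengths(ref)
  expect_true(all(rs$truth$start == M[rs$truth$trna_id] + 1L))

  # uniform six-class mix needs lengths that can reach a 3' half
  cfg6 <- simConfig(seed = 24, depth = 6000, contaminant_frac = 0,
                    frag_len_min = 16, frag_len_max = 50,
                    class_mix = setNames(rep(1 / 6, 6), TRF_CLASSES))
  rs6 <- simulateFragmentReads(ref, cfg6)
  counts <- table(factor(rs6$truth$class, levels = TRF_CLASSES))
  sd3 <- 3 * sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 1000) <= sd3))

  # 3' halves are >= 36 nt here, impossible at the default 16-35 window
  cfgbad <- simConfig(seed = 25, depth = 100, contaminant_frac = 0,
                      class_mix = c(TRF5 = 0, TRF3 = 0, TRF1 = 0,
                                    ITRF = 0, HALF5 = 0, HALF3 = 1))
  expect_error(simulateFragmentReads(ref, cfgbad), "HALF3")
})

test_that("contaminants are decoy copies or out-of-range sequences", {
  cfg <- simConfig(seed = 26, n_genes = 4, depth = 2000,
                   contaminant_frac = 0.2)
  g <- simulateTrnaGenes(cfg)
  ref <- buildMatureSet(g$annotations, g$genome)
  decoys <- simulateDecoySets(cfg)
  rs <- simulateFragmentReads(ref, cfg, decoys)
  tr <- rs$truth
  expect_identical(sum(tr$source != "trf"), 400L)
  rnd_len <- nchar(rs$reads$sequence[tr$source == "random"])
  expect_true(all(rnd_len < 12 | rnd_len > 50))
  dec_idx <- grepl("^decoy:", tr$source)
  all_dec <- Biostrings::DNAStringSet(unlist(lapply(decoys, as.character)))
  hit <- vapply(rs$reads$sequence[dec_idx], function(s)
    any(Biostrings::vcountPattern(s, all_dec) > 0), logical(1))
  expect_true(all(hit))
  # read ids are unique and truth covers every read exactly once
  expect_identical(anyDuplicated(tr$read_id), 0L)
  expect_setequal(tr$read_id, rs$reads$read_id)
})

test_that("time-course counts plant a clean day-7 effect", {
  # peak_frac = 1 with tiny dispersion: day-7 mean ~ 4x day-0 mean
  cfg <- simConfig(seed = 31, reps = 50, n_timepoints = 2, peak_frac = 1,
                   effect_log2fc = 2, mean_count = 500, nb_dispersion = 0.001)
  sim <- simulateTimecourseCounts(200, cfg)
  counts <- SummarizedExperiment::assay(sim$se, "counts")
  day <- SummarizedExperiment::colData(sim$se)$day
  ratio <- mean(counts[, day == 7]) / mean(counts[, day == 0])
  expect_lt(abs(ratio - 4) / 4, 0.1)

  # determinism
  sim2 <- simulateTimecourseCounts(200, cfg)
  expect_identical(counts, SummarizedExperiment::assay(sim2$se, "counts"))

  # zero effect is a valid null; truth still labels the planted set
  cfg0 <- simConfig(seed = 32, effect_log2fc = 0, peak_frac = 0.25)
  sim0 <- simulateTimecourseCounts(100, cfg0)
  expect_identical(length(sim0$truth$planted), 25L)
  expect_true(all(sim0$truth$log2fc$true_log2fc == 0))
})

test_that("embedded target sites behave as wild type or seed mutant", {
  trf <- "GGCGGUGAGAGCGCCGAAUCCUA"  # RNA form of the example tRF-23 sequence
  wt <- embedTargetSite(300, trf, seed = 5)
  hits <- gregexpr(rc(trf), wt$utr, fixed = TRUE)[[1]]
  expect_identical(length(hits[hits > 0]), 1L)
  expect_identical(as.integer(hits[1]), wt$site_start)
  expect_identical(substr(wt$utr, wt$site_start, wt$site_end), rc(trf))

  mut <- embedTargetSite(300, trf, mutate_positions = 2:8, seed = 5)
  seed7 <- rc(substr(gsub("U", "T", trf), 2, 8))
  expect_false(grepl(seed7, mut$utr, fixed = TRUE))
  # same seed: background identical outside the mutated positions
  diffs <- which(strsplit(wt$utr, "")[[1]] != strsplit(mut$utr, "")[[1]])
  expect_setequal(diffs, mut$mutated_utr_positions)

  expect_error(embedTargetSite(300, trf, mutate_positions = 99, seed = 1),
               "mutate_positions")
  expect_error(embedTargetSite(30, trf, seed = 1), "utr_len")
})
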
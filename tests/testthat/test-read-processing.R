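mk_reads <- function(seqs) data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                                      sequence = seqs, stringsAsFactors = FALSE)

test_that("adapter trimming truncates at the leftmost suffix-prefix match", {
  adapter <- "AGATCGGAAGAGC"
  insert <- "ACGTACGTACGTACGTACGT"
  r <- trimAdapter(mk_reads(c(paste0(insert, adapter),          # full adapter
                              insert,                           # none
                              paste0(insert, substr(adapter, 1, 5)))),  # 5 nt
                   adapter)
  expect_identical(r$sequence, c(insert, insert, insert))
  expect_error(trimAdapter(mk_reads("ACGT"), "AGAT"), "at least 5")
})

test_that("length filter retains exactly 12-50 nt and is idempotent", {
  reads <- mk_reads(vapply(1:60, function(n) strrep("A", n), character(1)))
  kept <- lengthFilter(reads)
  expect_identical(sort(nchar(kept$sequence)), 12:50)
  expect_identical(attr(kept, "discarded"), c(short = 11L, long = 10L))
  twice <- lengthFilter(kept)
  expect_identical(twice$sequence, kept$sequence)
  expect_identical(attr(twice, "discarded"), c(short = 0L, long = 0L))

  expect_identical(nrow(lengthFilter(mk_reads(character(0)))), 0L)
  all11 <- lengthFilter(mk_reads(rep(strrep("C", 11), 4)))
  expect_identical(nrow(all11), 0L)
  expect_identical(attr(all11, "discarded")[["short"]], 4L)
})

test_that("hierarchical decoy filtering removes by first matching set", {
  set.seed(7)
  mirna <- Biostrings::DNAStringSet(c(mir1 = "ACGTACGTACGTACGTACGTAC"))
  rrna <- Biostrings::DNAStringSet(c(rr1 = paste0(rand_seq(40),
                                                  "ACGTACGTACGTACGTACGTAC",
                                                  rand_seq(40))))
  decoys <- list(mirna = mirna, rrna = rrna)
  # a read equal to the miRNA decoy is also a substring of the rRNA decoy:
  # first-set precedence removes it as miRNA
  reads <- mk_reads(c("ACGTACGTACGTACGTACGTAC", rand_seq(25)))
  hf <- hierarchicalFilter(reads, decoys)
  expect_identical(hf$removed, c(mirna = 1L, rrna = 0L))
  expect_identical(hf$assignments$decoy_set, "mirna")
  expect_identical(hf$reads$read_id, "r2")

  # reverse-complement matching is on by default
  rcread <- mk_reads(rc("ACGTACGTACGTACGTACGTAC"))
  expect_identical(hierarchicalFilter(rcread, decoys)$removed[["mirna"]], 1L)
  expect_identical(
    hierarchicalFilter(rcread, decoys, rc = FALSE)$removed[["mirna"]], 0L)
})

test_that("planted decoy fixtures give the forced removal counts", {
  set.seed(8)
  mir <- vapply(1:5, function(i) rand_seq(22), character(1))
  rr <- rand_seq(150)
  decoys <- list(mirna = Biostrings::DNAStringSet(mir),
                 rrna = Biostrings::DNAStringSet(rr),
                 pirna = Biostrings::DNAStringSet(rand_seq(28)))
  reads <- mk_reads(c(sample(mir, 40, replace = TRUE),
                      vapply(1:10, function(i) {
                        p <- sample(1:120, 1); substr(rr, p, p + 25)
                      }, character(1)),
                      vapply(1:50, function(i) rand_seq(30), character(1))))
  hf <- hierarchicalFilter(reads, decoys)
  expect_identical(hf$removed, c(mirna = 40L, rrna = 10L, pirna = 0L))
  expect_identical(nrow(hf$reads), 50L)
  expect_warning(hierarchicalFilter(reads[0, ],
                                    list(empty = Biostrings::DNAStringSet())),
                 "empty decoy set")
})

test_that("frame alignment finds every placement with exact coordinates", {
  ref <- make_test_reference()
  frames <- as.character(frameSeqs(ref))
  reads <- mk_reads(c(substr(frames["tA"], 11, 30),   # unique placement
                      strrep("N", 20)))               # alignable nowhere
  aln <- alignToFrames(reads, ref)
  expect_identical(nrow(aln[aln$read_id == "r1", ]), 1L)
  expect_identical(aln$start[aln$read_id == "r1"], 11L)
  expect_identical(aln$end[aln$read_id == "r1"], 30L)
  expect_identical(aln$mismatches[1], 0L)
  expect_identical(attr(aln, "unaligned"), "r2")

  # a read present in both frames maps twice with multimap = 2
  shared <- substr(frames["tA"], 5, 24)
  ref2 <- MatureTRNASet(c("x", "y"),
                        c(paste0(shared, rand_seq(56), "CCA"),
                          paste0(rand_seq(10), shared, rand_seq(46), "CCA")),
                        c(rand_seq(50), rand_seq(50)))
  aln2 <- alignToFrames(mk_reads(shared), ref2)
  expect_identical(nrow(aln2), 2L)
  expect_identical(unique(aln2$multimap), 2L)

  expect_error(alignToFrames(mk_reads("ACGT"), ref, max_mismatch = 3), "mismatch")
})

test_that("exact alignment agrees with a naive all-positions substring scan", {
  ref <- make_test_reference()
  frames <- as.character(frameSeqs(ref))
  set.seed(9)
  reads <- mk_reads(c(vapply(1:30, function(i) {
    f <- sample(names(frames), 1)
    l <- sample(16:35, 1)
    s <- sample(nchar(frames[f]) - l + 1, 1)
    substr(frames[f], s, s + l - 1)
  }, character(1)), vapply(1:5, function(i) rand_seq(20), character(1))))
  aln <- alignToFrames(reads, ref)
  naive <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
    hits <- NULL
    for (f in names(frames)) {
      L <- nchar(reads$sequence[i])
      for (s in seq_len(nchar(frames[f]) - L + 1)) {
        if (substr(frames[f], s, s + L - 1) == reads$sequence[i])
          hits <- rbind(hits, data.frame(read_id = reads$read_id[i],
                                         trna_id = f, start = s,
                                         end = s + L - 1L))
      }
    }
    hits
  }))
  got <- aln[order(aln$read_id, aln$trna_id, aln$start),
             c("read_id", "trna_id", "start", "end")]
  want <- naive[order(naive$read_id, naive$trna_id, naive$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, data.frame(want))
})

test_that("every read lands in exactly one conservation bin", {
  cfg <- simConfig(seed = 51, n_genes = 6, depth = 1500,
                   contaminant_frac = 0.2)
  g <- simulateTrnaGenes(cfg)
  ref <- buildMatureSet(g$annotations, g$genome)
  decoys <- simulateDecoySets(cfg)
  rs <- simulateFragmentReads(ref, cfg, decoys)
  kept <- lengthFilter(rs$reads)
  d <- attr(kept, "discarded")
  hf <- hierarchicalFilter(kept, decoys)
  aln <- alignToFrames(hf$reads, ref)
  n_aligned <- length(unique(aln$read_id))
  n_unaligned <- length(attr(aln, "unaligned"))
  expect_identical(nrow(rs$reads),
                   as.integer(d[["short"]] + d[["long"]] + sum(hf$removed) +
                              n_unaligned + n_aligned))
})
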
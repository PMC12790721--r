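# Independent brute-force implementation of the positional class rules,
# written as a literal first-match-wins chain. Used only as an oracle.
oracle_classify <- function(start, end, M, als = 32L, ale = 38L) {
  if (start < 1 || end < start || end > M + 50L) return("UNCLASSIFIED")
  if (start == 1 && end >= als && end <= ale) return("HALF5")
  if (start == 1 && end < M) return("TRF5")
  if (end == M && start >= als && start <= ale) return("HALF3")
  if (end == M && start > ale) return("TRF3")
  if (start == M + 1 && end <= M + 50L) return("TRF1")
  if (start > 1 && end < M) return("ITRF")
  "UNCLASSIFIED"
}

# Exhaustive minimum duplex energy by enumeration over every non-crossing
# antiparallel pairing of two short sequences. A pairing is determined by a
# subset of positions in each strand of equal size k (ascending positions in
# one strand pair with descending in the other), so enumeration over subset
# pairs covers all non-crossing pairings.
oracle_duplex_mfe <- function(a, b) {
  ab <- strsplit(toupper(a), "")[[1]]
  bb <- strsplit(toupper(b), "")[[1]]
  m <- length(ab); n <- length(bb)
  pe <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)
  E <- matrix(Inf, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    v <- pe[paste0(ab[i], bb[j])]
    if (!is.na(v)) E[i, j] <- v
  }
  best <- 0
  for (k in seq_len(min(m, n))) {
    sa <- utils::combn(m, k)
    sb <- utils::combn(n, k)
    for (ia in seq_len(ncol(sa))) {
      pa <- sa[, ia]
      span_a <- pa[k] - pa[1] + 1 - k
      for (ib in seq_len(ncol(sb))) {
        pb <- rev(sb[, ib])  # antiparallel
        e <- sum(E[cbind(pa, pb)])
        if (is.finite(e)) {
          span_b <- pb[1] - pb[k] + 1 - k
          tot <- e + 0.5 * (span_a + span_b)
          if (tot < best) best <- tot
        }
      }
    }
  }
  best
}

# A tiny deterministic reference: one canonical-length tRNA (M = 79) plus a
# shorter one (M = 73), with fixed-offset landmarks.
make_test_reference <- function(seed = 42L) {
  set.seed(seed)
  body1 <- paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE), collapse = "")
  body2 <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE), collapse = "")
  tr1 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  tr2 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  assignLandmarks(MatureTRNASet(
    ids = c("tA", "tB"),
    mature = c(paste0(body1, "CCA"), paste0(body2, "CCA")),
    trailer = c(tr1, tr2)))
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(gsub("U", "T", toupper(x)))))

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
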
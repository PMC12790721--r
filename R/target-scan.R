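# Pair energies of the simplified intermolecular duplex model (kcal/mol-like
# arbitrary units): GC -3, AU -2, GU wobble -1; +0.5 per unpaired nucleotide
# between the outermost pairs of the duplex; no intramolecular structure,
# no crossing pairs.
pair_energy <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)
  out <- unname(e[key])
  out[is.na(out)] <- Inf
  out
}

is_wc <- function(a, b) paste0(a, b) %in% c("GC", "CG", "AT", "TA")
is_gu <- function(a, b) paste0(a, b) %in% c("GT", "TG")

#' miRNA-like seed match of a tRF against a target window
#'
#' TRUE iff the reverse complement of tRF positions 2-8 (the 7-nt seed)
#' occurs in the window with perfect Watson-Crick complementarity. G:U
#' wobble is not accepted in the seed unless \code{seed_wobble = TRUE}, in
#' which case T in the window may also oppose seed G, and C may oppose
#' seed... wobble pairing allows seed G:U(T) and U(T):G.
#'
#' @param trf tRF sequence (>= 8 nt; DNA or RNA alphabet).
#' @param window candidate target subsequence (sense strand).
#' @param seed_wobble accept G:U wobble pairs within the seed (default FALSE).
#' @return list(match = logical, start, end): the matched interval in window
#'   coordinates (NA when no match).
#' @export
seedMatch <- function(trf, window, seed_wobble = FALSE) {
  trf <- norm_dna(trf)
  window <- norm_dna(window)
  if (nchar(trf) < 8) stop("tRF must be at least 8 nt for a seed", call. = FALSE)
  if (nchar(window) < 7) return(list(match = FALSE, start = NA, end = NA))
  seed <- substr(trf, 2, 8)
  if (!seed_wobble) {
    pos <- regexpr(revcomp(seed), window, fixed = TRUE)
    if (pos > 0)
      return(list(match = TRUE, start = as.integer(pos),
                  end = as.integer(pos) + 6L))
    return(list(match = FALSE, start = NA, end = NA))
  }
  # wobble-tolerant: window base k pairs trf seed base 8-k+1 (antiparallel)
  sb <- rev(strsplit(seed, "")[[1]])
  wb <- strsplit(window, "")[[1]]
  for (s in seq_len(nchar(window) - 6L)) {
    w <- wb[s:(s + 6L)]
    if (all(is_wc(sb, w) | is_gu(sb, w)))
      return(list(match = TRUE, start = s, end = s + 6L))
  }
  list(match = FALSE, start = NA, end = NA)
}

#' Intermolecular duplex minimum free energy
#'
#' Dynamic program over intermolecular base pairs only (no hairpins within
#' either strand, no crossing pairs; the two strands pair antiparallel).
#' Pair energies: GC = -3.0, AU = -2.0, GU = -1.0; each unpaired nucleotide
#' between the outermost pairs of the duplex costs +0.5. The empty pairing
#' has energy 0, so the MFE is always <= 0.
#'
#' @param trf,site the two sequences (each 5-60 nt; DNA or RNA alphabet).
#' @return list(mfe = numeric, pairing = two-line string: '(' marks paired
#'   tRF positions, ')' paired site positions, '.' unpaired).
#' @export
duplexMFE <- function(trf, site) {
  A <- strsplit(norm_dna(trf), "")[[1]]
  B <- strsplit(norm_dna(site), "")[[1]]
  m <- length(A); n <- length(B)
  if (m < 1 || m > 60 || n < 1 || n > 60)
    stop("duplexMFE is defined for sequences of 1-60 nt", call. = FALSE)
  Br <- rev(B)  # reversed site: pairing becomes a left-to-right alignment
  # M[i,k]: best duplex energy whose 3'-most tRF pair is (i, k); D[i,k]:
  # min over pairs (i',k') with i'<=i, k'<=k of M + 0.5 per base skipped
  # since that pair.
  M <- matrix(Inf, m, n)
  D <- matrix(Inf, m, n)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      e <- pair_energy(A[i], Br[k])
      if (is.finite(e)) {
        prev <- if (i > 1 && k > 1) D[i - 1, k - 1] else Inf
        M[i, k] <- e + min(0, prev)
      }
      D[i, k] <- min(M[i, k],
                     if (i > 1) D[i - 1, k] + 0.5 else Inf,
                     if (k > 1) D[i, k - 1] + 0.5 else Inf)
    }
  }
  mfe <- min(0, M)
  pairs <- matrix(integer(0), ncol = 2)
  if (mfe < 0) {
    # traceback (all energies are multiples of 0.5: equality is exact)
    best <- which(M == mfe, arr.ind = TRUE)[1, ]
    i <- best[1]; k <- best[2]
    repeat {
      pairs <- rbind(pairs, c(i, k))
      e <- pair_energy(A[i], Br[k])
      if (i == 1 || k == 1 || M[i, k] == e) break  # no predecessor used
      ti <- i - 1; tk <- k - 1
      while (D[ti, tk] != M[ti, tk]) {
        if (ti > 1 && D[ti, tk] == D[ti - 1, tk] + 0.5) ti <- ti - 1
        else tk <- tk - 1
      }
      i <- ti; k <- tk
    }
  }
  l1 <- rep(".", m); l2 <- rep(".", n)
  if (nrow(pairs)) {
    l1[pairs[, 1]] <- "("
    l2[n - pairs[, 2] + 1] <- ")"
  }
  list(mfe = mfe, pairing = paste(paste(l1, collapse = ""),
                                  paste(l2, collapse = ""), sep = "\n"))
}

# miRanda-like additive alignment score of a tRF against a target window:
# Needleman-Wunsch of the tRF versus the reversed window with pair scoring
# WC +5, GU wobble +1 (outside the seed), mismatch -3, gap -8; tRF seed
# positions (2-8) are weighted x2 on matches/mismatches (wobble in the seed
# scores as a mismatch). End gaps in the window are free.
alignment_score <- function(trf, window, seed_wobble = FALSE) {
  A <- strsplit(norm_dna(trf), "")[[1]]
  Br <- rev(strsplit(norm_dna(window), "")[[1]])
  m <- length(A); n <- length(Br)
  sc <- function(i, k) {
    seed <- i >= 2 && i <= 8
    wt <- if (seed) 2 else 1
    if (is_wc(A[i], Br[k])) return(5 * wt)
    if (is_gu(A[i], Br[k]) && (!seed || seed_wobble)) return(1)
    -3 * wt
  }
  F <- matrix(-Inf, m + 1, n + 1)
  F[1, ] <- 0            # free leading window gaps
  F[, 1] <- -8 * (0:m)   # tRF gaps cost
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      F[i + 1, k + 1] <- max(F[i, k] + sc(i, k),
                             F[i, k + 1] - 8,
                             F[i + 1, k] - 8)
    }
  }
  max(F[m + 1, ])        # free trailing window gaps
}

#' Scan a 3'-UTR for tRF binding sites
#'
#' Slides a window of length(tRF) + 4 across the UTR (sense strand only).
#' Windows passing the seed match are scored with the additive alignment
#' score and the intermolecular duplex MFE; hits with
#' \code{score >= min_score} and \code{mfe <= max_energy} are returned,
#' sorted by MFE then score, with overlapping hits merged keeping the best.
#'
#' @param trf tRF query sequence (DNA or RNA).
#' @param utr UTR sequence (DNA or RNA).
#' @param min_score minimum alignment score (default 80).
#' @param max_energy maximum (most positive) duplex MFE (default -15).
#' @param trf_id label carried into the hit table.
#' @param seed_wobble accept G:U wobble in the seed (default FALSE).
#' @return data.frame (utr_start, utr_end, trf_id, seed_match, score, mfe,
#'   pairing), possibly with zero rows.
#' @export
scanUTR <- function(trf, utr, min_score = 80, max_energy = -15,
                    trf_id = "trf", seed_wobble = FALSE) {
  trf <- norm_dna(trf)
  utr <- norm_dna(utr)
  if (nchar(utr) < nchar(trf))
    stop("UTR shorter than the tRF query", call. = FALSE)
  w <- nchar(trf) + 4L
  hits <- list()
  for (s in seq_len(max(0L, nchar(utr) - w + 1L))) {
    win <- substr(utr, s, s + w - 1L)
    sm <- seedMatch(trf, win, seed_wobble = seed_wobble)
    if (!sm$match) next
    score <- alignment_score(trf, win, seed_wobble = seed_wobble)
    dp <- duplexMFE(trf, win)
    if (score >= min_score && dp$mfe <= max_energy)
      hits[[length(hits) + 1L]] <- data.frame(
        utr_start = s, utr_end = s + w - 1L, trf_id = trf_id,
        seed_match = TRUE, score = score, mfe = dp$mfe,
        pairing = dp$pairing, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(utr_start = integer(0), utr_end = integer(0),
                      trf_id = character(0), seed_match = logical(0),
                      score = numeric(0), mfe = numeric(0),
                      pairing = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$mfe, -out$score, out$utr_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      later <- (i + 1L):nrow(out)
      ovl <- out$utr_start[later] <= out$utr_end[i] &
             out$utr_end[later] >= out$utr_start[i]
      keep[later][ovl] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare tRF target scans of wild-type and mutated UTRs
#'
#' The computational analogue of a WT-versus-mutant reporter contrast: the
#' site should be found in the wild-type UTR and lost when seed-opposing
#' residues are mutated.
#'
#' @param trf tRF query sequence.
#' @param utr_wt,utr_mut UTR sequences of equal length.
#' @param min_score,max_energy scan thresholds (see \code{\link{scanUTR}}).
#' @return list(n_wt, n_mut, best_mfe_wt, best_mfe_mut, verdict) where
#'   verdict is one of "site ablated", "site retained", "no site in either",
#'   "site gained".
#' @export
compareWtMut <- function(trf, utr_wt, utr_mut, min_score = 80,
                         max_energy = -15) {
  if (nchar(utr_wt) != nchar(utr_mut))
    stop("WT and mutated UTRs must have equal length", call. = FALSE)
  hw <- scanUTR(trf, utr_wt, min_score, max_energy)
  hm <- scanUTR(trf, utr_mut, min_score, max_energy)
  verdict <- if (nrow(hw) > 0 && nrow(hm) == 0) "site ablated"
    else if (nrow(hw) > 0) "site retained"
    else if (nrow(hm) == 0) "no site in either"
    else "site gained"
  list(n_wt = nrow(hw), n_mut = nrow(hm),
       best_mfe_wt = if (nrow(hw)) min(hw$mfe) else NA_real_,
       best_mfe_mut = if (nrow(hm)) min(hm$mfe) else NA_real_,
       verdict = verdict, hits_wt = hw, hits_mut = hm)
}
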
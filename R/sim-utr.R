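#' The tRF-23-associated worked-example sequence
#'
#' The 23-nt sequence used throughout the worked examples and the demo
#' pipeline as the tRF query (DNA alphabet). It is treated as an opaque
#' example input for the target scanner.
#'
#' @export
TRF23_SEQUENCE <- "GGCGGTGAGAGCGCCGAATCCTA"

#' Embed a tRF target site in a synthetic 3'-UTR
#'
#' Wild-type mode (no \code{mutate_positions}) embeds the exact reverse
#' complement of the tRF at a random interior position of a random-background
#' UTR. Mutant mode substitutes, at the bases opposite the given tRF
#' positions, a base identical to the tRF base itself — which can neither
#' Watson-Crick- nor wobble-pair with it — leaving the rest of the site and
#' the background untouched. Running WT and MUT with the same seed yields
#' UTRs differing only at the mutated positions, the computational analogue
#' of a wild-type versus seed-mutated reporter construct.
#'
#' @param utr_len UTR length (>= length(trf) + 20).
#' @param trf tRF sequence (DNA or RNA).
#' @param mutate_positions integer positions in 1..length(trf) whose
#'   opposing site bases are mutated (empty for wild type).
#' @param seed random seed for the background and site placement.
#' @return list(utr = UTR sequence string, site_start, site_end (1-based
#'   closed interval of the embedded site), mutated_utr_positions).
#' @export
embedTargetSite <- function(utr_len, trf, mutate_positions = integer(0),
                            seed = 1L) {
  trf <- norm_dna(trf)
  L <- nchar(trf)
  if (utr_len < L + 20L)
    stop("utr_len must be at least length(trf) + 20", call. = FALSE)
  if (length(mutate_positions) &&
      (any(mutate_positions < 1L) || any(mutate_positions > L)))
    stop("mutate_positions must lie within 1..length(trf)", call. = FALSE)
  with_seed(seed, {
    bg <- random_dna(utr_len)
    site_start <- sample(11:(utr_len - L - 9L), 1)
    site <- revcomp(trf)
    utr <- paste0(substr(bg, 1, site_start - 1L), site,
                  substr(bg, site_start + L, utr_len))
    mut_pos <- integer(0)
    if (length(mutate_positions)) {
      ub <- strsplit(utr, "")[[1]]
      tb <- strsplit(trf, "")[[1]]
      mut_pos <- site_start + L - as.integer(mutate_positions)
      ub[mut_pos] <- tb[mutate_positions]  # self-base: not WC, not wobble
      utr <- paste(ub, collapse = "")
    }
    list(utr = utr, site_start = site_start, site_end = site_start + L - 1L,
         mutated_utr_positions = sort(mut_pos))
  })
}
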
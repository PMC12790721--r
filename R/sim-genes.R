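ANTICODON_TAGS <- c("Glu-CTC", "Gly-GCC", "Lys-CTT", "Val-CAC",
                    "Asp-GTC", "His-GTG", "Leu-CAG", "Ser-GCT")

#' Simulate tRNA gene loci
#'
#' Generates one contig per gene (flanks on both sides keep synthetic
#' placements unambiguous), an annotation row per gene, and the mature-
#' sequence ground truth. Roughly half of the genes land on the minus
#' strand; spliced mature body lengths are drawn uniformly from
#' \code{mature_len_min:mature_len_max}; with probability \code{intron_prob}
#' a gene carries one 10-20 nt intron inserted one base 3' of the canonical
#' anticodon position (after spliced base 37), as in genomic tRNA genes.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with `genome` (\link[Biostrings]{DNAStringSet}),
#'   `annotations` (data.frame in the \code{\link{parseAnnotations}} schema)
#'   and `truth` (list with `mature`: spliced mature sequences + CCA,
#'   `strand`, `has_intron`).
#' @export
simulateTrnaGenes <- function(config) {
  validateSimConfig(config)
  with_seed(config$seed, {
    flank <- max(60L, config$trailer_len + 10L)
    contigs <- character(config$n_genes)
    rows <- vector("list", config$n_genes)
    mature <- character(config$n_genes)
    strand <- character(config$n_genes)
    has_intron <- logical(config$n_genes)
    ids <- character(config$n_genes)
    for (g in seq_len(config$n_genes)) {
      body_len <- sample(config$mature_len_min:config$mature_len_max, 1)
      body <- random_dna(body_len)
      strand[g] <- sample(c("+", "-"), 1)
      has_intron[g] <- runif(1) < config$intron_prob
      intron_rel <- NULL  # 0-based offsets within the sense gene
      gene_sense <- body
      if (has_intron[g]) {
        ilen <- sample(10:20, 1)
        p <- if (body_len >= 45L) 37L else body_len %/% 2L
        gene_sense <- paste0(substr(body, 1, p), random_dna(ilen),
                             substr(body, p + 1, body_len))
        intron_rel <- c(p, p + ilen)
      }
      glen <- nchar(gene_sense)
      gene_fwd <- if (strand[g] == "+") gene_sense else revcomp(gene_sense)
      contigs[g] <- paste0(random_dna(flank), gene_fwd, random_dna(flank))
      gs <- flank
      ge <- flank + glen
      introns <- matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
      if (!is.null(intron_rel)) {
        introns <- if (strand[g] == "+")
          matrix(gs + intron_rel, ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
        else
          matrix(gs + c(glen - intron_rel[2], glen - intron_rel[1]), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
      }
      tag <- ANTICODON_TAGS[(g - 1L) %% length(ANTICODON_TAGS) + 1L]
      ids[g] <- sprintf("tRNA-%s-%d", tag, g)
      rows[[g]] <- data.frame(contig = sprintf("contig_%d", g),
                              start = gs, end = ge, strand = strand[g],
                              gene_id = ids[g], anticodon = tag,
                              introns = I(list(introns)),
                              stringsAsFactors = FALSE)
      mature[g] <- paste0(body, "CCA")
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- sprintf("contig_%d", seq_len(config$n_genes))
    mature_set <- Biostrings::DNAStringSet(mature)
    names(mature_set) <- ids
    list(genome = genome,
         annotations = do.call(rbind, rows),
         truth = list(mature = mature_set,
                      strand = setNames(strand, ids),
                      has_intron = setNames(has_intron, ids)))
  })
}

#' Simulate decoy sequence sets for the hierarchical filter
#'
#' Random miRNA-length (20-24 nt), rRNA-length (120-180 nt) and piRNA-length
#' (26-31 nt) decoy sequences, seeded from the configuration so the whole
#' input bundle is reproducible.
#'
#' @param config a \code{\link{simConfig}}.
#' @return named list of \link[Biostrings]{DNAStringSet}: mirna, rrna, pirna.
#' @export
simulateDecoySets <- function(config) {
  validateSimConfig(config)
  with_seed(config$seed + 1000L, {
    mk <- function(prefix, n, len_range) {
      s <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
        random_dna(sample(len_range, 1)), character(1)))
      names(s) <- sprintf("%s_%d", prefix, seq_len(n))
      s
    }
    list(mirna = mk("mir", 20L, 20:24),
         rrna = mk("rrna", 3L, 120:180),
         pirna = mk("pir", 10L, 26:31))
  })
}
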
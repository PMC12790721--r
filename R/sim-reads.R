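# Legal coordinate sets per class for one reference, under the classifier's
# rule table (first match wins), restricted to fragment lengths in
# [fmin, fmax]. Returns a list of candidate descriptors or NULL when the
# class is geometrically impossible for this reference.
class_coord_space <- function(M, als, ale, fmin, fmax) {
  if (is.na(als)) return(NULL)
  spaces <- list()
  e5 <- setdiff(seq(fmin, min(fmax, M - 1L)), seq(als, ale))
  if (length(e5)) spaces$TRF5 <- list(type = "end5", ends = e5)
  h5lo <- max(als, fmin); h5hi <- min(ale, fmax)
  if (h5lo <= h5hi) spaces$HALF5 <- list(type = "end5", ends = h5lo:h5hi)
  h3lo <- max(als, M - fmax + 1L); h3hi <- min(ale, M - fmin + 1L)
  if (h3lo <= h3hi) spaces$HALF3 <- list(type = "start3", starts = h3lo:h3hi)
  t3lo <- max(ale + 1L, M - fmax + 1L); t3hi <- M - fmin + 1L
  if (t3lo <= t3hi) spaces$TRF3 <- list(type = "start3", starts = t3lo:t3hi)
  t1max <- min(fmax, 50L)
  if (fmin <= t1max) spaces$TRF1 <- list(type = "trailer", lens = fmin:t1max)
  ilens <- seq(fmin, min(fmax, M - 2L))
  if (length(ilens) && fmin <= M - 2L)
    spaces$ITRF <- list(type = "internal", lens = ilens)
  spaces
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Simulate tRF fragment reads with ground-truth labels
#'
#' Draws non-contaminant reads as exact substrings of the mature + CCA +
#' trailer frame of a source tRNA, with coordinates sampled uniformly inside
#' the class-legal coordinate set so that the true class under the
#' positional rule table always matches the planted label. Contaminant reads
#' are either exact (sub)sequences of decoy sets (full copies of
#' miRNA-length decoys, 16-35 nt substrings of longer decoys) or random
#' sequences with lengths outside [12, 50].
#'
#' If a class has nonzero mix weight but is geometrically impossible for
#' some reference, reads of that class are drawn from the references where
#' it is possible; if it is impossible for every reference, generation
#' fails naming the class.
#'
#' @param reference a \linkS4class{MatureTRNASet} with landmarks assigned.
#' @param config a \code{\link{simConfig}}.
#' @param decoys optional decoy sets (see \code{\link{simulateDecoySets}});
#'   generated from `config` when NULL and contaminants are requested.
#' @return list with `reads` (data.frame read_id, sequence) and `truth`
#'   (data.frame read_id, source, trna_id, class, start, end).
#' @export
simulateFragmentReads <- function(reference, config, decoys = NULL) {
  validateSimConfig(config)
  if (length(reference) == 0) stop("reference is empty", call. = FALSE)
  n_cont <- round(config$depth * config$contaminant_frac)
  n_frag <- config$depth - n_cont
  if (n_cont > 0 && is.null(decoys)) decoys <- simulateDecoySets(config)
  M <- unname(matureLengths(reference))
  lm <- reference@landmarks
  frames <- as.character(frameSeqs(reference))
  ids <- trnaIds(reference)
  spaces <- lapply(seq_along(ids), function(i)
    class_coord_space(M[i], lm$aloop_start[i], lm$aloop_end[i],
                      config$frag_len_min, config$frag_len_max))
  feasible <- lapply(TRF_CLASSES, function(cl)
    which(vapply(spaces, function(sp) cl %in% names(sp), logical(1))))
  names(feasible) <- TRF_CLASSES
  for (cl in TRF_CLASSES) {
    if (config$class_mix[cl] > 0 && length(feasible[[cl]]) == 0)
      stop(sprintf(paste0("generation error: class %s is geometrically ",
                          "impossible for every reference at fragment ",
                          "lengths %d-%d"),
                   cl, config$frag_len_min, config$frag_len_max),
           call. = FALSE)
  }
  with_seed(config$seed + 2000L, {
    cls <- sample(TRF_CLASSES, n_frag, replace = TRUE, prob = config$class_mix)
    frag <- lapply(seq_len(n_frag), function(r) {
      cl <- cls[r]
      i <- sample1(feasible[[cl]])
      sp <- spaces[[i]][[cl]]
      coords <- switch(sp$type,
        end5 = c(1L, sample1(sp$ends)),
        start3 = { s <- sample1(sp$starts); c(s, M[i]) },
        trailer = { l <- sample1(sp$lens); c(M[i] + 1L, M[i] + l) },
        internal = { l <- sample1(sp$lens); s <- sample1(2:(M[i] - l))
                     c(s, s + l - 1L) })
      list(seq = substr(frames[i], coords[1], coords[2]),
           trna = ids[i], class = cl, start = coords[1], end = coords[2])
    })
    n_dec <- n_cont %/% 2L
    n_rand <- n_cont - n_dec
    dec <- lapply(seq_len(n_dec), function(r) {
      set_name <- sample(names(decoys), 1)
      d <- decoys[[set_name]][[sample1(seq_along(decoys[[set_name]]))]]
      dw <- length(d)
      s <- if (dw <= 50L) as.character(d) else {
        l <- sample(16:35, 1); p <- sample1(seq_len(dw - l + 1L))
        as.character(Biostrings::subseq(d, p, p + l - 1L))
      }
      list(seq = s, trna = NA_character_,
           class = paste0("decoy:", set_name), start = NA_integer_,
           end = NA_integer_)
    })
    rnd <- lapply(seq_len(n_rand), function(r) {
      l <- sample(c(5:11, 51:70), 1)
      list(seq = random_dna(l), trna = NA_character_, class = "random",
           start = NA_integer_, end = NA_integer_)
    })
    all_reads <- c(frag, dec, rnd)
    ord <- sample(length(all_reads))
    all_reads <- all_reads[ord]
    rid <- sprintf("read_%06d", seq_along(all_reads))
    src <- vapply(all_reads, `[[`, character(1), "class")
    truth <- data.frame(
      read_id = rid,
      source = ifelse(src %in% TRF_CLASSES, "trf", src),
      trna_id = vapply(all_reads, `[[`, character(1), "trna"),
      class = ifelse(src %in% TRF_CLASSES, src, NA_character_),
      start = vapply(all_reads, `[[`, integer(1), "start"),
      end = vapply(all_reads, `[[`, integer(1), "end"),
      stringsAsFactors = FALSE)
    list(reads = data.frame(read_id = rid,
                            sequence = vapply(all_reads, `[[`, character(1), "seq"),
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}
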
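#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator, with defaults
#' matching the study conditions the pipeline is designed for: fragments of
#' 16-35 nt, reads of 12-50 nt surviving the length filter, a four-day
#' (0/7/14/21) design with 3 replicates, and planted day-7 peaks of
#' |log2FC| = 2 (i.e. 4-fold), comfortably past the log2FC > 1 screen.
#'
#' The default class mix spreads reads over TRF5/TRF3/ITRF/TRF1/HALF5 and
#' gives 3' halves (HALF3) weight 0: a 3' half runs from the anticodon loop
#' to the mature 3' end and is therefore at least ~36 nt long for mature
#' lengths of 73-93 nt, which the default 16-35 nt fragment-length model
#' cannot produce. Supply a wider length window (and a nonzero HALF3 weight)
#' to simulate halves.
#'
#' @param seed integer random seed.
#' @param n_genes number of synthetic tRNA genes.
#' @param intron_prob probability a gene carries one intron (0-1).
#' @param trailer_len genomic nucleotides available downstream of each gene
#'   (>= 50).
#' @param frag_len_min,frag_len_max fragment length bounds in nt (defaults
#'   16 and 35; must lie within [12, 50]).
#' @param class_mix named proportions over the six tRF classes, summing to 1.
#' @param depth reads per sample.
#' @param contaminant_frac fraction of decoy-matching / out-of-length-range
#'   reads.
#' @param n_timepoints number of time points (4 = days 0/7/14/21; 2 = days
#'   0/7 for two-group simulations).
#' @param reps replicates per time point.
#' @param peak_frac fraction of tRFs planted as day-7 peaking.
#' @param effect_log2fc planted |log2FC| (default 2; must be >= 1 so planted
#'   positives pass the log2FC > 1 screen in expectation).
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param mean_count baseline mean count per tRF per sample.
#' @param mature_len_min,mature_len_max spliced mature body length range
#'   before CCA (defaults 70 and 90).
#' @return a `trf_sim_config` list.
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 20L,
                      intron_prob = 0.3,
                      trailer_len = 60L,
                      frag_len_min = 16L,
                      frag_len_max = 35L,
                      class_mix = c(TRF5 = 0.25, TRF3 = 0.25, TRF1 = 0.10,
                                    ITRF = 0.30, HALF5 = 0.10, HALF3 = 0),
                      depth = 10000L,
                      contaminant_frac = 0.05,
                      n_timepoints = 4L,
                      reps = 3L,
                      peak_frac = 0.1,
                      effect_log2fc = 2,
                      nb_dispersion = 0.05,
                      mean_count = 200,
                      mature_len_min = 70L,
                      mature_len_max = 90L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              intron_prob = intron_prob, trailer_len = as.integer(trailer_len),
              frag_len_min = as.integer(frag_len_min),
              frag_len_max = as.integer(frag_len_max),
              class_mix = class_mix, depth = as.integer(depth),
              contaminant_frac = contaminant_frac,
              n_timepoints = as.integer(n_timepoints),
              reps = as.integer(reps), peak_frac = peak_frac,
              effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
              mean_count = mean_count,
              mature_len_min = as.integer(mature_len_min),
              mature_len_max = as.integer(mature_len_max))
  class(cfg) <- "trf_sim_config"
  validateSimConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `trf_sim_config` list.
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validateSimConfig <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      config_error(field, "must be a probability in [0, 1]")
  }
  chk_pos <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min)
      config_error(field, sprintf("must be >= %s", min))
  }
  chk_pos("n_genes"); chk_pos("depth"); chk_pos("reps")
  chk_prob("intron_prob"); chk_prob("contaminant_frac"); chk_prob("peak_frac")
  if (cfg$trailer_len < 50L) config_error("trailer_len", "must be >= 50")
  if (cfg$frag_len_min < 12L) config_error("frag_len_min", "must be >= 12")
  if (cfg$frag_len_max > 50L) config_error("frag_len_max", "must be <= 50")
  if (cfg$frag_len_min > cfg$frag_len_max)
    config_error("frag_len_min", "must be <= frag_len_max")
  if (!all(sort(names(cfg$class_mix)) == sort(TRF_CLASSES)))
    config_error("class_mix", "must be named with the six tRF classes")
  if (any(cfg$class_mix < 0) || abs(sum(cfg$class_mix) - 1) > 1e-9)
    config_error("class_mix", "must be non-negative proportions summing to 1")
  if (!cfg$n_timepoints %in% c(2L, 4L))
    config_error("n_timepoints", "must be 2 or 4")
  if (cfg$effect_log2fc != 0 && cfg$effect_log2fc < 1)
    config_error("effect_log2fc",
                 "planted positives must have |log2FC| >= 1 (or exactly 0 for a null)")
  if (cfg$nb_dispersion <= 0) config_error("nb_dispersion", "must be > 0")
  if (cfg$mean_count <= 0) config_error("mean_count", "must be > 0")
  if (cfg$mature_len_min < 57L || cfg$mature_len_min > cfg$mature_len_max)
    config_error("mature_len_min", "must be >= 57 and <= mature_len_max")
  invisible(cfg)
}
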
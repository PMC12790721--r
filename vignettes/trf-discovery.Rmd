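---
title: "Methods: tRF discovery, classification, screening and target prediction"
author: "trfscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tRF discovery, classification, screening and target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfscape)
```

# The problem

tRNA loci produce, beyond mature tRNAs, a family of small non-coding RNAs:
tRNA-derived fragments (tRFs/tsRNAs). A fragment's biogenesis — and much of
its likely function — is encoded in *where* it sits on its source tRNA.
Anticodon-loop cleavage yields 5′- and 3′-halves; D-loop/anticodon-region
cleavage of the mature tRNA yields tRF-5; T-loop/anticodon-stem cleavage
yields the CCA-anchored tRF-3; RNase-Z processing of the precursor releases
the 3′ trailer as tRF-1; and internal fragments are i-tRFs. `trfscape`
implements the full computational chain needed to find, classify, quantify
and screen such fragments from small RNA-seq over a differentiation time
course (days 0/7/14/21), and to predict miRNA-like tRF binding sites in
3′-UTRs. A synthetic-data module generates all inputs with ground truth, so
every stage is testable at desk scale.

# The tRF search space

A tRF cannot be found by ordinary genome alignment: mature tRNAs are
spliced, carry a non-templated 3′ `CCA`, and tRF-1 fragments live in
genomic sequence *past* the gene. The reference builder therefore
constructs, per annotated tRNA gene:

* the **mature sequence**: exonic sequence (introns removed), oriented to
  the sense strand, with `CCA` appended — length `M`;
* the **trailer**: the 50 genomic nucleotides immediately 3′ of the gene on
  the sense strand;
* the **frame**: `mature + trailer`, positions `1..M+50` (1-based closed).
  All fragment coordinates downstream are in this frame.

Annotations use BED conventions (0-based half-open, forward strand, introns
strictly inside the gene); frame coordinates are 1-based closed. All
sequences are normalized to the DNA alphabet internally (RNA input is
accepted and converted). Post-transcriptional edits other than CCA (e.g.
the histidine 5′ G) are not modeled.

## Cloverleaf landmarks

The class rules need the structural loops, which plain sequence does not
give. We use a fixed-offset model anchored on the canonical 76-nt tRNA:
acceptor stem `[1,7]`, D-loop `[14,21]`, anticodon loop `[32,38]`, and the
T-loop anchored to the 3′ end at `[M-22, M-16]` so the CCA-proximal
geometry survives non-canonical lengths. Mature sequences shorter than
60 nt cannot carry this geometry and are flagged unclassifiable. The model
is deterministic and overridable; it trades per-molecule structural realism
for testability, which is the right trade at desk scale.

# Read processing

Adapter trimming is exact: the read is truncated at the leftmost position
where a ≥5-nt prefix of the adapter matches the read suffix. Reads of
12–50 nt are retained; shorter/longer reads are counted out. Surviving
reads pass a hierarchical decoy chain (default order miRNA → rRNA → piRNA;
the order is configurable because published pipelines differ on it): a read
is removed by the *first* set containing it as an exact substring, matching
both strands by default, mirroring what an aligner would do. Survivors are
placed in the frames by exact substring search (optionally ≤2 mismatches by
brute scan). We deliberately use exact string operations rather than a
heuristic aligner: at desk scale they are a complete specification, every
downstream number is reproducible, and each step has a trivial independent
oracle (the test suite checks alignment against a naive all-positions
scan). Multi-mapping reads are counted fractionally (1/multimap) so no read
is double-counted; every input read ends in exactly one conservation bin
(too short / too long / decoy set / unaligned / aligned), an invariant the
pipeline report and tests assert.

# Positional classification

Placed fragments are classified by a first-match-wins rule table over
`(start, end)` in the frame:

1. `start = 1`, `end` in the anticodon loop → **5′-half**;
2. `start = 1`, `end < M` → **tRF-5**;
3. `end = M`, `start` in the anticodon loop → **3′-half**;
4. `end = M`, `start` past the anticodon loop → **tRF-3**;
5. `start = M+1`, `end ≤ M+50` → **tRF-1**;
6. `1 < start`, `end < M` → **i-tRF**;
7. otherwise **UNCLASSIFIED** (junction-spanning reads, trailer-internal
   placements not starting at `M+1`, and full-length `1..M` placements —
   the last being a mature tRNA, not a fragment).

Halves precede tRF-5/tRF-3 because termination *in* the anticodon loop is
the halves' defining feature; the ordering resolves the boundary overlap
deterministically. tRF-3 must end exactly at the final CCA base and tRF-1
must start at the first trailer base; both choices are strict because the
evidence for partial-CCA ends is equivocal and looseness here would blur
classes. Classification is database-free: rather than looking fragments up
in versioned external registries, the positional rules make the classifier
applicable to any reference, including synthetic ones — which is what makes
full recovery testing possible. The test suite checks the implementation
against an independently written brute-force rule chain on exhaustive
coordinate grids for `M ∈ {70, 76, 79, 90}`.

A geometric consequence worth stating: with the fixed-offset landmarks, a
3′-half spans at least `M − 38 + 1` nucleotides — ≥ 36 nt for every mature
length in the 70–90 nt range. Fragment pools restricted to 16–35 nt
therefore contain at most five of the six classes; 3′-halves only appear
when longer fragments are admitted. The synthetic generator's default class
mix reflects this (below).

Candidate tRFs (distinct placements) are named `tRF-<L>-<code>`: the
sequence read as a base-4 numeral re-expressed in base 36. The scheme
guarantees format, determinism, injectivity and decodability (tested
exhaustively over 4^8 sequence families); it does not claim byte-parity
with external label registries, which use their own lookup tables.

# Quantification and the differential-expression screen

Counts are per (tRF, sample) sums of fractional read weights, held in a
`SummarizedExperiment` over the day 0/7/14/21 × replicates design.
Reporting uses plain counts-per-million (columns sum to 10^6). The screen
itself runs the three consecutive-day comparisons (0v7, 7v14, 14v21) and
calls a tRF significant iff `|log2FC| > 1` **and** BH `FDR < 0.05` (strict
inequalities; fold change > 2 or < 0.5 at `p`/FDR < 0.05 is the same rule).

Two numerical choices matter:

* **Normalization inside the test** is DESeq-style median-of-ratios
  (effective library sizes), not plain column totals. With a substantial
  planted fraction of day-7-induced tRFs (30% in the recovery tests), total
  counts are themselves inflated at day 7; plain CPM would shrink an
  observed log2FC of 2 to ≈ 1.07 and gut the screen. Median-of-ratios
  assumes most features are unchanged — the standard assumption — and
  restores the planted effect sizes.
* **The test** is a negative-binomial quasi-likelihood F-test (edgeR's
  `glmQLFit`/`glmQLFTest`) with tag-wise dispersion estimation. Small-RNA
  counts at 3 replicates are overdispersed; a test that ignores this (e.g.
  a plain conditional binomial on summed counts) rejects over half of null
  tRFs at p < 0.05 under dispersion 0.05, an order of magnitude off. The
  QL F-test measures at 0.051 ± 0.002 on 20-seed null simulations (2,000
  tRFs, 3 vs 3), with ≥ 99% power at the planted conditions (log2FC = 2,
  mean 500, dispersion 0.05) — both properties are asserted in the test
  suite at those problem sizes.

`log2FC` is reported as `log2((mean CPM_b + 0.5)/(mean CPM_a + 0.5))` on
effective-library CPM; the 0.5-CPM pseudocount keeps zero-count tRFs
finite, and all-zero tRFs get `p = 1`, `log2FC = 0` by convention. Peak day
is the argmax of mean normalized count over days, ties resolved to the
earliest day and flagged; the "day-7-peaking" set requires 0v7
significance with positive log2FC *and* peak day 7.

# Target scanning

The scanner asks the miRNA-style question: does the tRF recognise a site in
a (sense-strand) 3′-UTR?

* **Seed**: perfect Watson–Crick complementarity of tRF positions 2–8
  (7-mer); G:U wobble is disallowed in the seed by default (a flag relaxes
  it), matching the miRNA convention.
* **Alignment score**: tRF vs the window (length(tRF) + 4), antiparallel;
  WC +5, G:U +1 outside the seed, mismatch −3, gap −8, seed positions
  weighted ×2, window end gaps free.
* **Duplex MFE**: a dynamic program over *intermolecular* pairs only
  (GC −3.0, AU −2.0, GU −1.0, +0.5 per unpaired base between the outermost
  pairs, no crossing pairs, empty pairing = 0 so MFE ≤ 0). Because
  non-crossing intermolecular pairings of two strands are exactly the
  antiparallel alignments, the DP is O(mn); the suite proves it equal to
  exhaustive enumeration over all pairings of random 8-mers.

The energy/score model is deliberately self-contained and simplified — it
is not a nearest-neighbor thermodynamic model, and no parity with external
scanners is claimed; its contract is the procedure (seed + score + energy +
thresholds), with every constant stated above. Default thresholds
(`min_score = 80`, `max_energy = -15`) sit far below a perfect ~23-nt
duplex (score 150, energy ≈ −61 for the worked-example sequence) and far
above what random 7-mer seed matches achieve, so random 1-kb UTRs
essentially never produce hits while embedded sites always do. Overlapping
hits are merged keeping the lowest-energy one, making output independent of
window evaluation order. The WT-versus-mutant comparison reports "site
ablated" when the wild-type UTR has ≥1 hit and the seed-mutated UTR none —
the computational analogue of a reporter-assay contrast.

# The synthetic-data generator

The generator defines the conditions every recovery test runs under:

* **Genes**: 70–90 nt spliced bodies (uniform), ~half on the minus strand,
  one 10–20 nt intron with probability 0.3 inserted after spliced base 37
  (the canonical intron position), one contig per gene with ≥60-nt flanks
  so placements stay unambiguous by construction.
* **Fragments**: lengths uniform on [16, 35] — the observed tRF length
  range; only the range, not the distribution, is constrained by data, so
  uniform is the assumption-free choice. Coordinates are sampled uniformly
  *within the class-legal coordinate set* of the planted class, so the
  classifier's rule table provably returns the planted label for every
  read. The default class mix (tRF-5 0.25, tRF-3 0.25, i-tRF 0.30,
  tRF-1 0.10, 5′-half 0.10, 3′-half 0) gives 3′-halves zero weight because
  they are geometrically impossible under the 16–35 nt length model (see
  above); a class with nonzero weight that is impossible for *every*
  reference raises a generation error naming it.
* **Contaminants** (5% by default): half exact decoy (sub)sequences — full
  copies of miRNA-length decoys, 16–35 nt substrings of longer rRNA/piRNA
  decoys, so they survive the length filter and exercise the decoy chain —
  and half random sequences outside [12, 50] nt, exercising the length
  filter. FASTQ qualities are constant `I`; quality is unused downstream.
* **Counts**: negative-binomial (dispersion 0.05), one shared baseline mean
  per tRF, log-normal library-size factors (sdlog 0.2) for realistic depth
  variation, and a planted fraction (default 0.1) whose mean is multiplied
  by `2^2` at day 7 only. The planted |log2FC| of 2 clears the screen's
  log2FC > 1 threshold with margin; the default planted fraction is kept
  at 10% so the majority-null assumption behind normalization holds.
* **UTR pairs**: the reverse complement of the query tRF embedded at a
  random interior position of a random background; the mutant substitutes,
  opposite each selected tRF position, the tRF base itself — which can
  neither WC- nor wobble-pair — so WT and MUT differ only at the mutated
  positions under the same seed.

What the generator does **not** emulate: sequencing errors, adapter
chimeras, quality-score structure, strand-specific library artifacts,
post-transcriptional modifications (which in real data cause
misincorporations and truncations at modified positions), multi-copy tRNA
families sharing identical mature sequences, and real decoy transcriptomes.
Passing recovery tests therefore demonstrate the *procedure's*
correctness — coordinate arithmetic, rule tables, test calibration — not
robustness to the measurement noise of real libraries.

# Problem sizes and determinism

All randomness flows from a single integer seed per configuration
(stage-specific offsets below 2^31), and identical configurations reproduce
byte-identical FASTA/FASTQ/TSV/JSON outputs; the pipeline report contains
no timestamps, and the suite asserts two demo runs agree byte-for-byte.
Simulation sizes were chosen for sharp statistics at interactive runtimes:
2,000 tRFs × 20 seeds for null calibration (binomial σ ≈ 0.005 on a per-run
false-positive fraction), 2,000 tRFs at 30% planted for power/recovery,
4,000-read demo pipelines, and 8-mers for the exhaustive duplex oracle
(12,870 pairings per sequence pair).

# Known limitations

* Landmarks are fixed offsets, not per-molecule secondary structures;
  unusual tRNAs (long variable arms, non-canonical D-arms) will have
  slightly misplaced loop intervals.
* Exact matching has no error tolerance beyond the optional ≤2-mismatch
  scan; real reads with modifications-induced mismatches would need an
  aligner.
* The duplex model's constants are self-defined units, not kcal/mol; use
  the energies comparatively, not thermodynamically.
* The DE screen models a single factor (day); batch or donor effects are
  out of scope.
* Junction-spanning placements are left unclassified rather than assigned
  to a seventh category; how such reads should be treated is genuinely
  open.
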
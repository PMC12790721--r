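# trfscape

Discovery, classification and screening of tRNA-derived fragments (tRFs)
from small RNA-seq data.

tRFs (also called tsRNAs) are small non-coding RNAs cleaved from precursor
or mature tRNAs. Based on where a fragment sits on its source tRNA, the
field assigns it to one of six classes: **tRF-5** (anchored at the mature
5′ end), **tRF-3** (anchored at the 3′ CCA end), **tRF-1** (from the 3′
trailer of the pre-tRNA), **i-tRF** (internal), and the **5′-** and
**3′-halves** produced by anticodon-loop cleavage. `trfscape` implements a
complete desk-scale pipeline for finding and screening such fragments in a
differentiation time course, plus the miRNA-like target-site prediction
used to nominate tRF binding sites in 3′-UTRs:

1. **Reference construction** — from a genome and tRNA gene annotations:
   introns are removed, `CCA` is appended to every mature sequence, and the
   50 genomic nucleotides past the CCA are attached, giving the searchable
   frame `mature + trailer` (positions `1..M+50`, with `M` the mature
   length). Cloverleaf landmarks (D-loop, anticodon loop, T-loop) are
   placed at fixed offsets from the canonical 76-nt tRNA.
2. **Read processing** — exact adapter trimming, a 12–50 nt length filter,
   hierarchical removal of reads matching ordered decoy sets
   (miRNA → rRNA → piRNA), and exact substring placement of survivors into
   the frames.
3. **Positional classification** — a first-match-wins rule table over the
   fragment's frame coordinates assigns one of the six classes (halves take
   precedence at anticodon-loop boundaries); identical placements collapse
   into candidate tRFs, each named by a decodable, injective
   sequence-derived label (`tRF-<length>-<code>`).
4. **Differential-expression screen** — tRF × sample counts over a day
   0/7/14/21 design are tested pairwise (0v7, 7v14, 14v21) with a
   negative-binomial quasi-likelihood F-test on median-of-ratios effective
   library sizes; a tRF is significant iff `|log2FC| > 1` and BH
   `FDR < 0.05` (equivalently fold change > 2 or < 0.5), and each tRF is
   assigned its peak day.
5. **Target scanning** — miRNA-like recognition of a tRF on a 3′-UTR:
   perfect Watson–Crick complementarity of tRF positions 2–8 (the seed),
   an additive alignment score, and an intermolecular duplex minimum free
   energy (pair energies GC −3, AU −2, GU −1, +0.5 per interior unpaired
   base; no intramolecular pairs, no crossing pairs).

A first-class synthetic-data module generates every input the pipeline
consumes — tRNA genes with and without introns on both strands, fragment
reads drawn per class with ground-truth labels, contaminants, count time
courses with planted day-7 peaks, and wild-type/seed-mutated UTR pairs —
so every stage is testable against known truth.

## Worked example

```r
library(trfscape)

res <- runPipeline(demoConfig(seed = 1))
cat(renderReport(res$report), sep = "\n")
```

Highlights of the report this prints (seed 1: 12 synthetic tRNA genes,
4,000 reads, 5% contaminants, 10% planted day-7 peaks):

```
## Read filtering
- input: 4000
- removed_short: 15
- removed_long: 85
- removed_mirna: 25
- removed_rrna: 36
- removed_pirna: 39
- unaligned: 0
- aligned: 3800

## Differential expression
Screen thresholds: |log2FC| > 1 and FDR < 0.05.
- 0v7: 178 significant
Day-7-peaking fraction: 0.100 (planted 0.100).

## Target scan
WT hits: 1; MUT hits: 0; verdict: site ablated.
```

Every read is accounted for in exactly one bin (4000 = 100 out-of-range +
100 decoy-matching + 3800 aligned); the fragment length histogram spans
16–35 nt; the screen recovers the planted 10% day-7-peaking fraction
exactly; and the embedded tRF-23 site is found in the wild-type UTR but
not in its seed-mutated counterpart (best WT duplex energy −61).

Individual stages are exported too:

```r
classifyFragment(start = 1, end = 20, M = 79, aloop_start = 32, aloop_end = 38)
#> "TRF5"
licensePlate("GGCGGTGAGAGCGCCGAATCCTA")
#> "tRF-23-G8T1BE8V0"
duplexMFE("GGGG", "CCCC")$mfe
#> -12
```

## Package layout

- `R/` — S4 `MatureTRNASet` container plus the simulation, reference,
  read-processing, classification, quantification/DE and target-scan
  modules.
- `vignettes/trf-discovery.Rmd` — the methods vignette: models,
  parameters, numerical choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
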
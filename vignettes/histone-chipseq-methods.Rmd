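---
title: "Methods: simulation, quality control and consensus peak analysis for histone mark ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone mark ChIP-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`histomark` re-implements, at desk scale, the computational workflow of a
multi-tissue histone modification ChIP-seq study: four marks (H3K4me1,
H3K4me3, H3K27ac, H3K27me3) in two biological replicates per tissue, each
tissue with one input library. The pipeline covers read filtering,
six-metric quality control, per-replicate peak calling with a narrow and a
broad (island) caller, replicate consensus combining, cross-tissue
specificity analysis, enrichment-track and metagene topology profiling, and
PWM motif enrichment over tissue-specific active enhancers. Because real
libraries of 30–80 M reads on a gigabase genome are out of reach for a test
suite, every claim is exercised on simulated libraries whose statistical
structure mirrors the real design; the simulator is itself a first-class,
tested module.

# The simulator and what it emulates

`sim_config()` fixes the study conditions. Reads are 50 bp single-end;
fragments are truncated normal with mean 200 bp and sd 20 bp (the protocols
target "approximately 200 bp" without stating a spread; a truncated normal
is the simplest unimodal choice, and the sd of 20 bp is a free choice
recorded here). Each fragment emits one read on a uniformly chosen strand:
the plus read starts at the fragment start and the minus read ends at the
fragment end, so the distance between plus and minus 5′-end density modes
equals the fragment length — exactly the quantity the cross-correlation
estimator must recover.

**Scale.** The default genome is 10 Mb (two chromosomes, 6 + 4 Mb) with
200,000 reads per library. This preserves the read density of ~30 M reads
on a ~2.4 Gb genome, so per-window counts, per-bin fingerprint counts and
complexity collision rates are of realistic magnitude. Planted elements are
1 kb; 300 shared elements plus 30 per-tissue specific elements give one
mark ~3% genome coverage, matching the genome fraction that peaks of an
active mark occupy in real tissue. All of these are configuration fields;
tests that need the pinned small structure (5 shared + 3 specific per
tissue) override them.

**Enrichment.** A ChIP library for mark *m* in tissue *t* draws fragment
starts from a mixture of uniform background and an
`enrichment_fold`-elevated rate (default 20) inside every element carrying
*m* in *t* (all shared elements, plus *t*'s own specific elements).
Tissue-specific elements always carry H3K4me1 + H3K27ac, making them active
enhancers by construction. Per-element rates are jittered between
replicates by a lognormal factor (sdlog 0.25) so replicates are similar but
not identical. Input libraries are pure background.

**Duplicates.** A `duplication_rate` fraction of tags (default 0.1) are
exact coordinate copies of already-emitted tags. The simulator does not
pre-flag them; the deduplication operation must find them, so the
complexity metrics are computed, never read.

**The phantom peak.** In real aligned data the strand cross-correlation
profile shows a spurious peak at the read length, caused by reads stacking
on the uniquely mappable islands around repeats: the same interval is
covered from either strand, which correlates plus and minus 5′ ends at a
lag of exactly one read length. Without this artifact the RSC statistic is
vacuous — the fragment peak is by definition the profile maximum outside
the exclusion zone, so RSC ≥ 1 identically and the RSC threshold can never
fail. The simulator therefore draws a small fraction of reads
(`phantom_rate`, default 0.005) at `n_phantom_sites` (default 100) fixed
hotspot positions with identical spans on both strands. For a well-enriched
library the fragment peak dwarfs this artifact; for a library without
enrichment the phantom peak dominates and RSC collapses, as in real failed
experiments.

**Planted motifs.** One concrete instance of an IUPAC consensus (default
`DAAAYA`) is substituted into each tissue-specific enhancer at a random
offset and strand, and recorded in the truth set. `motif_consensus` accepts
a vector recycled over tissues; with one consensus per tissue each motif
has a single owner tissue and can be *uniquely detected* there. With a
single shared consensus (the default), unique detection is impossible by
construction — the motif is planted everywhere — which is worth knowing
before interpreting `uniquely_detected()` on simulated data.

**What the simulator does not model**: sequencing errors and base
qualities, paired ends, mappability and GC bias, chromatin accessibility
correlation between marks, fragment-size selection tails, and real genome
sequence composition. Tests passing on these simulations demonstrate that
the estimators recover the planted structure under the stated statistical
model; they do not certify behaviour under artifacts the model omits.

# Quality control

Filtering follows the strict rules used for real alignments: drop unmapped,
secondary, vendor-failed and optical-duplicate tags and anything with
MAPQ < 30 (each removed tag is counted once, under the first criterion in
that order). PCR duplicates are keyed by (chromosome, 5′-end, strand) —
the right key for fixed-length single-end reads — keeping the first tag in
sorted order.

Complexity is computed on filtered, *not yet deduplicated* tags:
NRF = distinct positions / total tags, PBC1 = single-read positions /
distinct positions, PBC2 = single-read / double-read positions (reported as
`Inf`, always a pass, when no position is seen exactly twice).

The cross-correlation profile correlates, per chromosome, the plus- and
minus-strand 5′-end count vectors at shifts 0..500, pooling chromosomes by
a length-weighted average. The implementation evaluates the exact truncated
Pearson correlation sparsely (cost proportional to distinct positions, not
genome length). Numerical choices:

* the phantom exclusion zone is read length ± 10 bp (the window the
  fragment-peak search skips);
* the profile is smoothed with a triangular kernel of half-width 15 bp
  *only for locating* the fragment peak; reported `cc` values, NSC and RSC
  use the raw profile at the located shifts. The planted 1 kb elements make
  the fragment peak broad, and the raw argmax has ~±25 bp sampling noise at
  these depths; a centre-peaked kernel cuts that several-fold while leaving
  a sharp peak's argmax exactly in place;
* per-chromosome profiles with an empty strand are dropped from the
  average; a library with an empty strand overall is an error.

The fingerprint metric tiles the genome into 500 bp bins (the tool the
study names does not state its bin size; 500 bp is this package's default,
configurable), counts deduplicated tags per bin in ChIP and in input, forms
the probability mass function over per-bin count values for each library,
and reports the Jensen–Shannon *distance* (square root of the divergence,
log base 2, so the value lies in [0, 1]). The comparator is the matched
input library — the natural reading, though a uniform synthetic reference
would also be defensible.

Verdicts compare each metric strictly (`>`) against NRF 0.5, PBC1 0.5,
PBC2 1, NSC 1.05, RSC 0.8, JSD 0.05.

# Peak calling and consensus

Both callers score fixed windows: tags are extended to the 200 bp fragment
size in the 3′ direction and counted by fragment midpoint (each fragment
counted once, keeping window counts Poisson-like). The expected count per
window is `max(local, global)` where *local* is the input count smoothed
over 5 kb, scaled by the ChIP/input depth ratio, and *global* is the ChIP
rate over the effective genome (genome fraction × genome length; fraction
0.63 for the broad mark, 1 otherwise). The floor guards against
zero-coverage input windows. P-values are upper-tail Poisson; q-values are
Benjamini–Hochberg (the study states only "FDR"; BH is the standard
reading).

The narrow caller keeps windows with q ≤ 0.5 (the *relaxed* threshold, see
below), merges adjacent runs, sets the peak q to the best member and the
summit to the highest-count window midpoint, and flags peaks significant at
the mark's FDR cutoff. The island caller deems windows with raw Poisson
p ≤ 0.2 eligible, assembles maximal runs bridging up to 4 consecutive
ineligible windows, scores an island as Σ −log p over eligible members, and
converts that score to an island p-value by Fisher's combination
(χ², 2k df) — a simplification of SICER's island-score null, chosen because
it is fully specified and exactly testable.

**Consensus rule.** Replicates are combined by building the ≥1 bp overlap
graph between the two replicates' *candidate* peaks and keeping every
connected component that (a) contains at least one peak from each replicate
and (b) has at least one member passing the mark's FDR cutoff; the
consensus peak is the merged union span of the component. Two design
decisions deserve emphasis:

* "Regions of enrichment" are relaxed-threshold calls (q ≤ 0.5,
  configurable), not significant calls. This is the only reading under
  which a combined set can exceed the smaller replicate's significant call
  count — a phenomenon the real data show (a brain H3K4me1 replicate pair
  with 143k and 65k calls combining to 96k) and which the test suite
  reproduces on a constructed fixture.
* The consensus interval is the union span, not the pairwise intersection,
  consistent with broad-caller consensus sets covering more genome despite
  fewer peaks.

Chained overlaps (one peak in replicate 1 bridging two in replicate 2) are
resolved by connected components, so no region is emitted twice.

# Tissue comparison

The Jaccard index is base-pair intersection over union of merged interval
sets (undefined, an error, when both sets are empty). Unique peaks are
defined by *any* overlap: a consensus peak of one tissue is unique iff it
overlaps zero base pairs of the same mark's consensus peaks in every other
tissue; one shared base pair disqualifies it. Active enhancers are the
base-pair intersection of a tissue's H3K4me1 and H3K27ac sets, and a
tissue-specific active enhancer must overlap neither mark in any other
tissue (the stricter raw-mark reading; testing against other tissues'
enhancer intersections instead would be more permissive, and is not what
"no overlap of these marks" says). Replicate similarity (the Jaccard
matrix) is computed on per-replicate significant calls; specificity is
computed on consensus peaks.

# Profiles

Enrichment tracks are reads-per-million per bin (default 50 bp), input
subtracted from each replicate with negative values floored at zero, then
averaged — equivalent to average-then-subtract under equal scaling, but
keeping per-replicate subtracted tracks available for diagnostics. The
metagene matrix samples a 3 kb flank on each side at track resolution and
rescales each gene body to 100 columns (bin count and flank resolution are
not stated by the study; both are configuration fields here); minus-strand
genes are reversed so columns always run 5′→3′. Signal is not conserved
under body rescaling (interpolation); the tested invariant is that a
constant track yields an exactly constant profile.

# Motif enrichment

JASPAR-format count matrices become log-odds matrices with pseudocount 0.25
per cell against a uniform background; scanning slides the matrix over both
strands and reports positions scoring ≥ 80% of the matrix's maximum
achievable score (`N` scores as the worst base of its column). Enrichment
is a one-sided Fisher exact test on the 2×2 table of sequences with ≥1 hit
× foreground/background, BH-adjusted across motifs and ranked by adjusted
p — a deliberate, exactly testable simplification of AME's ranking
statistic. The default background is 5 first-order Markov (dinucleotide)
shuffles of each foreground sequence: a single shuffle per sequence leaves
the chance-hit-rate estimate noisy enough that a short degenerate consensus
can appear enriched in the wrong tissue by background undersampling alone.
Pooled other-tissue enhancers are available as an alternative background. A
motif is *uniquely detected* in a tissue iff its adjusted p is ≤ α (0.05)
there and > α everywhere else.

Short degenerate motifs (e.g. the 6-mer `DAAAYA`) occur by chance roughly
every 700 bp of random sequence per strand, so presence-based enrichment
loses power as foreground sequences grow: over 1 kb enhancers nearly every
sequence contains a chance hit. The planted-motif recovery tests therefore
use 200 bp enhancers with 30 per tissue — short enough that presence is
informative, many enough for Fisher significance.

# Pipeline, determinism and problem sizes

`run_stage()` executes simulate → qc → callpeaks → combine → compare →
profile → motifs, exchanging only files (tagAlign, narrowPeak/broadPeak,
consensus BED6+3 with provenance, bedGraph, TSV/JSON reports) and appending
a manifest entry with parameters and md5 checksums per stage; identical
config and seed reproduce identical checksums. One master seed drives
everything: each library derives its own stream by a stable hash of
(tissue, mark, replicate), so adding a library never perturbs another's
reads. Untouched defaults reproduce the published software parameters (FDR
0.05/0.01/0.01/0.1, fragment 200, window 200, gap 4, genome fraction 0.63,
effective genome size 2,409,143,234) and the QC threshold row.

Problem sizes used by the test suite and acceptance script, chosen as
desk-scale renderings of the study design: the QC reference study uses the
default 10 Mb genome with 200k-read libraries; fragment-size recovery takes
the median over 20 such libraries; oracle-equivalence checks run 1000
random 100 kb fixtures against per-base brute force; planted-structure
recovery runs 20 seeds of a 1 Mb, 3-tissue design with 5 shared + 3
specific elements.

# Known limitations

* The peak callers are simplified stand-ins: no bimodal shift model, no
  multi-scale local background hierarchy, no island-filtered read
  retrieval. They are designed to be exactly testable, not bit-compatible
  with MACS2/SICER.
* The Fisher-on-presence motif statistic discards hit counts and scores;
  with long sequences or very degenerate motifs it saturates (see above).
* JSD is computed on count-value PMFs; tools that compute it on coverage
  Lorenz curves will give different absolute values.
* Optical duplicates are honoured as input flags only; no tile-coordinate
  detection is attempted.
* The simulator's two-level sharing structure (all tissues vs one tissue)
  omits intermediate k-of-n sharing; the classification code does not
  depend on this, but recovery tests only exercise the two-level case.
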
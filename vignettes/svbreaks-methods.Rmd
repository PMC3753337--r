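---
title: "Detecting rearrangements and reading their junctions: methods behind svbreaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rearrangements and reading their junctions: methods behind svbreaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbreaks)
library(dplyr)
```

# The problem

Tumour genomes — neuroblastoma prominently among them — carry large
structural rearrangements: unbalanced translocations, deletions,
inversions and duplications spanning tens of kilobases to megabases,
and in a subset of cases chromothripsis, the catastrophic shattering of
one chromosome followed by re-joining of a random subset of the
fragments. Mate-pair sequencing detects these events economically: the
two reads of a ~3 kb circularised fragment map far apart, so a modest
number of read pairs "tiles" the genome physically even when base-level
coverage is below 1X. The informative quantity is the *effective
(clone) coverage*,

$$C_\mathrm{eff} = \frac{n_\mathrm{pairs} \times \bar\ell}{G},$$

the expected number of fragments spanning any given genomic point
(`effective_coverage()`); it is also the expected number of read pairs
supporting any single breakpoint.

svbreaks implements the full desk side of such a study: simulation of
rearranged genomes with exactly controlled junction structure, a
paired-end-mapping (PEM) signature caller, read-depth copy-number
segmentation, gene-impact annotation, base-pair junction resolution
with repair-signature classification, a null model and enrichment test
for junction microhomology, breakpoint motif scans, an RNA-seq
expressed-rearrangement test, and a chromothripsis detector. Everything
is exercisable end to end on synthetic data, so every stage is testable
against a known truth.

# The simulator defines the study conditions

`simulate_genome()` draws i.i.d. bases at a requested composition;
`plan_rearrangements()` places either independent simple events
(deletions, inversions, tandem duplications, unbalanced translocations,
drawn log-uniform between 50 kb and 5 Mb by default, honouring the
convention that "large" SVs exceed 50 kb) or a chromothripsis event
that shatters a designated chromosome into at least twice `n_events`
fragments, keeps each with probability one half, and reassembles the
kept fragments in random order and orientation. Under a diploid
rendering (`include_reference_homolog = TRUE` keeps one intact
homolog), kept fragments sit at copy state two and lost fragments at
state one — the two-state oscillation that is the copy-number face of
chromothripsis.

`simulate_mate_pairs()` emulates a ~3 kb mate-pair library (Gaussian
insert, default sd 300 bp, 50 bp reads) mapped back to the reference:
concordant pairs are stored in *outward orientation* — leftmost read on
the `-` strand, rightmost on `+` — which is the orientation a
circularised mate-pair library produces after mapping, and the contract
the PEM caller relies on. Reads overlapping a junction are dropped
(they would not map uniquely), and pairs whose fragment spans a
junction become discordant by construction.

What the simulator does *not* model: base-call errors and quality
scores, alignment ambiguity in repeats (the synthetic genomes are
i.i.d., so 20-mers are effectively unique), GC-coverage bias,
subclonality, and aneuploidies beyond the one intact homolog. Passing
tests therefore demonstrate the *logic* of each stage — signatures,
clustering, classification, statistics — not robustness to alignment
artefacts of real short-read data.

# Planting junctions with base-exact control

The scientific heart of the simulator is junction engineering. A
junction between donor segments A and B can carry:

* **microhomology** of m bases — a word shared by both donor flanks,
  making the breakpoint ambiguous over an (m+1)-placement slide
  interval (the signature of microhomology-mediated repair);
* a **blunt** join (m = 0, the classic non-homologous end-joining
  outcome);
* an **untemplated insertion** of 1–17 bp;
* a **genomic shard** — a short fragment copied from a distant locus;
* a **templated insertion of nearby sequence** (donor within 10 kb of a
  breakpoint), the footprint of replicative template switching
  (FoSTeS/MMBIR).

Microhomology is planted by overwriting the first m reference bases of
the acceptor segment with the donor segment's continuation *before any
sequence is rendered*, so reference and derivative agree and the m-base
word genuinely occurs in both donors. One base at each end of the slide
interval is then adjusted so the realised homology cannot extend by
chance; planted m is thereby exact. When two junction contexts overlap
(it can happen between the two ends of an inversion), the blocking base
may be unavailable; the ground truth then records the *realised* slide
length measured from the final reference, so truth and sequence can
never disagree. Untemplated insertions get their terminal bases
adjusted so they cannot be absorbed into either flank alignment; shard
and templated fragments are copied verbatim with all four boundaries
blocked.

`shard_min` = 10 kb separates "templated insertion of nearby sequence"
from "genomic shard". The literature says only that shards come from
"some distance"; 10 kb is this package's convention, shared between
simulator and resolver and configurable in both.

# PEM-signature SV calling

`fit_insert_model()` estimates the insert distribution robustly
(median and 1.4826·MAD, with one trimming pass at `k_sigma` so
discordant contamination up to ~10% does not bias it). The concordant
window is $\mu \pm k_\sigma\sigma$ with $k_\sigma = 4$: the Gaussian
tail beyond 4 sigma (~6 per 100,000 pairs) keeps false discordant
pairs rare at 10X clone coverage. `classify_pairs()` is total: every
pair is exactly one of normal/abnormal, abnormal pairs carrying their
raw signature (orientation pattern × insert deviation × inter/intra).

`cluster_links()` groups discordant pairs of identical signature by
single linkage with a window of $\mu + k_\sigma\sigma$ on both ends,
discarding clusters under `min_support = 2` pairs (the study design
suggests ~8–14 pairs per SV at 8–14X, so two is a permissive floor).
The decision table in `assign_pem_type()` reproduces the eight
signature categories from orientation/spacing logic alone: stretched
outward links are deletions; shrunk outward links, insertions of a
known short fragment; same-strand links are inversions — confirmed at
both ends (`INV_FRAGMENT`) when a reciprocal same-strand cluster of the
opposite sign flanks the same locus pair, at one end (`INVERSION`)
otherwise; order-swapped ("inward") links wider than the insert are
tandem duplications; inter-chromosomal links are translocations when
outward-compatible, otherwise generic inter-chromosomal links. A
planted inversion legitimately yields *two* reciprocal links (one per
junction); the recovery tests treat one or two correctly-typed links as
success for inversions, and exactly one link for the other types.

# Copy-number profiling

`window_counts()` counts read starts in fixed windows (30 kb resolves
copy changes in real mate-pair data; the simulations here use 5 kb
windows against smaller genomes). `normalize_and_segment()` divides by
the genome-wide median window count, optionally rescales deviations by
a known tumour-cell purity, and segments each chromosome by recursive
binary splitting: a split is kept only if it reduces the squared error
by more than $\lambda\,\hat\sigma^2\log n$, with $\hat\sigma^2$
estimated robustly from window-to-window differences and $\lambda$
either fixed (3 in the examples here, a BIC-like choice) or chosen by
2-fold odd/even-window cross-validation.

Integer states are *not* simply `round(ploidy × ratio)`: when a
chromosome splits close to 50/50 between two copy states, the median
window count can land in the gap between the two populations and shift
every ratio off the integer grid. A global scale factor is therefore
calibrated by minimising the window-weighted distance of segment
ratios to the integer copy grid (preferring the admissible scale
closest to one), after which states are rounded and equal-state
neighbours merged. Segment boundaries land within one window of planted
breakpoints for segments of at least five windows; below that scale
calls are unreliable, which the chromothripsis detector accounts for.

# Junction resolution and classification

`resolve_junction()` mimics the analysis of a Sanger-sequenced
junction PCR product: exact `min_anchor`-mer seeds (default 20 — with
$4^{20} \gg$ genome size, unique in any genome this package simulates)
at both read ends, ungapped maximal extension, and the junction
structure read off the two alignments. Their overlap on the read *is*
the microhomology; a gap is a candidate insertion, re-mapped to decide
untemplated insertion versus shard versus templated insertion (gaps
under 15 bp are never re-mapped — too short to place uniquely). Reads
resolving to three segments yield one call per adjacent pair, so
shard/templated rearrangements count two junctions and are labelled
complex by `count_rearrangement_complexity()`.

Reported coordinates follow the maximal-prefix convention:
microhomologous bases are assigned to segment A, and `mh_len` records
the slide. `measure_microhomology()` implements the slide definition
directly (left extension + right extension) and is property-tested
against an exhaustive split-point search. Mismatch tolerance is
deliberately absent: Sanger-quality synthetic reads are near-perfect,
and exactness is what makes the round-trip tests sharp.

# The microhomology null model

Under independent joining of unrelated sequences, each slide direction
extends by a geometric number of matching bases with per-base match
probability $p = \sum_x f_x^2$ over the base frequencies $f$. The total
microhomology $M$ (sum of two independent geometric extensions) has

$$P(M = m) = (m + 1)\,p^m (1 - p)^2, \qquad m \ge 0,$$

so with uniform composition $P(M \ge 1) = 7/16 \approx 0.44$ — chance
alone makes microhomology common, which is why a formal test is needed
before reading mechanism into it. `mh_chisq()` compares observed
lengths against this null with bins $0, 1, \ldots, K{-}1, \ge K$, $K$
chosen so all expected counts are at least one and at least 80% are at
least five (Cochran's rule). `stratified_report()` runs the test
separately for chromothripsis and non-chromothripsis junctions and
tabulates per-sample microhomology/blunt/insertion counts;
insertion-class junctions are excluded from the test, as they carry no
microhomology by definition. The null composition can be matched to
the sequence around the observed breakpoints (250 bp windows, the same
as the motif scan) rather than assumed uniform.

The exact theoretical construction used in the original studies of
this question is not published alongside their tables; the
independent-flank slide model above is this package's stated null, and
the `sv_mh_null` object is the single pluggable point if a different
null is wanted. Printed p-values of the form 1e-36 depend on the real
junction sets and are not reproduction targets; the package instead
verifies its test's type-I error (0.03–0.07 at nominal 0.05, n = 59)
and its power under planted enrichment.

# Motif and composition scans

`scan_motifs()` counts breakpoints whose 40 bp (immediate) or 250 bp
(short-proximity) centred window contains a motif match on either
strand; `motif_enrichment()` compares against `n_background` random
position sets matched per chromosome, with add-one-smoothed empirical
p-values and Benjamini–Hochberg adjustment across motif×window
combinations. An empirical permutation test was chosen over a binomial
approximation because genome heterogeneity makes per-position hit
probabilities non-uniform. The shipped catalog
(`default_motif_catalog()`) is a small, editable set of motifs
repeatedly proposed in rearrangement biology (S/MAR AT-rich rule,
topoisomerase I/II consensus, translin sites, deletion-hotspot
consensus, and friends); the machinery is catalog-agnostic and any TSV
with name/pattern/max_mismatch columns can be scanned.
`composition_stats()` adds GC, polypurine, polypyrimidine and
alternating purine/pyrimidine run lengths with background z-scores.

# Expressed rearrangements

Only SVs annotated `Possible chimera` or `May change function` can
produce detectable abnormal transcripts, so only those are eligible.
`support_pairs()` accepts an RNA-seq pair as evidence iff one end maps
within the 5' partner on the retained side of its breakpoint — in an
exon, or in the single intron containing the breakpoint (the narrowest
reading of "intronic regions adjacent to the breakpoints") — and the
other end symmetrically in the 3' partner, with read strands matching
each partner's transcription sense (anti-sense pairs are not support).
An SV is *expressed* iff at least two supporting pairs exist; the
threshold property (flipping exactly at two) is tested explicitly.
`expression_summary()` partitions eligible SVs three ways: expressed,
partner genes silent (no RNA-seq pairs over a partner at all), and
genes expressed but junction unsupported.

# Chromothripsis detection

`chromothripsis_score()` combines four per-chromosome components:
adjacent-segment state switches (≥ 10), distinct copy states (≤ 3),
the window-weighted share of segments in the two dominant states
(≥ 0.9) and the share of all SV link ends on the chromosome (≥ 0.5).
All four must pass. Segments narrower than five windows are excluded
from the state statistics: below the five-window recovery scale they
are boundary slivers or depth chatter, and counting them produces both
missed detections (diluted oscillation share) and false flags
(chatter-generated switches). Chromosome pairs connected by at least
five inter-chromosomal links are additionally scored as a joined unit,
capturing two-chromosome shattering. No published numeric criterion
set is being reproduced here — the thresholds are this package's
explicit reconstruction of the phenomenology, and all are arguments.

Detector calibration in this package's tests: sensitivity ≥ 0.95 over
100 seeded chromothripsis genomes (1.6 Mb shattered chromosome, 40
fragments, 10X clone coverage, 5 kb windows) and zero flags over 100
matched simple-SV genomes.

# Problem sizes and numerical choices

The simulations in the test-suite and acceptance script use genomes of
0.5–1.8 Mb, 8–10X effective clone coverage, 5 kb copy-number windows
and 30–100 replicates per property — sizes chosen so the full suite
exercises every claim at comfortable statistical resolution on a single
CPU. Key defaults, all configurable: insert 3000 ± 300 bp, `k_sigma`
4, `min_support` 2, large-SV threshold 50 kb, `min_anchor` 20 bp,
`shard_min` 10 kb, promoter window 2 kb upstream of the TSS,
segmentation penalty λ = 3 (or cross-validated), expressed-SV
threshold 2 pairs. Seeds are explicit arguments everywhere; no
function touches the global RNG state.

Known limitations, beyond the simulator's idealisations listed above:
the PEM table does not attempt balanced-translocation reconstruction
from multiple links; the copy-number stage has a GC-correction hook
but no fitted bias model; the junction resolver assumes near-perfect
reads; and the RNA stage quantifies junction support, not transcript
abundance.
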
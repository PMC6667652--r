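---
title: "Methods: two-condition nucleosome and chromatin-state dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition nucleosome and chromatin-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

chromdyn compares chromatin organisation between two conditions — the
motivating setting is a transcription-factor knockdown (MYCN in
neuroblastoma cells) against a control — from three kinds of input:
MNase-seq fragment intervals, histone-modification ChIP-seq read midpoints
with an IgG control, and pre-called peak sets (H3K4me1 enhancer peaks and
transcription-factor binding peaks). Everything downstream of read
alignment is in scope; alignment, duplicate removal, peak calling and
RNA-seq quantification are not, and are consumed as exported tables.

All internal coordinates are 0-based half-open (BED native). Gene tables
exported from 1-based tools must be declared as such (`read_gene_table(...,
one_based = TRUE)`) and are shifted on load. Upstream/downstream windows
are strand-aware throughout: "2 kb upstream of the TSS" flips direction for
minus-strand genes.

## Nucleosome calling

The midpoint of each proper MNase fragment estimates the nucleosome dyad.
Per chromosome, dyad counts are smoothed with a Gaussian kernel
(sd `sigma` = 20 bp, truncated at 4 sigma); local maxima of the smoothed
profile are candidate dyads; candidates are accepted greedily by
descending smoothed height while suppressing anything closer than
`exclusion / 2` = 73.5 bp to an accepted call, so no two calls are nearer
than half a nucleosome. The kernel sd and the 147-bp exclusion zone are
the established defaults for nucleosome-resolution MNase data and are
exposed as parameters.

Each call's read count `rc` sums dyad multiplicities within ±73 bp (one
footprint); calls with `rc` < 6 are discarded to control false discovery.
Occupancy is reported as `rc` per million indexed dyads — a CPM-style
normalisation chosen here because "normalized read count" admits several
readings; it is monotone in `rc` and comparable across libraries.
Fuzziness is the *population* standard deviation of member dyad offsets
from the called dyad; the population form is chosen so a single-member
call has fuzziness exactly 0 rather than an undefined value. Member
assignment (±73 bp of the called dyad) can in principle double-count a
dyad between two calls spaced 74–146 bp apart; the membership window is
part of the fuzziness definition and is kept symmetric rather than
partitioned.

Replicate reproducibility is assessed as the Pearson correlation of
RPKM-normalised counts on a 10-kb genome grid; replicates passing a
threshold (default 0.8) are conventionally pooled before calling. Signal
tracks use the same RPKM formula at 10-bp resolution.

## Dynamics classification

Nucleosomes from the two conditions are paired per chromosome as *mutual
nearest neighbours* by dyad distance, with ties broken towards the smaller
coordinate. Mutual nearestness is the deterministic completion of "the
two closest nucleosomes form a pair": it guarantees each nucleosome joins
at most one pair. A pair with distance 0 is `fixed`; distance in
[1, 117) bp is a `shift` (the two 147-bp footprints still overlap by more
than 30 bp); pairs at ≥ 117 bp are dissolved into one `loss` plus one
`gain` and flagged `dissolved`, since nothing distinguishes them from an
unpaired eviction plus an unpaired assembly. Unpaired control nucleosomes
are losses (evicted); unpaired knockdown nucleosomes are gains
(assembled). The distance formulation of the shift band is primary; the
equivalent overlap phrasing (overlap > 30 bp) follows from it.

The canonical nucleosome-free region (NFR) spans 200 bp upstream to 50 bp
downstream of the TSS (250 bp, strand-aware). An NFR counts as *occupied*
when any called footprint (dyad − 73 .. dyad + 74) overlaps the window by
at least 118 bp — the integer ceiling of 80% of a 147-bp nucleosome,
rounded up so the rule errs conservative. The same threshold is applied
symmetrically in both conditions; the source rules only define the
transitions, and symmetry is the minimal completion. Status per gene:
`lost` (open in control, occupied after knockdown), `gained` (the
opposite), `retained`, or `absent_both`.

Occupancy heat maps around NFR sets are built as strand-oriented
region × bin matrices and clustered with K-means (default K = 5, seeded,
`nstart = 5`); labels are reproducible given the seed.

## Chromatin-state segmentation

Mark signal is binarized on a 200-bp genome grid against the IgG control:
the expected bin count is the control count scaled by the mark/control
library-size ratio (falling back to the genome-wide mean mark count per
bin where the control is empty), and a bin switches on when the Poisson
upper tail P(X ≥ observed) ≤ 1e-4 — the threshold convention of the
standard binarization tools. Binarized tracks for an ordered mark pair
(H3K9ac/H3K27me3 for promoters, H3K27ac/H3K27me3 for enhancers) are
combined bin-wise into four states (A-only, B-only, both, none) and runs
of equal state merge into segments that tile the genome exactly.

This deterministic binarize-and-combine stage *replaces* HMM-based
chromatin-state training. The target semantics is a four-emission-state
model over two marks, and under near-deterministic emissions the HMM
posterior reduces to the per-bin truth table; the substitution removes an
external training step while preserving the state definitions. It is a
deliberate simplification: no transition smoothing is applied, so
single-bin state islands are kept rather than absorbed.

A promoter (window: TSS − 2 kb .. TSS + 1 kb, strand-aware) containing a
`both` segment, or both an A-only and a B-only segment, carries both marks
(the bivalent class when the pair is H3K9ac/H3K27me3); exclusively A-only
segments give the A state, B likewise; otherwise none. "Contains" means
any nonzero overlap (configurable minimum). The same rule assigns enhancer
states over the H3K27ac/H3K27me3 pair: an enhancer with no H3K4me1 peak in
a condition is `off`; otherwise `intermediate` (both marks), `active`
(exclusively H3K27ac), `poised` (exclusively H3K27me3), or `primed`
(H3K4me1 only).

## Enhancers

H3K4me1 peaks within 2 kb of any TSS are removed so enhancers never
overlap promoters. Peaks from the two samples are merged when they
overlap by at least 50% *of the shorter peak* — the explicit form of the
merge rule, applied uniformly — keeping the higher-scoring peak's
interval and recording both original lengths. Peaks overlapping 1–49%
are both retained as distinct single-sample enhancers: the source rules
define only the ≥ 50% and disjoint cases, and keeping both is the
information-preserving completion. Conflicts among overlap candidates are
resolved greedily by descending overlap with coordinate tie-breaks, which
makes the merge independent of input order.

Width change is defined only for enhancers with a peak in both samples:
`broader` when the knockdown peak is strictly over 1.5-fold wider,
`shorter` in the opposite direction, else `stable`. A region is
MYCN-bound iff at least one binding peak overlaps it. The target gene is
the nearest TSS within 50 kb of the enhancer midpoint (a gene may be
targeted by several enhancers); enhancer–promoter association for the
independence analysis uses the nearest promoter within 100 kb. The two
distances are distinct parameters on purpose — they serve different
analyses and are not reconciled. "Nearest" is always midpoint-to-anchor,
with equidistant ties resolved towards the smaller coordinate.

## Independence testing

Associated pairs are cross-classified by promoter state change and by an
enhancer change class (on/off interconversion, activity change, or width
change), giving 2×2 tables. The test is the Pearson chi-square *without*
continuity correction,
χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)), df = 1. The source tables do
not name their test; the uncorrected Pearson form reproduces all six
published p-values to the printed 2 decimals (the Yates-corrected form
does not), which is the available evidence, so it is the default and
Fisher's exact test is offered as an option. The active/non-active
dichotomy used in the classifiers maps "active" to any state containing
the active mark of the pair; the mapping is a configurable convention
(`collapse_active()`), since the published analysis never defines it.

Calibration is checked by simulation: under the paired-label null model
(`generate_contingency_world()` with odds multiplier 1) the empirical
type-I error at α = 0.05 over 10,000 tables of 500 pairs is within
0.05 ± 0.01, and at odds ratio 4 with 500 pairs power exceeds 0.9. The
dependence model fixes both marginals and the odds ratio (the unique 2×2
joint with those constraints) so the multiplier cleanly interpolates from
independence.

## What the synthetic generator emulates — and what it does not

`simulate_truth()` lays out a desk-scale genome: 2 chromosomes × 2 Mb,
200 genes at 20-kb spacing on alternating strands, one enhancer 8 kb
3' of each TSS. Planted events (50 NFR losses, 50 NFR gains, 50 shifts,
100 promoter switches, 100 enhancer switches, 20 + 20 width changes,
50% MYCN-bound) are recorded in a truth object; recovery is always scored
against that record. Seeds derive one RNG stream per output from the
master seed plus a file tag, so outputs are byte-identical across reruns
and independent of generation order.

MNase fragments are 147 bp centred on normally jittered dyads (sd 5 bp),
with Poisson(λ = 20) fragments per nucleosome — enough that true
nucleosomes comfortably survive the rc ≥ 6 filter. The knockdown
condition reuses the control draws and applies only the planted edits;
with zero planted events the two conditions are byte-identical and every
call is `fixed`, which is the generator's null-case contract. Planted
shift magnitudes are drawn from 10–99 bp: strictly below half the 200-bp
array spacing, because a shift of exactly half the spacing lands the
nucleosome equidistant between its origin and the next array position,
where no pairing rule can identify the planted pair.

Mark tracks draw per-bin counts at background 2 reads per 200-bp bin and
20 inside footprints (10× enrichment). The background depth corresponds
to a 20–40M-read library at 200-bp resolution and was chosen once, at
design time, so that a 5-bin enhancer footprint has adequate per-footprint
detection power under the Poisson binarization; the enrichment ratio, bin
size and all thresholds are the standard values above.

The generator does **not** emulate: sequence content or mappability,
fragment-length variation, replicate-specific batch effects beyond
Poisson noise, overlapping or nested genes, enhancer clusters /
super-enhancers, or copy-number variation. Passing recovery tests
therefore demonstrates that the *rules and statistics* are implemented
correctly and are recoverable under clean Poisson noise — not that the
pipeline is robust to every artefact of real chromatin data.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run the full chain on the
2 × 2 Mb genome (about 33,000 fragments and 20,000 bins per condition),
10,000 simulated tables for calibration, and 10⁶ hypergeometric draws for
the permutation cross-check of the chi-square p-value — sizes chosen so
the whole suite completes in a few minutes on one core while keeping
every Monte-Carlo margin far from its threshold. Exact conditional
(permutation) p-values differ from the asymptotic chi-square p by the
discreteness of the hypergeometric support (up to ≈ 0.04 at the published
table sizes), so the permutation check asserts agreement to 0.05
absolute, while the statistic itself is checked algebraically.

Other numerical conventions: dyads are `floor((start + end) / 2)`;
smoothing uses an exact truncated-kernel convolution (no FFT), so
profiles are reproducible to the last bit; plateau local maxima take the
leftmost position; greedy selections order by (height, then coordinate);
K-means is seeded. Degenerate inputs follow fixed rules — empty fragment
input gives an empty index, an empty mark track binarizes to all-off with
a warning, zero-variance replicate tracks give `NaN` correlation with a
warning, and a 2×2 table with a zero marginal refuses the test rather
than reporting a misleading p.

## Applying the pipeline to real data

Genome-scale biological counts — the share of changed nucleosomes that
are evictions/assemblies, the number of promoters with NFR loss and MYCN
binding, total enhancer counts, primed/off interconversion percentages —
depend on the full deposited data sets and are deliberately not asserted
anywhere in this package. To compute them, export fragment BEDs,
midpoint BEDs, peak files, and a gene table from the aligned data
(mapq-filtered, deduplicated, replicates pooled after passing the
correlation check), point `run_pipeline()` at those files in place of the
simulated ones (each stage reads and writes plain TSV/BED, so stages can
be substituted independently), and read the fractions off
`dynamics.tsv`, `nfr_status.tsv`, `promoter_transitions.tsv` and
`enhancers.tsv` — the same tallies the synthetic run produces.

## Known limitations

- The binarize-and-combine stage has no transition model; sparse data
  produce more single-bin segments than an HMM would.
- Mutual-nearest pairing is local: a genuinely shifted nucleosome whose
  displacement exceeds half the local spacing is indistinguishable from
  an eviction/assembly pair, and is reported as such.
- Occupancy normalisation is per-million-dyads; cross-condition occupancy
  comparisons assume comparable digestion efficiency.
- The chi-square test is asymptotic; for tables with small expected cells
  use `method = "fisher"`.
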
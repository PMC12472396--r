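---
title: "Detecting diversified 3' termini in small RNA-seq data with termflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversified 3' termini in small RNA-seq data with termflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termflex)
```

## The problem

Bacterial cells release short RNA fragments (roughly 16-50 nt) cleaved
from tRNAs, rRNA operon transcripts and other structured RNAs. Some of
these fragments carry non-templated nucleotides at their 3' ends --
homopolymeric tails, short additions of any sequence, or longer
attachments that look like ligated foreign oligonucleotides. In *E. coli*,
5'-terminal fragments of the four identical leucine tRNAs (LeuT, LeuV,
LeuP, LeuQ) are an extreme case: a shared 19-mer accumulates random 3-9 nt
extensions so diverse that a large fraction of the possible motif space is
observed. termflex packages the computational machinery needed to find and
quantify this phenomenon in small RNA-seq data: exact 5'-end profiling, a
differential secretion screen, rule-based deviation classification, a
Shannon-diversity scan for loci emitting randomly extended fragments,
motif-richness summaries, and fold-change statistics for
oligonucleotide-treated communities. A deterministic simulator with
planted ground truth makes every stage testable without external
downloads.

## Data model and pre-processing

Genomes are uppercase DNA with 1-based inclusive coordinates; RNA input
(`U`) is transliterated to `T` at ingest so genome references and
synthetic oligonucleotide listings share one alphabet. Reads are kept when
at least 90% of their bases reach Phred Q20 (`qc_params()`), 3'-adapter
remnants are removed by truncating at the first occurrence of the
adapter's 5'-terminal 15-mer `ATCACCGACTGCCCA`, and only 16-50 nt inserts
are retained. The pipeline order is fixed -- quality filter, adapter trim,
length selection -- and the count surviving the final stage defines
`n_qc`, the normalization denominator. Whether quality filtering precedes
or follows adapter trimming is a convention of this package; with
Q20-filtered data the two orders give practically identical results.
5'-adapter removal is deliberately absent: the targeted library chemistry
leaves negligible 5' contamination.

## Exact 5'-end mapping

`map_read()` finds every exact occurrence of a read on both strands.
Plus-strand occurrences report the leftmost genomic base of the match;
minus-strand occurrences report the rightmost one -- in both cases the
biological 5' end. Reads matching several loci are attributed to all of
them in equal fractions, and overlapping self-occurrences count as
distinct loci. Reads containing `N` are unmapped by definition. Matching
is delegated to an exact substring search with overlaps enabled; a naive
sliding-window scan serves as the independent oracle in the tests.
`build_profile()` sums the fractional 5'-end weights of reads of all
lengths per position and scales per one million quality-controlled reads.
Normalizing by `n_qc` rather than by mapped reads matters here: libraries
rich in modified (hence unmappable) fragments would otherwise be inflated.
Replicate consistency is assessed with the Pearson correlation over the
concatenated per-position values of both strands.

## The differential secretion screen

The screen compares four conditions (wild type / mutant, intracellular /
secretome), each averaged over replicates. Normalized counts are summed in
sliding 5 bp windows with a 1 bp step; a window becomes a candidate when

* the larger of the two secretome means reaches 25 normalized reads,
* the wild-type/mutant secretome ratio is at least 1.5, and
* the mutant/wild-type intracellular ratio is at least 1.0.

Overlapping qualifying windows merge into loci; the peak is the position
of the per-position wild-type secretome maximum inside the locus, leftmost
on ties. Three points were genuinely open and are decided here as
package conventions: the 25-read floor is applied to the larger of the two
secretome window means (using the maximum avoids discarding loci silenced
in one condition); "comparable or elevated" intracellular levels are
quantified as a ratio floor of exactly 1.0 with a configurable tolerance
defaulting to 0 (the strictest reading); and zero denominators yield an
infinity marker that passes any `>=` comparison, with `0/0` scored as
parity. No multiple-testing correction is applied at this stage -- the
screen is a candidate generator, not a hypothesis test.

## Deviation classification

Reads are assigned to a locus by an exact 12-14 nt 5' anchor and their
post-anchor portion is aligned to the genomic continuation by banded edit
distance (band 3, unit costs) -- a reproducible replacement for manual
spreadsheet/alignment-based curation. The maximal trailing run of read
bases not aligned as matches is the 3' extension; it is classified as

* **non-template addition**: 1-3 nt of any sequence, or longer runs with
  at most 2 distinct nucleotides;
* **chimera**: at least 4 nt with at least 3 distinct nucleotides.

Aligned substitutions outside the read's terminal triplets (the first and
last 3 bases) are mismatches; aligned gaps are indels. Each read counts
once in the category tally -- extension categories take precedence, then
indel, then mismatch -- while all individual deviations are recorded.
Alignment ties are resolved deterministically: the endpoint closest to the
diagonal wins, and gaps are pushed rightmost. "Terminal triplets" are read
termini here (the extension-terminus reading is the other defensible
interpretation); since anchored collection fixes the 5' end, only 3'
extensions are scored.

One identifiability limit deserves emphasis. A planted tail whose bases
coincide with the genomic continuation is genuinely indistinguishable from
templated sequence, and a tail resembling a shifted copy of the
continuation can be absorbed as an indel by any unit-cost aligner. On
random tails over a random genome this reabsorbs a noticeable fraction of
short extensions; classifier recovery is therefore assessed on simulated
loci whose continuations are disjoint in alphabet from the planted tails
(poly-T continuations, T-free tails), where categories are unambiguous and
recovery is essentially perfect. Real extension-rate estimates inherit the
same conservatism: they undercount tails that resemble the genome.

Deviation frequencies across two replicates follow fixed gates: both
replicates at 100+ reads are averaged per category; otherwise a pooled
total of 80+ reads is summarized jointly; below 80 the locus is ignored.

## The random-extension scan

For a fixed anchor length `k` (13-22) and flank length `L` (4-10), the
scan processes reads of exactly `k + L` nt, discards any read that occurs
full-length anywhere in the genome, and keeps reads whose 5' k-mer occurs
in the genome and whose L-flank *diverges* from the genomic continuation:
at most `L - 4` positional matches (for `L = 4`, complete divergence). A
continuation truncated by the genome end counts every missing base as a
mismatch, which favors divergence and is documented as such. Qualifying
reads are attributed at full weight to every occurrence passing the rule;
groups sharing at least half of their read copies with another position
are annotated as potentially cross-contributed, since near-identical
anchors (e.g. two genes sharing a 13-mer prefix) attract each other's
reads.

Per (position, strand) group, diversity is the Shannon index over unique
read sequences, `H = -sum(p_i ln p_i)` in nats, computed on raw copy
numbers (frequencies are scale-invariant, so normalization cannot change
`H`). Because `H` depends non-linearly on the read profile, values from
different `(k, L)` runs are never averaged -- `grid_scan()` keeps the
per-position maximum, with the lexicographically smallest `(k, L)` on
ties, and flags positions with `max H > 2.0`. The grid is fully
user-configurable with 13-22 x 4-10 as the default; no fixed cell count is
hard-coded. Reads longer than `k + L` are simply not processed by that
grid cell (each read length is served by the cells with matching
`k + L`); an optional crop mode is deliberately not a default.

For scale: uniform usage of all 256 tetramer flanks bounds `H` at
`ln 256 = 5.55`; a locus with ~140 distinct flanks among 200 reads sits
near `H = 4.8`, while a locus emitting a single sequence scores 0.

## Motif richness and extension rate

Richness is the percentage of observed unique extensions of an exact
length relative to the full motif space -- 4, 16, 64 and 256 for mono-
through tetranucleotides; a 5-mer extension does not contribute its 4-mer
prefix. The extension rate is the percentage of collected reads with a
non-empty 3' extension. Averaging across libraries is left to the caller.

## Community response statistics

Genus count tables (e.g. a Kraken2-style abundance export) receive one
pseudocount in zero cells, are converted to within-sample percentages,
and per-subject fold-change ratios (treated/control) are tested against a
null ratio of 1 with `z = (mean - 1) / (sd / sqrt(n))`, using the sample
standard deviation (n-1 denominator) and the one-sided standard-normal
tail of `|z|`, with direction carried separately. The tail is evaluated
directly in the upper tail, so it remains accurate for large `|z|`, and
`log_p` is reported alongside for z-scores beyond double range. Inclusion
requires 0.01% representation in the direction-relevant sample in at
least 4 of 5 subject pairs. Variability of pooled ratios is summarized by
the mean absolute deviation around the mean (not the median-based MAD).
Both response directions are reported with explicit labels; no sign
convention is imposed on the volcano data.

## The simulator

`sim_config()` / `make_genome()` / `simulate_library()` generate uniform
A/C/G/T genomes (with optional literal embeddings, e.g. a known 19-mer at
a chosen position) and libraries of fragments cleaved at planted loci on
either strand. Extension models: none, templated continuation, A-rich
homopolymer tails (default 80% A / 20% C, geometric length capped at
10 nt), random N-mers (optionally resampled until they pass the
divergence rule against the true continuation), and a fixed chimeric
nanomere `GCCAAGGCG`. Uniform substitution and single-indel noise and
3'-adapter remnants are applied after extension; qualities are constant
Q30. One pseudo-random stream per run makes libraries byte-identical
under a fixed seed. Per-locus depth multipliers plant condition-dependent
abundance differences for the screen.

What the simulator does not emulate: Ion Torrent flow-space error
profiles, realistic library-size distributions, positional quality decay,
or 5'-end heterogeneity beyond the planted cleavage sites. Passing tests
on simulated data therefore demonstrate the correctness of the rules and
arithmetic, not robustness to platform-specific artifacts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every rule with comfortable statistical margins: 20 kb genomes
with 20 planted loci and ~7000-read libraries for the screen (planted
2-fold secretome losses with modestly elevated mutant intracellular
levels, against flat null loci); 10 kb genomes with one random-flank and
one templated locus at 200 reads each for the diversity scan; exhaustive
enumeration up to 6-mers for the extension classifier and all 256 x 256
tetramer pairs for the divergence rule. Shannon values are validated
against brute-force evaluation to 1e-12; community statistics against
direct spreadsheet-style recomputation to 1e-9. Ratios guard division by
zero with infinity markers; all tie-breaks (peak position, grid cell,
alignment path) are deterministic so identical inputs yield
byte-identical outputs.

## Known limitations

* Exact matching only: a sequencing error inside a fragment's templated
  part makes it invisible to the profile and the screen, and an error
  inside an anchor drops the read from classification.
* The screen has no error control across windows; candidate loci need
  orthogonal confirmation.
* Extension rates are conservative for tails resembling the local genomic
  continuation (see above).
* Cross-attribution between near-identical anchors is annotated, not
  resolved; resolving it requires inspecting the flanking motifs, as the
  annotation's shared-read report enables.
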
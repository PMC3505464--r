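---
title: "Methods: small-RNA annotation, hairpin discovery and chip profiling in mirfill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA annotation, hairpin discovery and chip profiling in mirfill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfill)
```

# Scope and model

`mirfill` re-implements a classic plant small-RNA workflow for the rice
grain-filling phase — read cleanup, exact genome placement, known-miRNA
annotation, novel hairpin discovery, miRU-style target scoring and
three-stage miRNA-chip analysis — as deterministic, individually testable
functions. Because the original sequencing data are not available, the
package treats the published summary tables as inputs (bundled under
`inst/extdata/` and exposed via `stage_expression_table()` and
`novel_mirna_table()`) and relies on a synthetic-data module with known
ground truth for everything that requires reads.

# Read preprocessing

Reads are canonicalised to DNA space (U→T) at ingest; all internal
matching is in DNA space and miRNA sequences are rendered back as RNA at
reporting boundaries. Cleanup applies, in order: optional 3′ adapter
trimming (leftmost occurrence of an adapter prefix with ≥ `min_overlap`
exactly matching bases; reads without any adapter occurrence are rejected
as artefacts rather than genuine short inserts), an 18–26 nt length
filter, discarding of reads containing N, and removal of reads occurring
as exact substrings of any catalog contaminant on either strand. This
exact-substring catalog match replaces a repeat-masking step: the contract
(drop rRNA/tRNA/snRNA/snoRNA fragments) is identical and needs no
external tool. Cleanup is conservative by construction: every raw read
lands in exactly one class (`clean`, `no_adapter`, `short`, `long`,
`ambiguous`, `contaminant`), an identity asserted by the tests.

Collapsing to unique sequences sorts by descending count with
lexicographic tie-break, so downstream results are independent of input
order.

# Genome placement

The placement contract is exact matching, no indels, both strands — the
behaviour of a zero-mismatch short-read aligner. Reads with more than
`max_hits` (default 20) placements are flagged `multi_mapped_discarded`;
the cap is configurable because the exact repeat-reporting semantics of
the original aligner invocation are not recoverable. Matching is
implemented on top of `Biostrings::matchPattern`; the index object is a
thin wrapper, and the tests verify agreement with a naive full-scan
search, hit-substring identity for every reported hit, and mirror-image
behaviour under reverse complementation. Coordinates are 0-based
half-open internally and at the BED boundary.

# Known-miRNA annotation

A read is compared gaplessly to each catalog precursor at every offset
whose implied 5′ and 3′ shifts from the annotated mature ends are both
within ±2 nt, accepting ≤2 Hamming mismatches. The best match minimises
(mismatches, |shift5|+|shift3|, name) lexicographically — a total order,
so annotation is deterministic under reordering. A read matching several
precursors of one family counts once toward the family, avoiding
double-counting inflation. Family names strip member letters, arm tags
and `.N` variant suffixes (`miR159a.2 → miR159`); star reads are tallied
separately after locating the precursor's main hairpin loop (the
hairpin-closing pair enclosed by the most outer pairs) and asking which
arm the read sits on. Loop-spanning reads are left undetermined.
Abundance tables count reads, not unique sequences; the published family
tables do not state which convention they used, and reads are the more
common convention.

# Folding and its consequences

Folding is maximum base pairing (Nussinov recursion; Watson–Crick + G:U;
minimum hairpin loop 3 nt) with a deterministic traceback that pairs the
5′-most base of each interval with its leftmost optimal partner. The
kernel is C++ (an O(n³) dynamic programme is impractical in pure R at
300 nt); the test oracle is a pure-R exhaustive enumeration of all nested
structures, kept free of memoisation so the two routes share no code
path. Maximum pairing was chosen over thermodynamic free-energy
minimisation because the source workflow prints no energies or structures
to match, while max-pairing is exactly reproducible and brute-force
checkable. A function can be passed as `fold(engine=)` to substitute an
external thermodynamic folder without changing any downstream contract.

Max-pairing has a known artefact that the duplex logic must absorb: around
a non-complementary column it gains a pair by briefly shifting the pairing
register, turning what a thermodynamic folder would show as a symmetric
internal loop into two compensating one-sided bulges, and it sometimes
re-pairs complementary duplex bases into flanking sequence entirely. The
duplex statistics therefore (i) anchor on the modal pairing register
(`i + partner(i)` is constant along an antiparallel stem), (ii) collapse
off-register islands shorter than 3 anchors, and (iii) count a symmetric
unpaired column as a mismatch only when its facing bases truly cannot
pair. Bulges are maximal one-sided unpaired runs, one bulge per run.
These choices make the accept/reject decision reflect sequence
complementarity, which is what the published ≤3-bulge/≤6-mismatch
criteria were applied to, rather than traceback idiosyncrasies.
"Mismatches" are counted per duplex column (not per base on both
strands); the published criterion wording is ambiguous on this point and
the per-column reading is the stricter-to-satisfy one under which the
planted-hairpin tests pass.

# Novel candidate discovery

For each placement of an unannotated read, 26 windows are excised (13
extensions of 20–260 nt in a 20-nt frame, upstream and downstream,
clipped at chromosome ends, reverse-complemented into sense orientation
for minus-strand hits). Each window is folded; the star interval is the
set of positions pairing with the mature interval, shifted so each duplex
strand carries a 2-nt 3′ overhang, and requires ≥60 % of mature positions
paired into it (the source states no figure; 0.6 passes perfect and
near-perfect plants while rejecting unstructured windows). Star-read
support tolerates the same ±2 nt end shifts as annotation, mirroring
Dicer-product heterogeneity. A candidate is accepted iff mismatches ≤ 6,
bulges ≤ 3, star reads ≥ 1 and the mature read is not a known-miRNA
match; among a hit's accepted windows the one with the fewest
mismatches + bulges, then the shortest precursor, is reported — one
candidate per locus.

# Target scoring

The reverse complement of the miRNA is slid along the transcript; at each
start the gapless placement and every single interior gap placement (one
unopposed miRNA base or one unopposed transcript base) are scored as
1.0 per mismatch + 0.5 per G:U + 2.0 per gapped position, and the best
alignment per start is reported when it scores ≤ `max_score` (default 5).
The weights are calibrated so a perfect site scores 0 and the retained
ceiling matches the maximum published score of 5; the published
half-integer score ladder is reproducible without position-dependent
(seed-region) weighting, which is left as an extension seam. At most one
gap keeps plant miRNA:target duplexes near-contiguous and the brute-force
oracle tractable. Overlapping sites are all reported. Published target
scores cannot be recomputed without the original transcript sequences, so
the scheme is validated on synthetic sites against an
exhaustive window/gap-placement oracle.

# Chip analysis

Per chip (stage × replicate): background mean subtraction, flooring at 0,
then median scaling to the first chip's median (the normalisation method
is unstated in the source; median scaling is deterministic, and quantile
normalisation is available by option). Detection requires mean >
3×background SD, replicate CV < 0.5, ≥50 % of repeat spots passing, and
mean ≥ 32 (the absolute floor is applied to normalised signals; whether
the original floor was raw or normalised is unstated). *t*-tests are
Student's (equal variance), two-sided, on log₂(signal+1) — the same scale
as the published clustering — comparing G1 and G3 replicates; raw
p-values are reported, with Benjamini–Hochberg available but off by
default, matching the published reporting. Classification treats the
2-fold consecutive-stage rule as operative: `up` if G2/G1 ≥ 2 or
G3/G2 ≥ 2 (and neither ≤ 0.5), `down` mirrored, probes whose largest
stage mean is below 100 set aside as `low_abundance`, conflicts flagged
as `unchanged` with a warning. Five of the 18 published differential rows
never reach a strict 2-fold consecutive change when their folds are
recomputed from the printed means; the package flags them rather than
silently matching. Fold changes are rounded half-up at 2 decimals, the
printed convention; one printed fold cell (0.52 for 65/123) is consistent
only with computation from unrounded means, and the validation suite
asserts 35/36 exact cells with all 36 within 0.01.

# Synthetic data: what it emulates and what it does not

The generator plants hairpins of the form
`ext5 + arm + loop + arm' + ext3` with a perfectly paired lower stem
(default 10 nt each side), a random loop (default 12 nt, ≥3), mature
20–24 nt on either arm, and a star arm that reverse-complements the
mature at all but ≤6 mutated positions; the recorded star sequence
follows the 2-nt 3′-overhang geometry exactly. The background genome is
i.i.d. uniform ACGT — spurious hairpins and repeat structure are rare, so
a zero-false-positive expectation is meaningful; real genomes, with their
inverted repeats and transposons, would produce candidates that these
tests cannot speak to. Read populations mix mature/star/contaminant/
background categories exactly (counts sum to `n_reads`), draw background
and contaminant lengths from a bimodal profile with 22.3 % at 21 nt and
50.5 % at 24 nt (the observed grain small-RNA size structure), and
optionally shift mature/star ends uniformly in ±2 nt. There is no
sequencing-error model beyond end shifts. Chip signals are
`background_mean + base × stage_multiplier × lognormal(CV) + N(0, sd)`
with log-normal multiplicative noise chosen to exercise the CV-based
detection rule; there is no cross-hybridisation or spatial model. The
default fixture keeps most probes flat so that median scaling has a
stable anchor, as on a real chip where only a minority of probes change.

All randomness flows from one integer seed through deterministic
per-operation substreams, so identical calls are byte-identical.

# Problem sizes and numerical choices

The test fixtures use 10-kb genomes, 3 planted hairpins and ~2,000 reads;
end-to-end recovery is asserted at three seeds, folding against the
enumeration oracle on 1,000 random sequences ≤ 18 nt, target-scan
equivalence on 2-kb transcripts, and chip multiplier recovery on 500
probes — sizes at which every expectation is exactly computable while the
whole suite stays quick. Percentages are rounded half-up at one decimal,
fold changes at two; ties in every selection (collapsing, matching,
window choice, traceback) are broken by a stated total order. Degenerate
inputs (empty read sets, empty genomes, unfoldable or loop-spanning
intervals, zero-variance t-tests) return defined values or typed
rejections rather than best-effort guesses.

# Known limitations

Alignment is exact-match only (the original zero-mismatch contract);
there is no quality-aware or spliced mapping. Folding ignores
thermodynamics, pseudoknots and partition functions. Target scoring has
no conservation, accessibility or seed-position weighting. Genomic
context (intergenic/intron/UTR) of candidates is reported only when a
user supplies annotation. The chip model knows nothing about probe
design, dye effects or image quantification. These boundaries are
deliberate: within them, every number the package emits is reproducible
from a seed and checkable against an independent oracle.
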
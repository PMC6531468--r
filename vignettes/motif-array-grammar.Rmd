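---
title: "Deriving a multi-element RNA-recognition model from SELEX-seq"
author: "selexarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a multi-element RNA-recognition model from SELEX-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexarray)
```

## The problem

Multidomain RNA-binding proteins — here the archetype is a six-domain
protein with two RRM and four KH domains — rarely recognize one long,
high-information motif. Instead each domain binds a short, degenerate
element (a tetramer, roughly), and affinity and specificity emerge from the
*arrangement*: which elements, in which order, at which spacings. This
package implements the computational side of deriving such a model from an
in vitro selection (SELEX-seq) experiment and of testing it against in vivo
CLIP data:

1. turn selection-round reads into clean sequence tags;
2. score k-mer enrichment per round against a matched negative control;
3. score *ordered pairs* of tetramers as a function of their gap;
4. scan transcript regions with the resulting motif-array grammar;
5. correlate array counts with a normalized in vivo binding index.

A synthetic-data module generates every input with planted ground truth, so
the full pipeline is testable end to end without any external download.

## Preprocessing model

Reads are assumed to be laid out as
`barcode + 5' adapter + UMI + insert + 3' adapter`. Demultiplexing is an
exact match of the barcode at the 5' terminus with 0 mismatches — the most
reproducible convention when no mismatch tolerance is specified by the
protocol. Adapters are located by exact substring search, taking the first
occurrence from each end; the UMI is the `umi_length` (default 5) bases
immediately 5' of the insert. Deduplication collapses on the *(UMI, insert)*
pair rather than the UMI alone: collapsing on UMI alone would discard
genuinely distinct inserts that happen to share a random barcode, which at
4^5 = 1024 UMIs and realistic pool sizes would be a large artificial loss.
Inserts are kept when 38–40 nt long and free of ambiguous bases (k-mer
counting requires unambiguous symbols). All sequences are canonicalized to
RNA (U) internally; FASTQ output uses T by sequencer convention.

## Enrichment z-scores

For word length k ∈ {4, 5, 6} the unit of counting is **tag containment**:
a tag contributes at most 1 to each motif it contains, however many times.
This makes counts directly comparable across motifs of different internal
repeat structure. With f(m) = count(m)/total tags, the raw z-score is

z_raw(m) = (f(m) − mean f) / sd f,

standardized over the complete 4^k universe of one sample/round, using the
population standard deviation (the universe is fixed and exhaustive, so the
sample/population distinction is immaterial in size but stated for
exactness). The corrected score subtracts the matched negative-control
selection (a carrier-protein-only SELEX) at the same round, per motif:
z_corrected = z_raw,sample − z_raw,control. Subtraction rather than a ratio
is deliberate: z-scores are signed and can be zero, so a ratio is neither
stable nor meaningful. A degenerate table with zero variance yields all-zero
z rather than NaN. Top-motif reports default to the fourth selection round,
with a highlight threshold of z > 1.5 matching the convention used for
cross-truncation comparison scatter plots.

## Pair-spacing analysis

The same z machinery is applied to cells indexed by (ordered tetramer pair,
gap), with the gap defined as the number of nucleotides strictly between
the end of the upstream motif and the start of the downstream motif (the
N_x notation: `GGCA-N20-CACA` is gap 20). Gaps run 0–25; the universe is
65,536 × 26 cells. Cells are standardized **jointly** over the whole
universe, not per gap: the published heat maps compare cells across gaps
within one panel, which requires a common scale, and the per-gap
alternative would erase genuine spacing preferences whenever one gap is
globally favoured. Pairs are ranked by the mean of their 26 corrected cell
z-scores; the top 500 define the membership pool for six motif-class groups:

* (a) the ten best pairs of two CA-rich tetramers,
* (b)–(e) the four ordered combinations of a CA-rich element with one of
  the two GGC-core elements (GGCA, CGGC),
* (f) two GGC-core elements.

A tetramer is *CA-rich* when it contains no G, at least three C/A residues,
at least one adjacent C–A alternation, and neither CCC nor AAA; exactly 30
of the 256 tetramers qualify. Group membership is computed once on the
reference (full-length-protein) sample and then frozen when profiling
truncation samples, so that profiles are comparable across constructs. For
RRM-tandem-like samples, which do not separate the GGCA/CGGC cores, groups
{b, d} and {c, e} are merged into two summary profiles; the merge is
implemented by group letter. Heat-map annotation thresholds default to
z > 4.6 for full-length-like and RRM-tandem samples and z > 2.5 for
KH-derivative samples, the thresholds used in the published description.

## The motif-array grammar

Transcript regions are scanned with three sequential criteria, applied to
every ordered pair of GGC-core anchor hits (G1 before G2):

1. anchor gap within 30–200 nt;
2. two CA elements strictly between the anchors, each at least 10 nt from
   the nearer anchor and at least 6 nt from each other;
3. one further CA element outside the anchor pair, 6–200 nt from the nearer
   anchor (either side).

These bounds are deliberately looser than the in vitro optimum to allow for
structural loops in real transcripts. The CA-element set is a *parameter*
(default: all 30 CA-rich tetramers) because published screens have used
curated subsets; absolute array counts, and therefore the proportions of
regions per array-count group, depend on this list and are not comparable
across different choices. Overlapping anchor hits (e.g. `CGGCA`) are both
candidate anchors. Qualifying anchor pairs are reduced to a non-overlapping
set by greedy left-to-right selection on the anchor interval — deterministic
and conservative where overlap handling is otherwise unspecified. Every
reported array stores witness coordinates (leftmost valid internal CA pair,
nearest external CA) that re-verify the criteria. Scanning is single-strand
(sense) only. Regions are grouped by array count as 0, 1, 2/3, ≥4.

## The binding index

The B index of a region is its CLIP tag count divided by its expression
level (mean RNA-seq coverage or any positive per-region value). Tags are
assigned by their start coordinate — the truncation-position convention for
iCLIP libraries, where the read start marks the crosslink site — with a
midpoint option for other CLIP flavours. Regions with zero expression are
excluded rather than given infinite indices; no minimum-coverage threshold
is applied beyond strict positivity. Groups 1, 2/3 and ≥4 are each compared
against group 0 with Welch's unequal-variance two-sample t test (two-sided,
Welch–Satterthwaite degrees of freedom), reported raw without
multiple-testing correction, matching the reporting convention for these
three planned comparisons.

## What the synthetic data emulates — and what it does not

`simulate_selex_rounds()` models selection as resampling with replacement:
the physical library (`pool_size × library_factor` molecules, default
factor 10) starts as a uniform random N40 pool; a sequence's weight is
1 + Σ motif gains + Σ pair gains (additive, so planted signals compose),
and round r is drawn with probability ∝ weight^schedule[r]. Each round's
*emitted* tags are a without-replacement subsample of `pool_size` molecules
— the sequencing step after UMI deduplication. Separating physical library
from sequencing depth matters: real selection libraries (~nanomoles, 10^14+
molecules) dwarf sequencing depth, so sequenced tags are effectively
independent draws from the evolved pool distribution; a simulator whose
physical pool equals its sequencing depth would instead accumulate shared
ancestry over rounds and overstate between-replicate noise. The exponent
schedule (default 1, 1.5, 2, 2.5) is the simplest monotone stand-in for
wash stringency that "increases each round"; no quantitative per-round
efficiency is published, so gains are free parameters calibrated only to
make enrichment detectable, not to match any published z magnitude. The
simulator does **not** model PCR bias, sequencing error, secondary
structure, or thermodynamic binding — so passing recovery tests shows the
analysis correctly inverts this selection model, not that it is robust to
every artefact of real libraries.

`make_fixture_101mers()` builds the designed 101-nt validation RNA
(`GGCA-N20-CACA-N14-CACA-N22-CGGC-N4-(CA)4`, with an 8-nt 5' and a 9-nt 3'
flank) and its six mutants (CA→UG, GGC→UG, allUG, the GGC↔CA block
exchange with and without CA→UG, and the (CA)4 relocation). The true
spacer sequences of the published construct are not reproducible from the
text, so spacers are motif-free {U, G} runs; boundary analysis dictated the
form `G…U…G` (starting with G, ending in UG), since other {U,G} junctions
with motif blocks create accidental CA-rich or GGC-core words (e.g.
U + CAC = UCAC, GG + CA = GGCA). Scanner results on the series depend only
on the layout, not on spacer identity.

`generate_regulome()` plants k copies (k from a configurable distribution
whose default mirrors the ~44/16/16/24 % split of 0/1/2–3/≥4 arrays
observed in expressed UTR sets) of the wild-type 101-mer template into
motif-free {U, G} background, separated by > 200 nt so neighbouring arrays
cannot form cross anchor pairs. Expression is lognormal (meanlog 2,
sdlog 1 — a typical right-skewed coverage distribution); tag counts are
Poisson with rate expression × (λ0 + λ1·k), defaults λ0 = 0.5, λ1 = 1, so
the expected B index is λ0 + λ1·k and λ1 = 0 is the null model. The
motif-free background isolates grammar recovery from background hit noise;
real UTRs have composition-driven spurious hits and partial arrays, so
recovery rates and group splits on this synthetic regulome say nothing
about absolute counts in real annotation sets.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere, matching BED.
* Ties in motif rankings break lexicographically; ties in the external-CA
  choice break toward the downstream side.
* Zero-variance tables give all-zero z (logged by the degenerate-input
  handling), never NaN; zero-variance correlation inputs give `NA` with the
  reason available to the caller.
* All generators are deterministic under their configured seed.
* Hot loops (k-mer containment, pair-gap counting, per-read motif flags)
  are small C++ kernels; every one is validated against a naive R oracle in
  the test suite.
* Problem sizes used by the validation suite — pools of 50,000 tags for
  hexamer recovery, 20,000 for spacing recovery, 2,000 synthetic regions
  for the binding-index contrast — were chosen as the smallest sizes at
  which the planted effects are unambiguous for routine revalidation.

## Known limitations

* The z-score definition (standardize, then subtract control) is one
  defensible reading of the published analysis, which does not print the
  formula; rank orders are robust to the alternative
  (correct-then-standardize) but absolute values are not.
* The scanner's greedy reduction undercounts overlapping array clusters
  relative to any convention that counts them separately; grouped
  comparisons (0 vs ≥1) are insensitive to this.
* Pentamer/hexamer *pair* analysis, positional weight matrices, and
  structure-aware accessibility are out of scope.
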
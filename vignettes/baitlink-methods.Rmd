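---
title: "baitlink: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{baitlink: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

baitlink links a single chromatin viewpoint — a 4C-seq "bait" such as a
risk-SNP enhancer — to candidate target genes. This vignette explains the
models and conventions behind each stage, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the design
decisions we made where the underlying protocol leaves room.

## Coordinates and restriction-fragment maps

All coordinates inside the package are 0-based, half-open (the BED
convention); conversion to and from 1-based systems happens only at I/O
boundaries (SAM positions, FASTA extraction). A fragment map is produced
by `digest_genome()`: every exact occurrence of an enzyme's recognition
motif cuts the chromosome at `motif_start + cut_offset`, overlapping
occurrences all cut, `N` never matches, and zero-length intervals (a cut
at position 0 or the chromosome end) are dropped so the fragments tile
each chromosome exactly. The two built-in enzymes carry their true
chemistry — DpnII cuts `^GATC` (offset 0) and CviQI cuts `G^TAC`
(offset 1); the offsets are data, not code, so other cutters are a
one-line `enzyme_spec()`.

The genome-level fragment map uses the first cutter only; the second
cutter participates at read level (`digest_read()`). Double-digest
sub-fragment maps are representable (digest with the second enzyme and
intersect) but are not the default, because per-fragment coverage of the
first-cutter map is the common analysis unit for this assay design.

## From read pairs to interaction calls

`demultiplex_and_trim()` keeps a pair iff exactly one mate begins with
the bait's reading primer (anchored Hamming match, `max_mismatch = 0` by
default — the primer is a known synthetic sequence, so mismatches signal
sequencing error rather than biology, and the budget is a parameter for
noisier libraries). Both sides of a kept pair are informative and both
are emitted: the trimmed remainder of the primer mate carries bait-side
sequence up to the ligation junction, and the untouched partner mate
carries the captured fragment. Keeping the bait-side piece costs nothing
(it lands in the excluded bait region) and preserves the per-pair
accounting.

Capture sequences are digested in silico with both cutters and placed on
the genome. Two placement routes exist:

* `place_sequences()` — an exact, genome-unique matcher for the
  simulated toy genome: a sequence is placed iff it occurs exactly once
  over both strands; ambiguous and absent sequences are counted and
  dropped. A self-reverse-complementary sequence occurring once counts
  as two oriented occurrences and is treated as ambiguous; at realistic
  read lengths this is vanishingly rare.
* `load_placements_sam()` — real data aligned externally enters as SAM;
  primary mapped records above a MAPQ floor are used, with
  reference-space widths taken from the CIGAR string.

`coverage_per_fragment()` assigns each placement to the fragment
containing its 5'-most aligned base and rescales counts to reads per
million (RPM), so per-replicate coverage always sums to 10^6 exactly.

`call_interactions()` declares a fragment an interacting site iff its
RPM exceeds the threshold (default 50, strict) **in every replicate**.
This is the strictest reading of "reproducible in two biological
replicates"; a mean-based rule would admit fragments strong in one
library only, which is what reproducibility filtering exists to prevent.
The bait fragment plus `exclusion_radius_fragments` (default 2) on each
side is never called: self-ligation and undigested template dominate the
viewpoint's immediate neighbourhood in any circularized-template assay,
and that signal is protocol, not contact. The call unit is a single
restriction fragment; we do not merge adjacent calls by default, so site
counts are directly comparable across parameter settings. Cis calls
carry a signed midpoint-to-SNP distance; cis/trans percentages from
`summarize_cis_trans()` are rounded to two decimals.

## Target-gene nomination

`nominate_targets()` implements a two-step filter: a gene is a candidate
iff it is significantly down-regulated after enhancer loss
(`log2fc < -1.3` and BH-adjusted `p < 0.05`, both strict, matching the
printed inequalities) **and** at least one interaction call lies within
`window` bp of the gene body with minimum-across-replicates RPM above
the cut (strict, consistent with the per-replicate calling rule).
Trans-supported genes are nominated identically to cis ones — enhancer
hubs contact other chromosomes, and several of the interesting targets
in this assay class are trans.

The assignment window is the one genuinely open parameter: the protocol
itself never specifies how an interacting region maps to a gene. We
default to 50 kb around the gene body, expose it in every call, and
report the supporting fragments and distances so users can audit each
nomination. Tightening any threshold provably never adds candidates,
and the test suite asserts that monotonicity.

`benjamini_hochberg()` delegates to `stats::p.adjust(method = "BH")`;
the test suite checks it against an independently written step-up
implementation. `overlap_gene_sets()` expresses thresholded gene-set
comparisons (including padj-only sets, via `fc_cut = 0`) and intersects
by gene id, warning when the two tables' universes differ.

## Efficiency-corrected 3C-qPCR

Standard curves are ordinary least squares of Ct on log10(template
dilution) over a genomic-DNA ligation library; the amplification
efficiency is `E = 10^(-1/slope) - 1`, and a primer pair passes QC iff
`0.90 <= E <= 1.10`. The bounds are treated as inclusive — "between 90%
and 110%" reads most naturally as a closed interval, and the choice is a
parameter. Relative quantities are `RQ = (1+E)^(-Ct)`; anchor
normalization (to the bait self-ligation product) happens **within each
biological replicate** before cross-replicate summarization, preserving
the pairing between a replicate's anchor and its test regions. Technical
replicates are averaged on the Ct scale before conversion to RQ (the
log-domain mean, appropriate for exponential amplification); averaging
RQ instead is a configuration choice the API accommodates by passing
pre-averaged values. Replicate summaries report the n−1 sample SEM
(missing when n = 1), and promoter/flank comparisons propagate SEM to
first order (delta method), which the tests validate against Monte-Carlo
propagation.

## Allele-specific motif scoring

JASPAR position frequency matrices (bracketed or plain rows) become
probability matrices with a total pseudocount (default 0.8) split
equally across the four bases — equal splitting keeps the prior
allele-neutral, which matters precisely because we score allele
differences. Scores are log2 odds against a background (default
uniform). For each allele the SNP base is substituted into its genomic
context and **every** motif-length window overlapping the SNP is scored
on both strands; the report carries each allele's best window and the
difference `delta = best_alt - best_ref`. Best-window aggregation (not
sum-occupancy) matches how a single binding site at a SNP is read.
Windows containing N are skipped. The scorer is tested exactly against
exhaustive enumeration, including strand-symmetry identities.
ChIP-qPCR allele comparisons use percent-input arithmetic with the
input-dilution correction, where the dilution factor provably cancels
from the fold ratio.

## The synthetic study scenario

`make_scenario()` generates every input with known truth: a 1 Mb + 0.5
Mb genome, a bait near 300 kb on chr1, three planted contact peaks (cis
at +50 kb and +400 kb, trans), two replicate libraries of 10^5 pairs, a
200-gene DE table with one planted down-regulated target per peak, a
four-primer-pair Ct table (true efficiencies 0.95, 1.00, 1.05, 0.85 —
the last exists to fail QC), and a synthetic SOX-family-like PFM whose
consensus the SNP's alternative allele completes.

Choices worth stating explicitly:

* **Genome composition.** Chance GATC occurrences are mutated away and
  GATC is injected every ~400 bp, so the first-cutter map has a
  predictable density (~2 500 + 1 250 fragments) and fragment counts are
  testable; CviQI sites are left random so read-level digestion stays
  non-trivial.
* **Contact model.** Partner fragments are sampled with cis background
  weight `(1 + |d|/d0)^(-alpha)` with `alpha = 3`, `d0 = 2` kb, a flat
  trans floor `eps = 2e-5`, and absolute peak weights (default 0.01,
  about 175x the cis background at 50 kb). The steep decay concentrates
  background mass within ~20 kb of the bait. This is a deliberate
  requirement of the recovery design, not a claim about chromatin: with
  10^6 RPM spread over ~3 750 fragments the mean covered-fragment RPM is
  ~270, so any shallow decay (exponents near 1 with a 10 kb scale) puts
  essentially every cis fragment above an RPM-50 threshold and no
  planted/background separation exists at all. Relatedly, defining peak
  heights as multiples of their *local* background cannot work for a
  far-cis peak under any monotone decay (its local background is below
  what the threshold permits anywhere), which is why peak weights are
  absolute. The chosen values make recovery non-trivial — ~110
  background fragments near the bait are genuinely called — while
  leaving planted peaks (~900-3000 RPM) and distant background (~5 RPM)
  cleanly separated.
* **Reads.** Error-free by design: the tested difficulty is placement
  ambiguity and the digestion/trimming chain, not base-calling noise.
  The primer mate is the reading primer plus bait-side sequence up to
  the first-cutter site; the partner mate is a prefix of the partner
  fragment; which physical mate carries the primer is randomized.
* **DE table.** Null genes draw `log2fc ~ N(0, 0.2)`, `p ~ U(0,1)`;
  targets draw `log2fc ~ N(-2, 0.3)` rejection-sampled below −1.3 and
  `p ~ U(0, 1e-5)`, so planted targets pass the default filter with
  certainty and a null gene would need a ~6.5-sigma fold-change draw to
  produce a false nomination.
* **Ct tables.** `Ct = intercept - log(template)/log(1+E) + N(0, 0.1^2)`.
  The scenario ties intercepts across primer pairs so that
  `Ct(template=1) * log(1+E)` is constant — the statement that all
  standard curves derive from one genomic-DNA library with a common
  template scale. Without that coupling, cross-primer RQ ratios would
  absorb arbitrary per-primer offsets and template ratios would not be
  recoverable even in principle.
* **Determinism.** Every generator is a pure function of its parameters
  and seed; per-replicate streams derive deterministically from
  (seed, replicate label).

What passing the recovery tests does **not** show about real data: no
PCR-duplicate structure, no quality-score or substitution noise, no
mappability structure beyond exact uniqueness, no background model for
4C signal (z-scores, domainograms), and genome sizes three orders of
magnitude below human. The planted-truth results demonstrate that the
chain of operations is correct, not that the thresholds are optimal for
any particular biological dataset.

## Problem sizes and numerical notes

The default test and acceptance workloads use the scenario above
(2 x 10^5 read pairs, ~3 750 fragments, 200 genes), 200 simulated
standard curves for efficiency recovery, and oracle sweeps of 1 000
random sequences (digestion), 100 random PWMs (allele scoring) and
1 000 random p-vectors (BH) — sizes chosen so the whole suite exercises
every claim in minutes on one CPU while keeping all stochastic margins
(peak RPM vs threshold, target fold-change vs cut) multiple sigma wide.
Ties in nomination ordering break alphabetically by gene id; RPM
conservation is exact up to floating-point summation (tested at 1e-9
relative); efficiency recovery from exactly collinear points is exact to
1e-12 because the OLS slope is then algebraic.

## Known limitations

Real 4C libraries need an external aligner (ingest SAM); the toy matcher
requires exact unique occurrences and will discard reads a gapped
aligner would place. Interaction calling is threshold-based by design —
no statistical background model is fitted, so calls near the bait
reflect proximity signal and should be interpreted through the reported
distances. DE estimation, enrichment analysis and peak calling are out
of scope: the package consumes their outputs.
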
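---
title: "Detecting and exploiting spliced-leader trans-splicing in copepod transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and exploiting spliced-leader trans-splicing in copepod transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slsplice)
```

## The model

Calanoid copepods attach a common 46-nt spliced leader (CopepodSL) to the
5′ end of many mRNAs. The leader is the exon of a small precursor RNA
(slRNA) of 108–158 nt whose intron (62–111 nt) begins with the GU splice
donor and carries a purine-flanked pyrimidine tract — the Sm-binding site —
in a single-stranded region between stem-loops. Because the leader is
added post-transcriptionally, every trans-spliced transcript begins with a
near-identical prefix; everything in this package follows from that one
structural fact.

The pipeline mirrors the analysis workflow such a discovery implies:
leader discovery from full-length cDNA 5′ ends, SL screening and trimming,
feature annotation of the trimmed bodies, slRNA gene-unit annotation in
genomic sequence, and a structural check of candidate slRNAs. A
synthetic-data generator with exact truth tables stands in for the
original sequencing libraries, so the whole chain is testable offline.

## Leader discovery

Full-length cDNAs place the leader at position 0–5 of every read (a small
offset allows for occasional 5′ extensions such as ATT, observed on a
minority of clones). A gapped multiple alignment is therefore unnecessary:
`cluster_five_prime_prefixes()` anchors records on an exact shared k-mer
(default k = 12) inside a 60-nt 5′ window, aligns members on the anchor,
and assigns each record to its highest-support anchor (ties broken
lexicographically, for determinism). Defaults — `min_support = 5`,
`min_freq = 0.1`, conservation threshold 0.9 with a 5-column confirmation
window — are tolerant of the 44–47-nt exon-length variation seen among
slRNA genes.

`build_degenerate_consensus()` turns aligned columns into the IUPAC code
of all bases at frequency ≥ `min_freq`, keeping the full position
frequency matrix. `find_sl_boundary()` calls the leader's 3′ end at the
first column whose own conservation (maximum base frequency) falls below
the threshold *and* whose following `window` columns stay below it on
average. The second condition stops a single noisy column inside the
leader from truncating it; the first stops the look-ahead window from
firing early while still inside a perfectly conserved leader (a window
mean that straddles the boundary dips below 0.9 up to `window − 1` columns
too soon otherwise).

## Screening

`match_sl()` scans offsets 0–5 for the whole consensus and keeps the
lowest-mismatch placement, counting mismatches only at non-degenerate
consensus positions; ties resolve toward the smaller offset (prefer no
extension). The default budget of 2 mismatches keeps the probability of a
chance full match in random sequence far below 10⁻⁶ per transcript — the
package asserts zero false matches over thousands of simulated
contaminants — while the threshold is exact by construction: a leader
carrying three substitutions is rejected. `match_sl_partial()` models
5′-truncated ESTs: it anchors at transcript position 0 only and accepts
the longest consensus *suffix* of at least 15 nt (a leader prefix at the
start of a transcript is not SL evidence, and internal hits are ignored).
The 15-nt floor is a configurable choice; shorter suffixes match random
starts too often to be informative.

`rarefaction_curve()` uses the exact hypergeometric expectation
E(n) = Σ_g (1 − C(N−c_g, n)/C(N, n)) rather than resampling; the test
suite checks it against a 100,000-draw Monte-Carlo oracle.

## mRNA annotation

Feature definitions are anchored on the trimmed body (all coordinates
0-based, half-open):

* **ORF** — the 5′-most AUG that opens a frame with an in-frame stop and a
  CDS of ≥ 30 codons (stop included). The 30-codon floor is a package
  choice: copepod CDS average ~450–550 bp, so genuine ORFs far exceed it,
  while shorter ORFs in UTR sequence are overwhelmingly spurious. When no
  AUG yields a stop the annotation stays anchored at the first AUG,
  frame-truncated and flagged incomplete.
* **UTRs** — 5′ UTR is the distance from the first nucleotide after the
  leader to the start codon; 3′ UTR runs from the first nucleotide after
  the stop codon to the first A of the poly(A) tail.
* **Poly(A) tail** — the longest terminal window at least 90% A and ≥ 8 nt,
  reported from its first A whose suffix still meets the purity rule. The
  purity tolerance absorbs isolated sequencing slips; the run floor keeps
  short genomic A-runs from being called tails. A stop codon or 3′ UTR
  ending in A merges into the tail under this rule — an intrinsic
  ambiguity of oligo-dT-primed data that the generator avoids by keeping
  the last ten 3′-UTR bases A-free.
* **Signals** — every AATAAA between stop and tail is reported with its
  offset to the cleavage site; 7–20 nt is flagged as the canonical range.
* **Kozak profile** — contexts (−3…−1, AUG, +4…+6) are tallied into a
  4×9 matrix; the consensus takes the modal base per column, with ties
  reported as IUPAC codes (the same convention as the leader consensus,
  rather than an arbitrary pick).
* **Composition** — maximal homopolymer runs of ≥ 4 (i.e. "more than 3
  repeats"); GC over unambiguous bases; codon usage as plain tallies with
  stops included.
* **cRP checklist** — detected gene names are string-normalised
  (case-insensitive, punctuation stripped) against the canonical
  eukaryotic set of 32 small-subunit and 47 large-subunit cytoplasmic
  ribosomal proteins shipped in `inst/extdata/crp79.tsv` (the
  plant-specific RPLP3 and the Y-chromosome RPS4 isoform are excluded
  from that canon). No homology search is performed; the reference file
  is user-replaceable.

Summary statistics report the population standard deviation (divide by n);
the convention is stated in the output rather than assumed.

## slRNA gene units

`locate_sl_exons()` scans both strands for the consensus with the same
mismatch budget, resolving overlaps to the lower-mismatch, then 5′-most
hit. Because exons of 44, 45, 46 or 47 nt all match the 46-nt consensus
within two mismatches, the exon 3′ end is refined afterwards: the first
length among 46, 45, 47, 44 (majority first) whose following dinucleotide
is GT becomes the exon end. The unit 3′ end cannot be recovered from
sequence alone — experimentally it required 3′-RACE — so the default rule
places it 20 nt after the best Sm-site hit, with the Sm scan capped at
exon end + 111 nt (the maximum observed intron) so that a scan can never
run into a downstream unit of a tandem array. Both the offset and the cap
are explicit parameters of the model, not facts about the data.

The Sm search accepts RR(pyrimidine tract)RR with tract length 4–12 and
at most one internal A/G interruption — spanning both the conserved
eukaryotic form (tract 4–6) and the longer copepod variants (6–12).
Interruptions count only interior bases: the tract must begin and end
with a pyrimidine, so a flanking purine can never be absorbed into the
tract. Hits are ranked by tract length, then position. Exon and intron
lengths outside [44, 47] and [62, 111] raise QC flags but never drop a
model: the ranges are observed, not definitional.

`detect_array_layout()` classifies a sequence as `fiveS_clustered` when
the 20-nt 5S rDNA probe (TACTTGGATGGGTGACCGCC) occurs on either strand
outside the exons, `tandem` for ≥ 2 units without a probe hit, and
`singleton` otherwise. Only probe presence is tested; full 5S gene
annotation is out of scope. Minus-strand slRNA units are located but unit
annotation operates on the plus strand (reverse-complement the input for
minus-strand units); this is a documented limitation.

## Secondary structure

The structural claims of interest are topological — which hairpins exist
and whether the Sm site is single-stranded — so the package uses
deterministic base-pair maximization (Nussinov-style dynamic programming)
instead of thermodynamic folding; temperature has no analogue here.
Pairing is Watson–Crick plus GU wobble, the minimum hairpin loop is 3 nt,
and the traceback is fixed: the left end of every interval pairs with the
smallest admissible partner that still achieves the interval's maximum,
and stays unpaired only when no partner does. Identical inputs therefore
give identical structures on every platform. The fold is verified against
exhaustive enumeration for all tested sequences up to 12 nt.

`classify_slrna_structure()` reports the hairpin count, whether some
hairpin's outer pair spans the exon/intron boundary with the GU donor
enclosed, the number of exon-internal hairpins, and the unpaired fraction
of the Sm span; a structure passes when the boundary hairpin exists and
the Sm site is ≥ 70% unpaired. The pass threshold leaves room for the
site's purine flanks to pair while requiring the tract itself to stay
open. Where several equally good foldings exist the classifier reports
counts for the one deterministic traceback rather than asserting a unique
biological structure.

## The synthetic-data generator

`generate_transcriptome()` emulates the statistical structure of copepod
full-length cDNA libraries: a concrete leader instance (W→A, Y→C — a fixed
instance keeps exact-match tests stable; degenerate sampling is available
through the `leader` argument), an ATT extension with probability 0.09
(three of 33 cDNAs in the motivating libraries), 5′ UTRs from a truncated
normal 24 ± 36 nt and 3′ UTRs 249 ± 209 nt (floored at 10; only a
mean ± sd is reported for these lengths, so truncated normals with
resampled negatives are the minimal assumption — note truncation raises
the realised 3′-UTR mean to ~286), CDS length 184 ± 124 codons (floored at 40, comfortably
above the 30-codon ORF floor), Kozak context AAAATGGCT with 10% per-base
noise on the six non-AUG positions, an AATAAA signal in half of the
transcripts placed 7–20 nt before cleavage, poly(A) tails of 15–40 nt,
~46% GC, and injected A-runs up to 12 nt in a third of 3′ UTRs.
Gene labels follow a 1/rank distribution over ~0.6·n genes, giving the
skewed clone-count spectrum that rarefaction needs.

Exact truth recovery is engineered, not hoped for: upstream AUGs are
scrubbed from 5′ UTRs, stray AATAAA copies are removed (a planted signal
is protected during scrubbing), and the last ten 3′-UTR bases are kept
A-free so that the tail's first A is unambiguous under the 0.9-purity
rule for tails up to 40 nt. These scrubs make noise-free generator output
exactly recoverable — which is what makes the parameter-recovery tests
sharp — at the cost of mildly unnatural sequence (real UTRs do contain
upstream AUGs and decoy signals). Leader noise is honest per-position
Bernoulli substitution; at rate 0.02 about 6% of leaders draw three or
more substitutions and are, by the exact-threshold contract, correctly
rejected at the default mismatch budget. Sensitivity statements in the
tests are therefore made over the detectable set (≤ 2 substitutions), and
the raw detection rate is reported alongside.

`generate_slrna_array()` builds flank + n × (exon + intron + spacer)
with every intron starting GTAA (the AA makes GT-donor refinement exact
for all four exon-length variants), a planted Sm site ending exactly
20 nt before the unit end (matching the annotation rule's offset — the
geometry a 3′-RACE-calibrated pipeline would see), spacers of 50–400 nt,
and optionally the 5S probe inside a spacer. Intron filler, intron tail
and spacers contain only isolated pyrimidines (never two adjacent), which
provably excludes any competing pyrimidine tract of length ≥ 4 — including
across segment junctions — so the planted Sm site is the unique best hit.
Real introns are of course not purine-spaced; this is a deliberate
simplification that buys exact recoverability.

`generate_structured_slrna()` samples stem/loop geometries for a fixed
topology — two exon hairpins, an exon/intron-boundary hairpin enclosing
the GU donor, an intron hairpin, a single-stranded Sm tract, a 3′
hairpin — and encodes them with role-restricted letters: stem arms are
A/U complementary blocks, loops and linkers are C (inert: the only G in
the molecule is the splice donor, which pairs a dedicated loop C), and
the Sm flank purines are the closing A-arm of one hairpin and the opening
A-arm of the next, so no unpaired purine exists anywhere. Under base-pair
maximization every A then has to pair an arm U (stranding any arm is
strictly suboptimal), and the deterministic smallest-partner traceback
recovers the designed local stems. These sequences are structural
scaffolds — their "exon" is not a CopepodSL copy — and they exercise the
structure classifier, not SL matching. Passing tests on them show the
classifier and fold behave as specified; they do not show that real
slRNAs fold this way.

## What passing tests do and do not show

The generator encodes the study conditions; recovery tests show the
pipeline inverts its own generative model exactly in the noise-free case
and degrades as theory predicts under substitution noise. They do not
show performance on real libraries, where leader variants are discrete
slRNA-type polymorphisms rather than i.i.d. noise, UTRs contain decoy
motifs, and oligo-dT priming produces internal tails. The mismatch
budget, partial-match floor, tail purity and Sm-offset rule are the knobs
a user should revisit for real data.

## Numerical and design choices

* Coordinates: 0-based, half-open, everywhere.
* Internal alphabet DNA; U restored on output for RNA inputs; N (and any
  ambiguity code in the target) matches at zero cost so sequencing
  ambiguity never breaks detection.
* Ties: equal-support clusters by lexicographic anchor; equal-mismatch
  offsets toward 0; equal-length Sm tracts by position; fold traceback by
  smallest partner. All outputs are reproducible byte for byte.
* `summarize_library()` sd is population sd.
* The pipeline (`run_pipeline()`) runs the stages in the fixed order
  discover → screen → trim → annotate → slRNA → fold, writing one TSV per
  stage and a manifest of parameters and input checksums; the exported
  functions are the package's interface, and `run_pipeline()` is the
  single-call entry point for a whole run.
* Problem sizes in the test suite (20 libraries of 130 records for
  screening; 500 transcripts for annotation recovery; 500 short sequences
  for the fold oracle; 50 array sequences) were chosen as the smallest
  sets that still exercise every code path and distributional claim.

## Known limitations

* Minus-strand slRNA units require reverse-complemented input for unit
  annotation.
* The unit 3′-end rule (Sm end + 20 nt) is a stand-in for experimental
  3′-end determination and is wrong whenever the true spacing differs.
* Base-pair maximization ignores stacking energies: it overpairs relative
  to thermodynamic folds and should be read as a topological screen, not
  a structure prediction.
* cRP completeness is name matching, not homology: a detected gene under
  a nonstandard name counts as missing.
* BLAST-style database survey, GO annotation and read-level simulation
  are out of scope.
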
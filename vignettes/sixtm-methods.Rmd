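---
title: "Methods: classifying truncated GPCR splice variants and their enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying truncated GPCR splice variants and their enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Canonical G protein-coupled receptors (GPCRs) carry seven transmembrane
helices (7TM). Alternative transcription and splicing of the opioid receptor
genes (*OPRM1*, *OPRD1*, *OPRK1*, *OPRL1*) produce, in addition to 7TM
receptors, N-terminally truncated 6TM receptors (translation effectively
starting at exon 2, skipping the exon-1-encoded TM1) and 1TM fragments
(exon-1 open reading frames running into a premature termination codon, PTC,
introduced by a cassette exon). `sixtm` implements the computational side of
that biology as a tested pipeline: deciding which receptor products a
transcript can encode, screening protein isoform databases for truncated
variants, quantifying exon-level evolutionary divergence and conservation,
and testing whether truncated-receptor genes are over-represented among
disease gene sets. Raw sequencing and database retrieval are replaced by
seed-deterministic synthetic generators with known ground truth, so every
stage is verifiable offline.

## Transcript topology classification

A transcript model is an ordered set of 1-based closed exon intervals
(`transcript_model()`); `spliced_sequence()` assembles the mRNA
(reverse-complemented on the minus strand). `scan_orfs()` reports an open
reading frame for every qualifying start codon; the `aug_gug_cug` policy
admits the near-cognate starts CUG and GUG, which initiate translation of
some 6TM variants from extended exon 2, and the initiator is always decoded
as methionine. Codons containing `N` are untranslatable and end the scan of
that frame.

`classify_products()` applies these rules:

* The ORF from the 5'-most qualifying start is translated and its helices
  predicted. Seven helices: a **7TM** product. Six helices with TM1 absent
  and TM2..TM7 present in a global alignment to the canonical receptor: a
  **6TM** product.
* If the primary ORF ends at a PTC (a stop upstream of the final exon-exon
  junction) with exactly one helix, a **1TM** fragment is recorded and
  reinitiation is considered: the first AUG strictly downstream of the PTC
  is translated and accepted as a 6TM product under the same alignment
  criterion. We anchor reinitiation at the PTC rather than at a named
  "exon 2" boundary: in the receptor architecture modelled here the cassette
  exon carries no AUG after its stop codon, so the first downstream AUG *is*
  the restart methionine at the start of exon 2, and the PTC-anchored rule
  needs no exon-labelling convention. Only that first AUG is considered.
* NMD candidacy uses the classical junction rule: the stop must lie at least
  `junction_rule_nt` (default 50) nucleotides upstream of the last
  exon-exon junction. No single threshold is universal in the literature;
  50 nt is the textbook value and the parameter is exposed.

Equal-length ORF ties cannot arise under these rules (each start determines
its ORF); among starts, 5'-most wins.

### Transmembrane helix prediction

Server-based predictors (TMHMM, TMpred, Phobius) cannot anchor a
reproducible test suite, so `predict_tm_helices()` is a deterministic
Kyte-Doolittle sliding-window predictor. Mean hydropathy is computed in a
window of 19 residues at every admissible centre; maximal runs of centres
with mean >= 1.6 become helix calls; a run abutting the first or last
admissible centre is extended to the protein terminus (otherwise terminal
helices would be clipped by the window half-width); calls shorter than 15
residues are dropped and overlapping calls are merged. Window 19 and
threshold 1.6 are the classical surface/TM settings for the Kyte-Doolittle
scale; 15 residues is the shortest stretch that plausibly spans the
membrane. All four parameters are configurable. Interior helix boundaries
are the centre run itself, not the window span: extending every run by the
half-width would fuse helices separated by loops shorter than the window,
which contradicts the 7-helix architecture the predictor must resolve.
Exact concordance with the server-based predictors is not claimed; the
planted-locus tests quantify what this predictor recovers by construction.

## The isoform truncation screen

`run_screen()` mirrors a UniProt-style screen. For each gene the canonical
protein carries exactly seven annotated TM domains (enforced on input).
Each non-fragment isoform is globally aligned to the canonical protein
(`align_isoform()`: Needleman-Wunsch, BLOSUM62, gap open 10 / extend 1 --
standard protein-alignment settings; the choice is a design decision since
no aligner is prescribed by the screen's definition). `tm_presence()` calls
TMk present when >= 50% of its canonical residues align to non-gap isoform
residues; the fractional criterion (configurable `coverage_min`) tolerates
splice-boundary shifts inside helices while rejecting whole-helix
deletions, and deliberately exposes the ambiguity of how partially
spliced-out helices should count. When a TM is absent, the maximal
isoform-only run adjacent to its columns (`replaced_segments()`) is tested
for de novo helix-forming potential; a hit rescues the TM
(`classify_truncation()`). Selection is: at least 4 effective TM helices
and TM1 or TM7 missing; fragment-flagged isoforms are excluded before
analysis. 6TM vs 5TM labels derive from the effective TM count after
rescue; when both TM1 and TM7 are missing the N-terminal label takes
precedence.

## Exon divergence and conservation

`substitution_counts()` counts transitions (A<->G, C<->T) and transversions
per alignment column; columns containing a gap or `N` are excluded from the
aligned length and the counts (ungapped lengths count `N`). Whether
gap-free columns only should enter the counts is asserted as a convention
here, not inferred. `k2p_distance()` is the exact closed form
`K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`, with a saturation error when the
logarithm's argument is non-positive. The same computation serves UTR and
coding regions; a region label is carried through unchanged. Alignment
generation is out of scope (alignments are inputs, or come from the
generator); `align_nucleotide()` (match +1 / mismatch -1 / gap -2) exists
for small demonstrations only. Repeat masking is a pre-masked-input
convention, not implemented.

`conservation_summary()` averages per-base conservation scores (range 0-1,
PhastCons-style) over an exon's own positions; the conventional 100-nt
retrieval flank never enters the mean. The published "+/-" entries
accompanying such means are interpreted as the standard error over
positions (the SD is also reported); with a single scored position the SEM
is defined as 0.

## Enrichment statistics

`fold_enrichment()` is the joint-to-marginal frequency ratio
`k N / (m n)`; `binomial_tail_p()` is the exact one-sided upper tail
`P(X >= k)` for `X ~ Binomial(n, m/N)`, summed directly in log space.
The one-sided upper-tail convention is not stated with the published
numbers, but recomputing all three printed p-values (1.04e-6, 0.01, 0.002)
from the printed counts confirms it; that recomputation is itself a unit
test. Symbols match case-insensitively with no alias resolution, and no
multiple-testing correction is applied (raw p-values are reported, as in
the source analysis). Fold is reported rounded to one decimal and stored at
full precision. A hypergeometric/Fisher alternative is deliberately not the
default: the method under test is the binomial comparison.

## What the generators emulate -- and what they do not

`gen_receptor_locus()` plants the shared opioid-receptor architecture
(exon 1 = start + TM1, exons 2-3 = TM2..TM7, PTC cassette between 1 and 2)
with hydrophobic L/I/V/F-rich helices and hydrophilic S/T/G/N/P-rich loops,
codon-level construction guaranteeing an in-frame AUG at the exon-2 start,
and UTR/intron filler drawn from {A,C,T} so no incidental AUG/CUG/GUG can
precede the planted starts. The generator verifies its own truth (7 helices
on the canonical protein; the planted number on the PTC fragment) and
redraws hydrophilic segments on violation, erroring after 100 attempts.
Realistic codon usage, splice-signal sequence, and uORF content are
explicitly not modelled, and loops are compositionally idealised -- passing
tests therefore demonstrate correctness of the decision logic on
unambiguous architectures, not predictor accuracy on borderline natural
sequences. `gen_isoform_benchmark()` plants whole-TM deletions with
5-residue margins (accuracy on sub-helix deletions is governed by
`coverage_min`, not tested as truth). `gen_k2p_pair()` parameterises by
realised-proportion targets rather than rate x time, so the closed form is
itself the oracle and no substitution-process machinery is needed; indels
are not simulated. `gen_enrichment_universe()` plants exact or
hypergeometric-null overlaps on synthetic symbols. All generators are
seed-deterministic down to written bytes and restore the caller's RNG
state.

The full disorder and GPCR gene lists are supplementary data not shipped
here; `synthetic_supplementary_gene_sets()` reconstructs a universe that
matches every published marginal exactly (sizes 800/1383/383/824, N =
19,020; 6TM overlaps 7/4/3; all-GPCR overlaps 118 and 96, the integer
counts implied by the published ~3.4x and ~1.6x folds, with a chance-level
17 for addiction). The 12-gene 6TM list is the published one
(`sixtm_truncated_genes()`); every filler symbol is synthetic. Checks run
on these lists validate the arithmetic on a reconstructed input, not the
curation of the original lists.

## Problem sizes and numerical choices

The simulation scales used throughout were chosen as the package's study
conditions: 50 planted loci for topology classification, 20 benchmarks of
10 genes for the screen, 200 evolved pairs of 10 kb for K2P parameter
recovery (the mean estimate falls within 2% of the planted distance, as the
acceptance tests verify), 1,000 random cases for each brute-force oracle
comparison, and 1,000-5,000 draws for null calibrations. Binomial tails are
summed in log space (log-sum-exp), keeping p-values near 1e-30 exact to
working precision; the K2P domain check rejects saturated inputs rather
than returning `NaN`; coordinates are 1-based closed internally (BED
converted at the boundary); minus-strand exon lists are stored 5'-to-3' in
transcript orientation.

## Known limitations

* The hydropathy predictor is intentionally simple; it has no topology
  (in/out) model, no signal-peptide logic, and will disagree with HMM-based
  predictors near marginal helices.
* Reproduction of the published human-macaque exon divergence values is out
  of scope (requires genome retrieval); the divergence module is validated
  against planted truth and an independent phylogenetics implementation
  instead.
* Transcripts sharing exons with an antisense gene are representable (a
  transcript is just exons on one strand) but receive no special handling.
* IRES-mediated initiation is noted metadata only; reinitiation here is
  AUG-based.
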
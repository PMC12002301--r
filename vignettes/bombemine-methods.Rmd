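---
title: "Methods: mining and characterizing bombesin-type neuropeptide systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing bombesin-type neuropeptide systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bombemine)
```

`bombemine` implements the computational chain by which a bombesin
(BN)-type neuropeptide signaling system can be discovered in a phylum
where none was previously known: candidate precursors are mined from
nucleotide sequence collections, mature peptides are predicted with a
prohormone-processing grammar, predictions are grouped into
cross-species families, and orthology is tested on three independent
evidence lines — conserved alignment columns, clade membership in a
supported tree, and shared intron positions/phases. Peptide mass and
fragment-ion prediction support mass spectrometric confirmation, and a
pharmacology module quantifies receptor and organ responses. This
vignette documents the models, the tunable parameters and their
defaults, the synthetic-data generators the tests rely on, and the
numerical choices made where the design was genuinely open.

## The prohormone-processing grammar

Neuropeptide precursors are secreted proteins: an N-terminal signal
peptide followed by peptide-coding segments bounded by convertase
cleavage sites. The grammar implemented here assumes:

* **Cleavage** occurs C-terminal to dibasic sites (KR and RR by default;
  KK and RK can be enabled, as can single-R monobasic sites). Overlapping
  pairs are resolved leftmost-greedily, so "KRR" is a KR site. The basic
  residues are assigned to *neither* mature product, reflecting
  carboxypeptidase trimming — the mature 14-residue starfish peptide
  EPRRNYNRVFGPTY-NH₂ carries no flanking K/R.
* **Amidation**: a product ending in Gly is recorded as des-Gly amide
  (mass delta −0.98402 Da, monoisotopic).
* **Pyroglutamate**: an N-terminal Gln is flagged as potential pGlu
  (−17.02655 Da). Glu-derived pGlu is not assigned by default; the known
  pGlu peptides of this family all begin with Gln.
* **Length filter** `min_len`–`max_len` (default 5–40 residues), applied
  after Gly removal. Bioactive family members range from 9 (phyllolitorin)
  to ~30 residues (gastrin-releasing peptide), comfortably inside it.

One rule deserves emphasis because it decides a real ambiguity. A
dibasic site whose upstream product (measured from the previous
boundary) would be non-empty but shorter than `min_len` is *demoted*: it
is not used to segment the precursor, and instead the full-length
segment is reported as a `parent` peptide and the portion C-terminal to
the demoted pair as a `child`. The motivating case is the internal RR at
positions 3–4 of the 14-residue peptide above: cleaving there as a
primary site would strand a two-residue "EP" stub, which is an unlikely
convertase product, yet the N-terminally truncated decapeptide is a real
partial-processing form found alongside the full peptide in tissue
extracts. Reporting both, linked as parent/child, matches what is
observed without privileging either. A short stretch at the bare protein
N-terminus (an unprocessed leader whose true start may lie upstream of
the sequenced fragment) never demotes the first site; only stubs
downstream of the signal peptide or of a previous cleavage do.

### Signal-peptide gate

An intentionally transparent heuristic stands in for dedicated signal
peptide predictors (which cannot be redistributed or assumed present):
the gate fires when a basic residue occurs in the first five positions
and an 8-residue window within positions 3–25 has mean Kyte–Doolittle
hydropathy ≥ 2.0; the cleavage position is the first small residue
(A/G/S/C, the signal-peptidase −1 rule) at or after the end of that
window, within positions 15–35. Externally computed signal calls can be
supplied via `override` and take precedence. The heuristic is calibrated
to the generator below, not to real proteomes — on real data an external
predictor should be used and passed through.

### Precursor-likeness score

Candidates are ranked by a fixed additive score:
2·[has signal] + 2·[≥1 amidated, cleavage-bounded peptide] +
1·[family-motif hit] + 0.5·[peptide adjacent to the signal-peptide end].
The weights express a qualitative ordering (structural evidence counts
double, the motif once, adjacency breaks ties — the family's defining
peptide sits immediately after the signal peptide in known precursors);
they are not trained. The score replaces a trained profile model with a
reproducible, inspectable criterion; an externally computed score column
can be substituted when a trained model is available. The top
`top_k = 5000` candidates are retained, the same working depth a
realistic screen would use.

## Family clustering

Predicted peptides from distinct precursors (and, optionally, distinct
species) are linked when their terminal windows share ≥ *m* of *k*
residues (defaults *k* = 6, *m* = 4, C-terminal — BN-family peptides are
defined by their C-termini). For peptides shorter than *k* the window
shrinks and the threshold scales as ⌈*m*·len/*k*⌉. Families are
single-linkage connected components with ≥ 2 members: terminal
similarity is treated as transitive evidence of family membership, which
matches how candidate lists are actually screened, at the cost of
potential chaining; the clique alternative would fragment families over
single divergent positions.

## Alignment and conserved columns

Pairwise alignment is global Needleman–Wunsch with affine gaps (a gap of
length L costs `gap_open + (L−1)·gap_extend`; defaults −10/−1,
BLOSUM62). Traceback ties are broken deterministically: diagonal over
up over left. Residues missing from the substitution matrix score 0
against everything. The progressive MSA takes its merge order from UPGMA
(average-linkage `hclust`) on pairwise alignment identity distances and
merges profiles with mean-of-pairs column scores; sequences are
processed in id order internally, so the result is independent of input
order. The DP kernels are compiled (Rcpp), as alignment is the only
stage whose cost grows quadratically in sequence length.

Conserved columns follow a group-aware rule: a column is reported, per
residue, when that residue occurs in at least one group-A row (e.g. an
echinoderm peptide) and at least `min_b` group-B rows (e.g. chordate
peptides). "Several" is quantified as `min_b = 3` by default and is
configurable; 2 would admit too many coincidences at peptide lengths of
10–15, while 4 would demand more chordate sampling than a typical
alignment contains. Manual curation steps applied to published
alignments are not reproducible and are not attempted.

## Gene structure

The spliced aligner is anchor-chain-extend: exact `anchor_k`-mer matches
(default 12 nt) between transcript and genomic sequence are merged into
maximal exact segments, chained by a dynamic program that maximizes
matched transcript coverage subject to intron lengths in
`[min_intron, max_intron]` (defaults 30–100000 nt), and junction
placements inside the ambiguity overlap are chosen to satisfy GT..AG.
Full transcript coverage is required; anything less raises
"unalignable" rather than returning a partial model. Intron phase is
the number of nucleotides of the interrupted codon lying 5′ of the
intron — `(CDS nt upstream) mod 3` — and introns outside the annotated
CDS get no phase. The CDS offset is taken as an annotation input rather
than inferred from the longest ORF, because a chance upstream in-frame
ATG in a UTR would silently shift every downstream coordinate.

For cross-species comparison, each intron is assigned to the alignment
column of its interrupted codon (phase 1/2) or of the preceding codon
(phase 0), and columns where ≥ 2 species carry an intron of equal phase
are marked shared. A phase-1 intron interrupting the peptide-coding
region and a phase-0 intron near the 3′ end of the coding sequence,
conserved across phyla, are exactly the kind of orthology evidence this
table is designed to surface, alongside lineage-specific introns that
appear in only one group.

## Phylogeny

Distances are p-distances with pairwise gap deletion, optionally with
the Kimura protein correction d = −ln(1 − p − 0.2p²); p ≥ 0.85 is capped
(with a warning) before correction since the correction diverges.
Trees are built with Saitou–Nei neighbor joining, with two determinism
rules: Q-score ties join the lowest-index pair, and negative branch
lengths are clamped to zero with the deficit moved to the sibling
branch, preserving path lengths through the joined node. Bootstrap
support resamples alignment columns with replacement and counts, for
each internal bipartition of the full-data tree, the fraction of
replicate trees containing it.

Distance+NJ is a deliberate desk-scale stand-in for maximum-likelihood
inference with rate heterogeneity: the package's validation surface is
clade recovery on data with known structure (NJ is exact on additive
distances), not reproduction of any published topology. Externally
computed trees can be read from newick and fed directly to the clade
test. The clade test itself roots the tree on a declared outgroup
(falling back to single-leaf rooting if the outgroup is not
monophyletic), finds the smallest clade containing the query and all
reference leaves, and requires that it exclude every contrast leaf. In
the orthology pipeline the claim is additionally gated on bootstrap
support ≥ 0.9 for that clade's bipartition: a compositionally biased
but structureless query can drift into a family clade under distance
methods, and demanding a well-supported node is the standard guard.

## Mass spectrometry support

Monoisotopic and average residue masses are fixed package constants;
the test suite checks them against an independent elemental-composition
oracle (residue formulas × atomic masses) to 10⁻⁴ Da, so the constants
and the oracle are separate codes. Neutral peptide mass is the residue
sum plus water plus terminal deltas (amide −0.98402 Da, pGlu −17.02655
Da, monoisotopic). Fragment prediction covers b/y ions (the dominant
CID series), singly and doubly charged by default, with the N-terminal
delta applied to b ions and water plus the C-terminal delta to y ions,
so that complementary pairs sum to the neutral peptide mass — an
identity asserted for thousands of random peptides. Spectrum matching
assigns each theoretical ion greedily to the nearest unused peak within
a ppm tolerance (config; instrument-dependent) and reports the fraction
of inter-residue bonds supported by ≥ 1 ion.

## Pharmacology

Receptor-assay luminescence is normalized within each experiment to its
own maximum (100%), so experiments of different absolute brightness are
comparable. The 4PL model is parameterized in log10 concentration:

$$resp = bottom + \frac{top - bottom}{1 + 10^{\,hill\,(\log_{10}EC_{50} - \log_{10}conc)}}$$

fitted by least squares on all replicate points jointly (not on
per-concentration means — replicates carry the error information), with
multi-start Levenberg–Marquardt: bottom/top from the response range,
log-EC50 at the concentration nearest half-range, Hill slope in
{0.5, 1, 2} plus ±1-log EC50 jitter, best residual sum of squares wins.
Fits require ≥ 4 distinct positive concentrations and refuse degenerate
(zero-variance) responses. Organ pharmacology uses percent-of-reference
normalization (a reference agonist's contraction defines 100% within
each preparation); cumulative (no-wash) dose series are reported as
measured and flagged when non-monotone rather than forced monotone.
Stomach-area time courses are normalized per animal to the final
pre-injection area. Group comparisons use the classical pooled-variance
two-tailed Student's t-test, with Welch's form behind a flag.

## What the generators emulate — and what they do not

Every stage is validated against planted ground truth:

* `make_precursor()` plants the canonical precursor architecture: a
  21-residue signal region (Met, a basic residue, a strongly hydrophobic
  core, a small residue at the cleavage position), then dibasic-flanked
  14-residue peptides whose segments end with the family consensus motif
  (default `RIFGPxxG` — the echinoderm family C-terminus plus its amide
  donor), separated by linkers free of basic pairs. Decoys contain no
  signal region, no basic pairs and no terminal Gly. The signal core is
  sampled from strongly hydrophobic residues with tryptophan rare and no
  small residues, so the planted cleavage position is identifiable by
  the declared heuristic; real signal peptides are more varied, which is
  why the gate is pluggable.
* `make_gene()` plants GT..AG introns of specified lengths and phases
  into a coding sequence with flanking UTRs, re-rolling intron ends
  until the splice boundary is unambiguous within the anchor window, so
  the planted structure is the unique canonical spliced alignment.
* `make_dose_response()` applies multiplicative normal noise
  (`response × (1 + ε)`, ε ~ N(0, cv)) to the 4PL mean; assay noise is
  not characterized further, and 5% cv with quadruplicates over
  10⁻¹⁴–10⁻⁶ M is used as the realistic test condition.
* `make_spectrum()` emits all singly charged b/y ions plus uniform
  noise peaks — no isotope envelopes, charge envelopes or
  intensity models.

Passing on these generators therefore demonstrates algorithmic
correctness — exact recovery of planted truth, correct formulas,
deterministic behavior — not performance on real transcriptomes, real
chromatograms or real spectra, which contain error modes the generators
deliberately omit (sequencing error, alternative splicing, co-eluting
peptides, heteroscedastic assay noise).

## Problem sizes and numerical choices

The test suite runs at the sizes the recovery claims are stated at:
100-seed proteomes of 10 planted precursors + 500 decoys for discovery
ranking and family recovery; 100 planted three-intron genes for exact
structure recovery; 50 random additive 4–8 taxon matrices for NJ
topology recovery plus 100-replicate bootstraps on 200-column two-clade
alignments; 1000 random peptides for the fragment-mass identity; 200
Monte-Carlo seeds at 5% cv for EC50 recovery (|Δlog₁₀EC50| < 0.1 in ≥
95% of seeds, bias < 0.02). Optimizer tolerance for noise-free 4PL
recovery is 10⁻⁶ in log₁₀EC50; mass comparisons against the elemental
oracle use 10⁻⁴ Da; newick round-trips preserve branch lengths to
10⁻⁹.

## Known limitations

* The signal-peptide gate is a calibrated stand-in; real-data use
  should supply external predictions.
* The precursor score is untrained; its weights order evidence types
  but the absolute scale is arbitrary.
* Distance+NJ can mis-place compositionally unusual sequences
  (long-branch effects); the support gate mitigates but does not
  eliminate this, and published ML topologies can be imported instead.
* The spliced aligner requires exact anchors and full transcript
  coverage; it will refuse diverged cross-species transcript/genome
  pairs rather than guess.
* Monobasic cleavage is limited to single arginine and is off by
  default; unusual processing (e.g. at lysine) is not modeled.
* Dose-response fitting assumes a sigmoid with a single site; biphasic
  curves will fit poorly and are not detected automatically.
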
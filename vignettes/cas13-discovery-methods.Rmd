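---
title: "Methods: mining contigs for Cas13 effectors with cas13scout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining contigs for Cas13 effectors with cas13scout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas13scout)
```

## The discovery problem

Type VI CRISPR-Cas systems encode a single RNA-guided RNase effector,
Cas13, flanked by a CRISPR array of near-identical direct repeats (DRs)
separated by unique spacers. Cas13 proteins are recognisable by two HEPN
(higher eukaryotes and prokaryotes nucleotide-binding) RNase domains, each
anchored by the catalytic motif R-X4-H, and most type VI loci lack the
Cas1/Cas2 adaptation module. `cas13scout` implements a desk-scale mining
pipeline over assembled contigs:

1. detect CRISPR arrays de novo (seed-and-extend repeat finder);
2. extract 20 kb of flanking DNA on each side of every array;
3. call ORFs in all six frames under the bacterial genetic code and keep
   proteins of **more than 400 residues**;
4. score the surviving proteins against a profile-HMM library built from
   family-labelled Cas13 alignments (a hit in any family keeps the protein);
5. require **two** HEPN R-X4-H motifs at least 100 residues apart
   (single-motif proteins are treated as incomplete effectors);
6. classify survivors into known or novel subtypes by UPGMA over pairwise
   global-alignment identity, anchored by labelled reference proteins;
7. characterise the DR (consensus, conservation, base-pair-maximisation
   secondary structure) and match spacers to a target database; and
8. predict the functional crRNA DR orientation from the protein
   architecture: an elongated N-terminal domain (NTD) implies a 5'-DR
   crRNA (Cas13a/c/d-like), its absence a 3'-DR crRNA (Cas13b/X/Bt-like).

Every step is exposed as a data-frame-in / tibble-out function so the
pipeline can be run piecewise; `run_discovery()` chains them and returns a
`cas13_report` with per-stage counts.

## Array detection

No published parameter set exists for the array detector used upstream of
this kind of survey, so the finder is a CRT/MinCED-style seed-and-extend
detector with explicit, conservative defaults chosen to bracket the
observed type VI repeat (~36 nt) and spacer (~30 nt) scales with margin:

| parameter | default | meaning |
|---|---|---|
| `seed_k` | 8 | exact k-mer seed length (nt) |
| `repeat_len_min/max` | 23 / 50 | admissible repeat-unit length (nt) |
| `spacer_len_min/max` | 20 / 60 | admissible spacer length (nt) |
| `min_units` | 3 | minimum repeat units per array |
| `max_repeat_mismatch_frac` | 0.2 | per-unit Hamming distance to the column-majority consensus |

A k-mer seeds an array when it recurs at distances compatible with one
repeat-plus-spacer period. Seeds are extended column-wise across all
occurrences: a boundary column is absorbed while at least half of the
units agree on one base; extension also stops at the repeat-length cap and
before units would collide. Candidates are then validated against the
length windows and the per-unit mismatch bound, and overlapping candidates
are resolved deterministically (more units, then longer span, then smaller
start). k-mers containing `N` never seed, so assembly gaps cannot produce
repeats. Array strand is reported as `+` throughout; repeat detection is
strand-symmetric and the putative functional DR orientation is decided
later from folding.

With few units the 50% column-identity rule is genuinely ambiguous at
boundaries: a random column that happens to be conserved across three
units *is* part of the repeat under any data-driven definition. The
synthetic-locus generator therefore makes planted truth identifiable by
construction (below) rather than pretending the rule resolves what the
data cannot.

## The synthetic-locus generator

All tests run against generated loci with recorded ground truth; no
external accession is needed. `synth_contig()` draws a background contig
base-by-base from a seeded generator, plants an array and gene cassettes
at recorded coordinates, and returns truth tables whose re-extraction from
the emitted sequence is exact. Three constraints make the planted array
identifiable:

* mutations never touch the first 12 repeat columns, so an exact seed
  k-mer survives in every unit;
* per column, strictly fewer than half the units are mutated, so the
  column-majority consensus equals the planted repeat;
* the two columns flanking each repeat boundary are resampled until their
  across-unit identity falls below 50%, so extension stops exactly at the
  planted boundary.

Planted genes are uniform synonymous back-translations of their protein
(ATG start, random stop codon) preceded by an in-frame stop guard, so the
ORF caller must recover exactly the planted CDS. Family alignments are
per-site mutants of a seeded ancestor with the R/H anchors (and the
motif's second residue) held invariant; accidental R-X4-H motifs are
scrubbed from every emitted protein so motif architecture is exactly the
planted one. Background composition is uniform by default with an optional
GC-bias parameter.

The canonical test metagenome plants three Cas13-like loci (a Cas13a-like
and a Cas13b-like candidate at 10% divergence from their reference
families, plus one candidate from a novel family at ~65% divergence from
Cas13a), Cas1/Cas2 genes beside the Cas13a locus only, and four decoys
that must each die at a designed stage: a 350-aa truncation (length
filter), a shuffled and a motif-free random protein (HMM search), and a
single-HEPN homolog (dual-HEPN filter). All arrays plant 36-nt DRs and
30-nt spacers, the published averages for these systems. What passing
these tests does *not* show: behaviour on real metagenomes with indels,
compositional bias, degenerate repeats, nested arrays or fragmented
assemblies — none of which the generator emulates.

## Profile HMMs

The family models are minimal Krogh-style profile HMMs: match states from
alignment columns with gap fraction below 0.5, insert and delete states
around them, transition set M→{M,I,D}, I→{M,I}, D→{M,D}, and global
alignment of the whole protein to the profile. Emissions are add-one
pseudocounts over the 20 amino acids, `(count + 1)/(total + 20)`;
transitions are add-one over each state's admissible moves, estimated from
the observed per-sequence state paths (D→I / I→D adjacencies, which the
reduced transition set cannot represent, are not counted). The background
is uniform 1/20 and scores are log-odds in bits,
`log2 P(seq | profile) − log2 P(seq | background)`, computed in log space
by compiled Forward/Viterbi kernels; both are checked against exhaustive
path enumeration on small profiles. Non-standard residues (B, J, O, U, X,
Z) emit the background probability and are score-neutral.

The default acceptance threshold is 20 bits. There is no E-value
calibration (that needs large random-sequence fitting, out of scope here)
and no local alignment mode; ranking operates on bit scores only. With
few, closely related reference sequences the add-one pseudocounts make
profiles deliberately soft; the search is a gate, not a classifier — final
family labels come from the taxonomy stage.

## HEPN rules and crRNA orientation

HEPN detection is motif-anchored rather than domain-HMM-based: every
window with `R` at position i and `H` at i+5 is a hit, overlaps included,
and the RNXXXH variant (asparagine at the second position) is recorded per
hit. Two hits at least `min_separation_aa = 100` residues apart count as
two HEPN domains ("at least two", not "exactly two"); Cas13 HEPN domains
sit near opposite termini, and 100 aa cleanly separates two motifs of one
domain from two domains. The NTD call is an offset heuristic: NTD-present
iff the first motif starts at or beyond `ntd_offset_aa = 250` (the
boundary itself counts as present). The default separates the
Cas13a/c/d-like architectures (first HEPN deep in the protein) from
Cas13b/X-like ones (HEPN near the N terminus); it is a proxy for the
structure-based NTD delineation used with real proteins. The orientation
rule is then: NTD → 5'-DR crRNA; no NTD (but HEPN-positive) → 3'-DR;
no HEPN anchor → undetermined. Raising the offset can only move calls from
5' to 3', never the reverse.

## Subtype classification

Pairwise distance is `1 − identity` under Needleman-Wunsch global
alignment with match +1, mismatch 0, linear gap −1; identity is identical
aligned positions over alignment length, and pairs are ordered
canonically before aligning so ties cannot break symmetry. UPGMA merges
the closest pair with size-weighted mean updates; ties break on the
lexicographically smallest pair of cluster labels (a cluster is labelled
by its smallest member id), making the tree order-independent. Node height
is half the merge distance, so the tree is ultrametric and cophenetic
distances reproduce ultrametric inputs exactly. Trees export to Newick
with height-difference branch lengths.

Cutting the tree at `cut_height` yields clusters; a cluster with
references of exactly one family inherits the family, reference-free
clusters become `novel_k` (numbered by smallest member id), and clusters
mixing reference families are flagged ambiguous rather than silently
merged. The package default cut is 0.35 (70% divergence). The canonical
fixture run uses 0.25: its novel family must simultaneously pass the
20-bit HMM gate (which bounds its divergence from the known families
above) and fall outside every known-family cluster (which bounds it
below); at 70% those bands leave no robust margin for a generated family,
at 50% they do. The threshold behind real subtype counts is unstated in
the source material, and no particular clade count on real data is
claimed. A distance-based UPGMA tree deliberately stands in for
maximum-likelihood phylogenetics, which is out of scope.

## DR structure and protospacer matching

The DR consensus is column-majority (ties resolved by base order
A < C < G < T), transcribed to RNA, with per-column conservation reported;
length-discordant repeats are end-padded and flagged rather than
realigned. Secondary structure uses Nussinov base-pair maximisation
(Watson-Crick plus G-U wobble, minimum hairpin loop of 3), not
thermodynamic folding: pair counts are exactly verifiable against
enumeration at these lengths, which a free-energy model is not. Structure
similarity across DRs is therefore reported as pair counts and pair maps,
never as free energies. Both the consensus and its reverse complement are
folded and the denser orientation is flagged — explicitly a heuristic —
as the putative functional DR orientation. Spacer matching is ungapped
(protospacers are rarely gapped): every alignment of each spacer on
either target strand with at most 3 mismatches is reported in forward
target coordinates; spacers shorter than 15 nt are rejected.

## Determinism, problem sizes, degenerate inputs

Every generator is a pure function of its seed (RNG state is saved and
restored around each call), and the pipeline itself contains no
randomness, so identical inputs give byte-identical reports; the test
suite asserts this at file level. The shipped checks run at these sizes:
100 planted-array contigs of 20-50 kb plus 100 dinucleotide-shuffled
controls (Altschul-Erickson shuffle, exact dinucleotide counts); 50 random
3-kb sequences against the six-frame ORF oracle; exhaustive
Forward/Viterbi enumeration over profiles with up to 3 match states and
all sequences of length up to 4 over a three-letter sub-alphabet (the full
20-letter grid is combinatorially out of reach; the oracle itself is
exact); 1,000 random proteins for the motif scanner; 20 random 6-leaf
matrices against a naive UPGMA plus `hclust` average-linkage as a second
cross-check; 200 random RNAs of length up to 12 against structure
enumeration; and the five-contig canonical metagenome end to end.

Degenerate inputs are defined rather than accidental: empty FASTA reads
as an empty table; duplicate record ids are an error (downstream joins
key on id); lowercase and `U`-coded input is normalised, other ambiguity
codes are rejected; a homopolymer cannot seed an array (its gaps violate
the period bounds); a tandem repeat without spacers is rejected by
`spacer_len_min`; an empty contig set yields an empty report with zero
counts and success.

## Known limitations

* The array detector's 50% boundary rule over-extends on very few units
  when a flanking column is conserved by chance; exact boundaries are only
  guaranteed where the data make them identifiable.
* Global-only profile alignment penalises domain fusions and fragments;
  there are no E-values, so bit thresholds are not comparable across
  profile lengths.
* The NTD offset rule is a one-dimensional proxy for structural domain
  calling.
* The 400-residue filter is applied before the HMM search (the pipeline's
  stage order); genuinely short effectors below it are invisible, and the
  alternative order is available via configuration.
* Subtype labels depend on the cut height and the reference panel; novel
  numbering is stable only for a fixed input set.
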
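---
title: "Methods: degenerate-primer surveys of WS/DGAT genes"
author: "ampliseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degenerate-primer surveys of WS/DGAT genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The survey procedure

Bacterial wax ester synthase / acyl-CoA:diacylglycerol acyltransferases
(WS/DGAT, also called Atf) catalyze the last step of neutral-lipid (TAG and
wax ester) storage and carry a small set of strongly conserved sequence
elements — most prominently the active-site heptapeptide `HHxxxDG`, plus
the `ND` and `PLW` elements — embedded in an otherwise fast-evolving
protein. That architecture supports a classical culture-independent survey:

1. align reference orthologs, find conserved blocks, and reverse translate
   them under a codon usage table into IUPAC degenerate primer pairs;
2. validate the pairs in silico against known positive and negative
   templates (the desk analogue of a pure-culture PCR panel);
3. amplify environmental DNA, clone, and dereplicate the clone library by
   in-silico RFLP (HhaI or HincII digestion patterns);
4. trim primers, select a reading frame, translate, and verify the
   conserved motifs;
5. flag chimeric clones;
6. compute corrected pairwise distances, group sequences into types at a
   distance cutoff, and build a neighbour-joining tree of type
   representatives with bootstrap supports.

`ampliseek` implements every step as a tested, deterministic function, and
adds a synthetic-data generator that plants ground truth (type membership,
chimeras, off-targets) so the whole chain can be validated end to end.

## Models and conventions

**Coordinates.** All user-facing coordinates are 1-based and inclusive.
Codon *s* of an ungapped reference covers nucleotides `3s-2 .. 3s`; a primer
pair anchored at codons *s* (forward block start) and *e* (reverse block
end) implies a product of `3e - 3s + 3` bp, spanning the first nucleotide
of codon *s* through the last of codon *e*. This convention is pinned so
every product size in the package is reproducible arithmetic; published
product sizes quoted to ±1 bp can differ from it by a fencepost.

**Conservation score.** The score of an alignment column is the frequency
of its modal non-gap residue over all rows; gaps count as mismatching
symbols. It is the simplest score consistent with "conserved region", and
block discovery (`find_conserved_blocks`) takes maximal runs of columns at
or above a threshold. With few, moderately diverged references, flanking
variable columns are sometimes conserved by chance and extend an anchor
block; a realistic design panel (many orthologs, deep divergence, as used
for the published WS/DGAT primers) makes this vanishingly rare. The
acceptance script therefore designs on a 16-reference, 35%-divergence
panel while the survey simulation keeps the 5-reference default.

**Reverse translation.** Residues are processed left to right; synonymous
codons are merged position-wise into one IUPAC codon in descending usage
order (ties alphabetical) while (a) every expansion of the merged codon
still translates back to the residue and (b) the running product of
per-residue degeneracies stays within the cap (default 128). The
translate-back constraint matters for six-codon residues (L, R, S), whose
full codon sets cannot be captured by a single IUPAC codon without
admitting foreign amino acids.

**Melting temperature** uses the Wallace rule (2 °C per A/T, 4 °C per
G/C) with degenerate positions contributing the average over their base
set — a deliberate, order-of-magnitude estimate; no nearest-neighbour
thermodynamics.

**In-silico PCR.** A primer binds where at most `max_mismatch` positions
(default 2) fail IUPAC compatibility and the `three_prime_exact` bases
(default 3) at its 3' end all match, reflecting the polymerase's
3'-extension requirement. Both strands are searched; every convergent
forward/reverse combination within the size window is reported (no
"dominant band" heuristic). Defaults were chosen so the published
degenerate primers hit their own source-gene architecture exactly while
shuffled templates stay negative, and the tests verify both. Templates
with ambiguity codes are rejected: clone and genome inputs should be
resolved sequence.

**RFLP.** Digestion cuts at every site occurrence (complete-digest
semantics, overlapping sites included) at the enzyme's top-strand offset:
HhaI `GCG^C`, HincII `GTY^RAC`. Fragment lengths always sum to the input
length. Because HincII cuts bluntly at the centre of its palindromic site,
its pattern is identical whichever strand is read; HhaI leaves 2-nt
3'-overhangs, so the two terminal fragments of a read shift by 2 bp when
the opposite strand is sequenced. Pattern grouping defaults to exact
(0 bp) binning — in-silico fragments are exact — with an optional gel-like
tolerance. The pattern representative is the lexicographically lowest
clone id; singleton patterns are retained.

**Frame selection.** The paper-style pipeline translates clones but no
frame-selection rule is ever stated in such protocols; `best_frame` picks,
among the six frame/strand combinations, the translation with the fewest
stop codons, breaking ties by presence of `HHxxxDG`, then plus strand
before minus and lowest frame. Deterministic by construction.

**Chimera screen.** Reference-database chimera detectors are replaced by a
declared, parameter-light surrogate with the same intent: split the insert
at its midpoint, assign each half its nearest reference by p-distance, and
flag when the halves disagree and each half is closer to its own best
reference by more than a margin δ (default 0.05). In `run_survey` the
chimera call is computed for every trimmed clone and recorded in its own
report column — the exclusion flag still respects stage order (motif
screen first) — because per-clone calls are what precision/recall against
planted truth can be measured on. When no reference set is supplied,
motif-passing representatives of multi-member RFLP patterns stand in.

**Distances and typing.** p-distances use pairwise deletion of gapped
columns. Corrections: Jukes–Cantor `d = -(3/4) ln(1 - 4p/3)` for
nucleotides (saturation at p ≥ 0.75) and the Kimura protein approximation
`d = -ln(1 - p - 0.2 p²)` for translations (saturation near p ≈ 0.854) —
the protein formula because the survey's trees are built from translated
sequences. Sequence types are furthest-neighbour (complete-linkage)
clusters whose internal diameter never exceeds the cutoff; the historical
default of distance-based OTU assignment. The type representative
minimizes the within-type distance sum, ties to the lowest id.

**Neighbour joining** follows Saitou–Nei with the standard Q-criterion;
ties break to the lowest index pair; a negative branch length is clamped
to zero with the deficit moved to its sister branch so path lengths
through the join are preserved. On additive matrices the input tree is
recovered exactly (tested to 1e-9 against path lengths, and against
exhaustive least-squares topology search for small n). **Bootstrap**
supports resample alignment columns with replacement; each internal edge
of the full-data tree receives the percentage of successful replicate
trees containing the same bipartition (supports are mapped onto the
full-data tree, not a consensus). Replicates that saturate under the
correction model are skipped and tallied. **Parsimony** is scoring only
(no tree search): minimal state changes per column by Hartigan's counting
rule, which is exact on multifurcating nodes such as the basal
trifurcation of an unrooted tree and reduces to Fitch's intersection rule
on binary nodes.

## The synthetic generator: what it emulates, and what not

`family_spec()` describes a gene family as an alternating layout of
conserved anchor peptides and variable regions. The default layout plants
`RPLWEM` (forward primer anchor), an `HHxxxDG`-matching block, an
`ND`-containing block, and `SNVPAG` (reverse primer anchor), spaced so the
anchored product is 798 bp — the ~800 bp regime of a WS/DGAT degenerate
survey. References substitute variable-region residues i.i.d. (default
divergence 0.15 per site, 5 references); anchors are never mutated, and
their residues are encoded with the modal codon of the usage table, so
anchor blocks are conserved at the nucleotide level the way deeply
conserved primer sites are in real families.

`library_spec()` draws clones from the references' amplicons with i.i.d.
substitution errors (default 0.01 per site, Sanger-library scale); a
fraction are exact-midpoint fusions of two distinct references' amplicons
(default 0.10) and a fraction are base-composition-matched shuffles that
keep the primer ends and the product size but no anchors (default 0.05),
so they pass the size filter and fail the motif screen. Everything is
deterministic under the spec seed, and `generate_library` returns the
planted truth table alongside the FASTA-ready clones.

Deliberate simplifications: substitution-only errors (no indels — the
downstream distance code assumes length-preserving, codon-aligned
inserts); chimeras fuse exactly at the midpoint, which is favourable to
the split-half detector and is acknowledged as such; off-targets are
shuffles, not real foreign genes. Passing the end-to-end tests therefore
shows the pipeline's bookkeeping and statistics are correct under the
stated noise model; it does not certify behaviour on indel-rich or
low-quality real reads.

## Calibrating the sequence-type cutoff to the generator

Published surveys define sequence types at 0.01 distance — appropriate
for essentially error-free consensus sequences of near-identical clones.
The generator's conditions are coarser by design: clones of one reference
differ from each other through two independent draws of 1% sequencing
error over a 762-nt insert (254 translated residues), giving within-type
Kimura-corrected protein distances around 0.04 with an upper tail near
0.13 (complete linkage sees the *maximum* pair, and a Binomial(762, 0.01)
error count has a long tail); references differ at ~26% of translated
positions, i.e. between-type distances ≥ ~0.31. Any cutoff inside that
gap separates the planted types exactly; the package uses 0.20, the
approximate midpoint, wherever the synthetic defaults are analysed. With
real, proof-read Sanger consensus data the conventional 0.01 applies
unchanged — `cutoff` is an explicit argument everywhere.

## Problem sizes and determinism

The shipped tests and the acceptance script run, on one CPU in a few
minutes: 100-clone libraries (798-bp amplicons, 5 references), RFLP
dereplication to ~30 patterns, typing over pattern representatives, and
1,000-replicate bootstraps over the 5 type representatives; the
neighbour-joining oracle checks use 100 random additive matrices (n ≤ 8)
with exhaustive least-squares search at n ≤ 6; parsimony is verified
against exhaustive internal-state enumeration on all 4- and 5-taxon
topologies. Every stochastic step takes an explicit integer seed; rerunning
any pipeline entry point with the same inputs and seed reproduces outputs
byte for byte.

## Known limitations

- No thermodynamic annealing model, hairpin/dimer screen, or PCR
  efficiency simulation; amplification is a combinatorial predicate.
- The chimera surrogate needs trusted references (or clean multi-member
  patterns) and a detectable breakpoint near the split; it will miss
  fusions of very similar parents, and clones whose primer ends are too
  damaged to trim are removed before any call can be made.
- Distance code expects aligned, equal-length inputs; there is no internal
  aligner. The generator respects this; real data must be aligned
  upstream.
- Parsimony is Fitch/Hartigan scoring of a given topology only; tree
  search, maximum likelihood, and outgroup-aware rooting beyond "root on a
  named leaf" are out of scope.
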
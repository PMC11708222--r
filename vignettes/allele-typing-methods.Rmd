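---
title: "Methods: marker-gene allele typing, dispersal, and single-gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gene allele typing, dispersal, and single-gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelegeo)
```

## The model

`allelegeo` types isolates of one species at a small panel of diagnostic
positions in a single marker gene and asks two questions of the resulting
allele groups: how widely each group is dispersed geographically, and how
well the single-gene phylogeny recapitulates clades assigned from external
(typically genome-wide) data.

The central assumption is that the input is one coding sequence per isolate
over the IUPAC nucleotide alphabet, with heterozygosity collapsed into
ambiguity codes (`R` for A/G and so on) rather than phased into two
haplotypes.  Everything downstream respects that encoding:

* **Compatibility, not equality.**  Two IUPAC codes match when their base
  sets intersect (`iupac_compatible`).  This is the only sequence
  comparison primitive used in probe scanning, SNP counting and p-distance,
  so a heterozygous position never creates a spurious mismatch against
  either of its two underlying alleles.
* **Calls are amino-acid sets.**  At a diagnostic site the observed codon
  is expanded over its ambiguity codes into concrete codons and translated
  with the standard genetic code; one amino acid is a homozygous call, two
  or more a heterozygous call.  An amino acid outside the site's configured
  allele list is reported verbatim with status `novel` — the panel should
  discover new alleles, not hide them.
* **Search, don't index.**  Sites are located by scanning for a probe (the
  reference codon plus 6 nt of flank on each side, a 15-nt window within
  the 7–16-nt range that keeps probes specific but tolerant) rather than by
  coordinates.  Indels anywhere outside a probe window therefore cannot
  shift a call.  A probe matching at two places makes the isolate untypable
  (`multiple_hits`) instead of silently picking one — mistyping is worse
  than an explicit failure.

### Composite genotypes and groups

An isolate's composite key concatenates the site calls in panel order, with
heterozygous alleles sorted alphabetically and joined by `/`, then a
deletion suffix: `FL` (full length) or `Δ` (block deleted), e.g.
`189A/T-223D/G-405L-475H/L-FL`.  The key is a pure function of the calls,
so key equality is the grouping relation.  Sites that fail
(`not_found`/`multiple_hits`) are keyed `?`/`!` and make the isolate
untypable; untypable isolates are listed alongside the groups rather than
forced into them.

### The repeat-flanked deletion

The default panel carries a 36-codon block (residues 524–559) that can be
cleanly excised by recombination between two copies of an 8-nt direct
repeat.  For the excision to remove exactly the block, the repeat copies
must tile its boundaries: the package places copy 1 as the first 8 nt of
the block and copy 2 as the 8 nt immediately following it, so that
recombination retaining a single copy deletes precisely the 108 nt of the
block.  Detection measures the distance between two 15-nt anchor probes
(immediately upstream of the block; immediately downstream of the second
repeat copy): a gap of 0 is `full_length`, a gap equal to the block length
is `deleted`, anything else — including a heterozygous deletion, which an
IUPAC string cannot encode — is `undetermined`.  The number of repeat
copies surviving between the anchors (two expected in full-length alleles,
one in deleted alleles) is reported as a consistency check only; the gap,
which is fully determined by the panel geometry, decides the state.

### Open reading frames and frameshifts

Translation proceeds codon by codon until the first stop (a codon counts
as a stop only when every ambiguity expansion is a stop).  The sequence is
then globally aligned to the reference; the running net indel length along
the alignment, taken modulo 3, flags frameshifts, and the reference codon
containing the first indel is reported.  On the synthetic reference, a
single-nucleotide deletion inside codon 138 is engineered to put the
shifted reading frame onto a stop right after residue 148 — a worked
example of the truncation architecture seen in natural loss-of-function
alleles, verifiable end to end with `translate_orf`.

### Dispersal

Distances are great-circle (haversine) on a sphere of radius 6371.0088 km
(the IUGG mean radius; any conventional radius gives the same qualitative
answers, fixing one makes tests exact).  A group's dispersal statistics are
the maximum and mean over all pairwise distances between members with
coordinates; members without coordinates are counted separately, never
dropped silently.  Locations are identified by name, not by coordinates,
mirroring how sampling sites are reported in survey metadata; the GeoJSON
export emits one feature per (group, location) with the member count.

### Phylogeny

Pairwise global alignment is Needleman–Wunsch with linear gap penalties
(defaults +1 match, −1 mismatch, −2 gap; IUPAC-compatible pairs score as
matches).  Same-gene sequences are near-identical, so pairwise alignment
reproduces the column structure a progressive aligner would give while
keeping the implementation self-contained; traceback ties prefer diagonal,
then a gap in the second sequence, making alignments deterministic.
Distances are uncorrected p-distances in which internal gap columns count
as differences; terminal overhangs are trimmed so that length differences
at the ends do not inflate distances.  Trees are built with classical
Saitou–Nei neighbor joining: the Q-criterion pair is joined at each step,
ties broken by the lowest pair of current indices, negative limb lengths
clamped to zero.  On additive matrices this recovers the generating tree
exactly (topology and branch lengths), which the tests verify against
random trees and against an independent implementation (`ape::nj`).

Concordance with external clade labels treats the unrooted tree's *clans*:
a label passes when some edge separates exactly its members from all other
labeled leaves (unlabeled leaves may fall on either side); the score is the
fraction of labels with at least two members that pass.  Rooting is never
inferred — neighbor-joining trees are unrooted and any rooted reading of
monophyly would be arbitrary.

## The synthetic generator

`simulate_panel` exists so that every stage has ground truth.  It emulates
the statistical structure the analysis assumes:

* a 586-codon reference (long enough to hold the 559th residue plus the
  downstream repeat and anchor, and in the size class of the protein
  family; this is a package default, not a measured value) with the
  engineered repeat, frameshift, and reference alleles described above;
* five allele groups of ten isolates each by default, modeled on the kinds
  of alleles a natural survey yields: a common full-length allele, two
  single-site variants, one allele heterozygous at three sites, and one
  carrying the 36-codon deletion together with the codon-138 frameshift
  (the default `frameshift = "auto"` couples the truncation to deleted
  genotypes, as observed on natural loss-of-function alleles);
* group-private backbone substitutions (8 per group by default) so groups
  behave as clades in the tree;
* per-member background substitutions (rate 0.002/nt by default, the order
  of intra-species marker divergence) restricted to positions outside all
  probe windows, anchors and engineered regions, and chosen to avoid
  creating in-frame stops — functional alleles under purifying selection
  do not accumulate nonsense variants, and keeping ORFs intact makes the
  ORF report informative;
* sampling coordinates drawn per group around a centroid by a random
  bearing and a half-normal great-circle distance with the group's
  dispersion parameter (km).  Sampling along geodesics keeps the scatter
  honest at any latitude, unlike adding Gaussian noise to raw lat/lon.
  Members share named sampling sites (two per site on average) so that
  per-location counts are exercised.

Heterozygosity in explicit genotype strings is planted as the position-wise
IUPAC union of a codon pair chosen to decode back to exactly the two
requested amino acids (minimal nucleotide change from the reference, ties
alphabetical).  The `het_prob` parameter applies when a group's genotype is
drawn at random, and it acts at the *group* level: all members of a group
share one genotype.  Per-member randomization at planted sites would make
members of the same group type differently, contradicting the generator's
own contract that the planted partition is recoverable exactly.

What the generator does **not** emulate: recombination between groups,
within-group genealogy (members are i.i.d. noise around one haplotype),
sequencing error inside probe windows, alignment artifacts from real indel
polymorphism, and selection.  Passing the recovery tests therefore shows
the pipeline is correct under its stated assumptions, not that real panels
are free of untypable or ambiguous isolates.

## Numerical and interface choices

* Codons are 1-based; codon *i* occupies reference nucleotides
  3*i*−2 … 3*i*.  Probe scan offsets are reported 1-based, following R
  convention.
* `U` is normalized to `T` on input; alignment gaps (`-`) are accepted in
  FASTA input and stripped before typing, to tolerate aligned exports.
* Missing coordinates stay missing (never zero), and a record must carry
  both coordinates or neither.
* Analysis regions (e.g. nucleotides 819–1,904 of a gene, with an optional
  numbering offset from the start codon) are extracted before alignment.
* Newick output writes branch lengths with 6 decimals and single-quotes
  labels containing metacharacters; trees re-parse to isomorphic trees.
* All output orderings are fixed (groups by size then key; deterministic
  column orders) so reruns are byte-identical.

The test suite keeps simulations small deliberately: recovery tests use
3–5 groups of 3–10 members, tree tests use 9–20 sequences, and the
oracle-checked properties (alignment optimality by exhaustive enumeration,
neighbor-joining recovery of random additive matrices) use sequences of at
most 6 nt and trees of 4–8 taxa — sizes at which the independent oracles
are exact and fast.

## Limitations

* Heterozygous presence/absence of the deletion cannot be detected from a
  single IUPAC string; such isolates surface as `undetermined`.
* No haplotype phasing: a doubly heterozygous isolate's two underlying
  haplotypes are not reconstructed.
* No bootstrap support, no substitution-model correction (deliberately:
  distances are plain p-distances), no progressive multiple alignment.
* The converter from any particular repository's native matrix format to
  FASTA + TSV is left to the user.
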
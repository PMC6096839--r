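---
title: "How nhkir names non-human KIR sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How nhkir names non-human KIR sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhkir)
```

## The naming model

A non-human KIR designation encodes structure, not history: a
four-character species prefix, the `KIR` acronym, the number of
extracellular Ig-like domains (1–3), a tail-class letter (`L`ong,
`S`hort, `P`seudogene), an optional `W` for provisional "workshop"
genes, an optional `X` marking membership of the deeply divergent
KIR3DX lineage (printed before the tail letter in cattle, after it in
the macaque), and a gene number.  Allele names append up to three
colon-separated digit fields that form a hierarchy of difference
classes:

1. **first field (3 digits)** — alleles whose coding sequences differ
   non-synonymously (different proteins);
2. **second field (2 digits)** — alleles encoding the same protein but
   differing by synonymous substitutions;
3. **third field (2 digits)** — alleles identical across the coding
   sequence and differing only in introns or untranslated flanks.

An `N` suffix marks alleles demonstrated not to be expressed.  The
remaining expression suffixes (`L`, `S`, `C`, `A`, `Q`) encode
laboratory measurements of expression level or localization that no
sequence-only engine can infer, so `nhkir` accepts them as curator
metadata but never assigns them; as of the registry shipped here, none
is in use.

Two representation decisions follow the printed tables rather than any
normalization instinct.  Zero-padding of gene numbers is *data*:
macaque genes are deliberately two-digit (`3DL01`) so that renamed
sequences cannot be confused with their legacy names, while ape and
cattle numbers are unpadded (`3DL1`); equality on the gene number is
therefore string equality, and the per-species width is configuration.
Second, the cattle `3DXL1` and macaque `3DLX1` marker positions are
kept distinct in the grammar — both orders are in print and they are
not the same thing.

Legacy (pre-standardization) names are deliberately *not* parseable by
the grammar: forms like `KIR3DH1`, `Pt-KIR3DL1/2` or `2DL501NK` follow
no common syntax.  They are opaque keys in a lookup table built from
the registry's previous-designation columns, matched after trimming,
optional species-prefix stripping and case folding.  Compound names
containing `/` are indexed both whole and split, because the orangutan
tables use both conventions.  Resolution returns *all* matching current
designations — several legacy symbols were genuinely applied to more
than one locus — and an accession identifier, when supplied, filters
but never enlarges the candidate set.

## Tier classification

Differences between a candidate and a reference coding sequence are
classified codon by codon under the standard genetic code, with the
reading frame anchored at the first base of the annotated cds.
Equal-length pairs are compared directly; length-discordant pairs are
globally aligned with affine gap penalties (match 1, mismatch −1, gap
open −4, gap extend −1 — conventional nucleotide-scale values) through
`Biostrings::pairwiseAlignment`.  Classification then applies three
rules: a substitution codon is synonymous or non-synonymous according
to whether its translation changes; any codon touched by an alignment
gap escalates to the non-synonymous tier (an indel changes the
protein); and codons containing IUPAC ambiguity codes in either
sequence are excluded from the counts and reported.  A sequence more
than 1% ambiguous is rejected outright.  Intron and flank blocks are
compared only when both sequences carry them, since absence of
annotation is not evidence of identity.  Pairs below the comparability
floor (default 0.70 aligned identity) raise a "not comparable" error
instead of a tier — at that distance the comparison is between genes,
not alleles.  If either sequence is marked incomplete the result is
flagged `partial_basis`: the tiers are then evidence over the shared
region only.

## Structural features

The Ig-domain count is annotation-driven (the number of `D0`/`D1`/`D2`
exon spans), never motif-predicted: alternative splicing can remove a
domain exon from a transcript, and the precedent for the macaque
lineage-V gene is that genomic exon content, not an individual cDNA,
defines the gene.  When a genomic exon table accompanies a transcript,
it wins.

Tail class is the one feature the nomenclature leaves qualitative.
`nhkir` types a tail **L** when the cytoplasmic exon is at least 60
codons long *or* its peptide contains an ITIM-like motif
(`[ILVS]-x-Y-x-x-[LV]`), else **S**.  Sixty codons sits comfortably
between the two natural classes (short activating tails run a few
dozen codons; long inhibitory tails carry tandem ITIMs and roughly
double that), and the motif rescues truncated-but-inhibitory tails.
Both the threshold and the pattern are configuration
(`kir_allocator_config()`), and the decision is recorded in the
feature report.

Null-allele (suffix `N`) candidates are flagged on three lesions: a
premature in-frame stop before 90% of the annotated protein length
(stops in the final tenth typically spare function, and 90% is the
configurable default `premature_stop_fraction`), a frameshift (cds
length not divisible by three in a sequence claimed complete), or a
lost start codon.

## Locus assignment and the recombinant rule

Recombinant alleles are named for the locus contributing the majority
of their sequence.  `kir_assign_locus()` implements this in two
stages.  First, 100-nt windows at 50-nt stride (plus one final window
flush with the 3' end, so no tail goes uncounted) each vote for the
gene of their nearest registered allele; a window whose best identity
is tied between genes abstains.  Second, when more than one gene
collects votes, the two leading genes are compared at nucleotide
resolution: an optimal two-segment changepoint fit against each gene's
nearest allele estimates the fraction of the sequence each locus owns,
taking the midpoint of the optimal-breakpoint plateau (the optimum is
flat between informative sites, and the plateau edge is a biased
estimate).  The leading locus must own strictly more than half the
sequence with a margin of `majority_margin` (default 0.02, i.e. 2% of
the cds): a call inside that band is below the method's resolution and
raises an "ambiguous recombinant" error for manual review instead of a
name.  Ties among three or more contributing loci are likewise
surfaced, never guessed.

The new-gene decision is identity-based, standing in for the committee's
phylogenetic divergence judgement, which is out of scope here.  It is
gated on the *windowed mosaic identity* — the mean over windows of each
window's best per-allele identity — rather than on global identity to
any single allele.  The distinction matters precisely for recombinants:
a chimera of two known genes at 0.90 mutual identity is only ~0.95
globally identical to its majority parent, yet locally near-identical
to one parent everywhere, so a global gate at the 0.96 threshold would
misclassify known-locus recombinants as new genes.  A genuinely
divergent sequence, by contrast, is below threshold in every window.
Sequences failing the mosaic gate become provisional **workshop**
proposals: `W` is a flag, not a namespace, so the proposal takes the
next unused gene number in the species' main series (the divergent-X
series and the number-free `1D`/`DP` forms are numbered apart), at the
species' configured digit width, with domain count and tail class read
from the candidate's features.  Promotion of a workshop gene to a plain
symbol once genomic or segregation evidence arrives is a curator
action (`kir_rename_gene()`), never automatic.

## Name allocation

Within the assigned gene, the candidate is classified against every
sequenced allele.  Exact identity over the full shared region returns
the existing name — resubmission is idempotent and leaves the registry
unchanged.  Otherwise the nearest allele at the deepest matching tier
anchors the new name: a synonymous-only variant extends that allele at
the second field, a non-coding-only variant at the third, and anything
else takes the next first-field number.  Numbers are allocated
max-plus-one, zero-padded to the field width; gaps left by withdrawn
names are historical record and are never refilled; exhaustion of a
field (999/99) is an error.  When a bare short name is first extended
— say `*001` gains a synonymous sibling — the incumbent keeps its
printed form as an alias, its canonical form becomes `*001:01`, and
the newcomer is `*001:02`; this matches the convention that longer
names are assigned only when necessary, and the decision's rationale
trail records the aliasing.  Ties in nearest-allele identity break by
canonical name order, so decisions are deterministic.

Before any of this, submissions face two checks: species with a
full-length mandate (the macaques, by default) reject partial
sequences, and every submission needs replication evidence — at least
two individuals or two independent PCR/cloning experiments.  Failures
reject the submission with the failed check named; nothing is
allocated.  Satellite macaque species (Mafa, Mane) are configured to
assign against the rhesus registry, keeping their own prefix on
output, so their genes are named to match the closest rhesus gene.

## The synthetic generator

`kir_generate_gene_set()` emulates the block anatomy of a KIR
transcript — 21-codon leader starting ATG, one to three 96-codon
Ig-domain exons with the Ig-fold cysteine pair at fixed spacing, a
24-codon stem, a 21-codon transmembrane segment, a cytoplasmic tail of
requested length, a terminal stop — plus 120-nt untranslated flanks.
Genes are derived from one ancestor by substituting
`round(L * (1 - d) / 2)` sites each, which puts pairwise identities
within about ±1% of the target `d` for kilobase-scale sequences;
requests needing more than ~40% substitution per gene are refused as
unsatisfiable.  Codon sampling and substitution both avoid minting
incidental stop codons, so lesions appear only where a mutation class
(`stop`, `frameshift`) requests them.  All randomness comes from R's
Mersenne–Twister generator seeded per call; the caller's RNG state is
saved and restored, and a fixed seed reproduces output byte for byte.

What the generator does *not* emulate bounds what green tests mean:
substitutions are uniform with no transition/transversion bias, no
rate variation, no recombination hotspots, no indel polymorphism
beyond the single-base frameshift class, and domain exons are
idealized in length.  Passing tests therefore demonstrate that the
engine implements the naming rules correctly on sequences with the
right anatomy — not that any particular real dataset would be
error-free, where alignment quality and annotation errors dominate.

## Problem sizes and numerical choices

The shipped test-and-verification workload uses the registry's 364
designations for the grammar round-trip; 1,000 seeded mutants (mixed
synonymous / non-synonymous / non-coding / premature-stop classes,
1–3 sites each) checked against an independent translate-and-compare
oracle built on `Biostrings::translate`; a chimera breakpoint sweep
from 0.55 to 0.95 in steps of 0.05 between two genes at 0.90 identity,
plus the 0.50 even split that must raise the ambiguity error; and 50
sequential tier-1 submissions for the monotonicity and idempotence
properties.  These sizes exercise every decision path while keeping
the whole suite inside a couple of minutes on one core.

Remaining numerical conventions, for completeness: coordinates are
0-based half-open with the frame anchored at the cds start; trailing
partial codons are dropped from translation; ambiguous codons
translate to `X`; accession identifiers are validated by shape only
(letters then digits) and never resolved externally; and deposition-
order ties in allocation break by accession then input order, recorded
in the rationale trail.

## Known limitations

* New-gene calls proxy phylogenetic divergence with an identity
  threshold; borderline lineages deserve a real tree, which is out of
  scope.
* Tier-3 comparison requires both sequences to carry the same
  non-coding blocks; registry alleles without stored flanks can never
  be distinguished at the third field.
* Partial sequences are compared over the shared region and flagged,
  but the nomenclature itself does not say how a partial should rank
  against longer alleles; curators see the `partial_basis` flag and
  decide.
* The registry ships the published tables verbatim, including their
  quirks: one accession pinned to two alleles, and a cattle gene count
  whose prose (16) disagrees with its own table (17 designations) —
  the registry keeps all 17 and flags the discrepancy in metadata.
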
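---
title: "Mining plastome micro-variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining plastome micro-variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmine)
```

`plastmine` mines the marker classes that intraspecific chloroplast-genome
comparisons report — SNPs, microsatellites (cpSSRs), indels and small
inversions — from a set of collinear plastome sequences plus their multiple
alignment. This vignette explains each model and rule, the tunable
parameters, the simulator used to validate the detectors, and the design
choices taken where more than one reasonable definition exists.

## The quadripartite model

A plastome is a circular molecule of roughly 120–160 kb laid out as a large
single-copy region (LSC), an inverted repeat (IRb), a small single-copy
region (SSC), and the second inverted-repeat copy (IRa), where IRa is the
reverse complement of IRb. `detect_quadripartite()` defines the IR pair as
the *maximal pair of disjoint, exactly reverse-complementary repeats* of at
least `min_ir_len` bp (default 1000; real plastome IRs exceed 20 kb, so the
threshold only excludes small dispersed repeats). Detection seeds 25-mers of
the genome against its reverse complement, groups seed hits by diagonal,
extends each candidate to its maximal exact match, and handles wrap-around
on a doubled sequence, so a rotated input — even one cut inside an IR — is
resolved correctly. Requiring *exact* reverse complementarity is a modelling
choice: observed IRa/IRb lengths within a genotype are equal, and exactness
gives an unambiguous, testable definition. Genomes whose IR copies have
internal mismatches are out of scope; they yield either a shorter exact pair
or a structured "no-IR" result in which downstream region labels become
`whole`. Two distinct candidate pairs tying at the maximal length raise an
error listing the candidates rather than guessing.

The shorter single-copy arc is SSC. The canonical presentation rotates the
genome so the LSC starts at position 1; when the strand is otherwise
undetermined (no annotation), the canonical strand is the one whose LSC
sequence is lexicographically no greater than its reverse complement — an
arbitrary but deterministic tie-break. Pipelines that must keep alignment
coordinates fixed use `canonical = FALSE`, which reports spans in the input
genome's own coordinates and requires the input to be region-contiguous
(LSC first), as a whole-genome alignment of collinear genomes presumes.

Coordinates are 1-based inclusive throughout the package, matching R and
Bioconductor convention; BED output is 0-based half-open and VCF 1-based,
with each flat file stating its convention in a header comment. The
coordinate converters are tested to be exact inverses.

## SNP calling and the substitution spectrum

A SNP is an alignment column with no gap in any genotype and at least two
distinct non-N bases. Gap-containing columns are excluded entirely — they
are indel territory — which keeps the arithmetic `total = transitions +
transversions` exact. N alleles are ignored for allele counting; a column
with one non-N state is not a SNP. Multiallelic columns are counted once and
flagged, but excluded from the six-class spectrum. Variants inside the IR
are counted once: a column whose reference position lies in IRa is dropped
when the mirrored IRb position carries the complementary variant
genotype-by-genotype.

Two class presentations are computed. The unordered base-pair classes
(`A-G`, `C-T`, `A-T`, `A-C`, `G-T`, `G-C`) carry the Ts/Tv accounting
(transitions are `A-G` and `C-T`; the ratio is reported as Tv/Ts, `NA` when
there are no transitions). These labels are *not* individually
strand-invariant: complementing a genome maps `A-G` onto `C-T` and `A-C`
onto `G-T`. The strand-symmetric presentation is the directed base-pair
type polarized by the reference allele — `AT>GC`, `GC>AT`, `AT>CG`,
`GC>TA`, `AT>TA`, `GC>CG` — in which a substitution pools with its
complement (C→T with G→A), exactly the "non-strand-specific" six types that
comparative plastome reports tabulate. Both tables live in the
`snp_spectrum` object; the symmetry tests assert invariance of the directed
table and of the Ts/Tv totals, plus the exact complement-mapping of the
unordered table.

`count_site_classes()` reports variable sites (gap-free, ≥2 states) and
parsimony-informative sites (≥2 states each carried by ≥2 genotypes) as raw
alignment statistics; inversion cores count as variable columns here even
though they are not SNPs.

## SSR mining

SSR detection follows the MISA convention: a locus is a maximal perfect
tandem repeat of a primitive 1–6 bp unit whose repeat count meets the
per-unit-length thresholds `c(10, 5, 4, 3, 3, 3)` — so a qualifying
mononucleotide tract is ≥10 bp and a pentanucleotide tract ≥15 bp.
Hexanucleotide units are searched even though plastome surveys rarely find
them. The miner scans the vector of base-equals-base-at-lag-u comparisons
and takes maximal runs of complete units; a repeat whose unit is itself a
repetition of a shorter unit (e.g. `AA`) is reported at the shorter unit
length only. Overlapping loci are resolved by keeping the greater tract
length, breaking ties toward the smaller unit and then the leftmost start.
Qualifying repeats separated by at most `compound_max_gap` bases (default
100, the cited tool's default) merge into one compound locus written
`(ATA)4g(TAA)6`, interruption in lowercase. Loci wholly inside IRa are
suppressed so each IR locus is counted once. The test suite proves the
miner identical to an independent exhaustive enumerator (greedy
backreference regex + quadratic overlap resolution) on 50 random 10 kb
sequences.

Cross-genotype comparison (`compare_ssrs()`) anchors loci through the
alignment rather than by flank matching: per-genotype tracts of the same
canonical motif class (motifs collapsed over rotations and reverse
complements, so `A` and `T` tracts share class `A/T`) whose alignment spans
overlap form one locus cluster. A genotype lacking a qualifying tract at an
anchored locus is still measured and recorded with its actual sub-threshold
tract length; a locus is polymorphic when its carriers show at least two
distinct tract lengths. Two same-class loci of one genotype in one cluster
(an anchor collision) is an error, not a silent merge. `extract_flanks()`
cuts forward-strand flanking sequence (default 250 bp, wrapping through the
circular origin) for an external primer designer; primer design itself is
out of scope.

## Indels and their classification

Indel events are maximal runs of contiguous alignment columns with a
constant gap pattern across genotypes, so a gap run shared by several
genotypes is one event. Columns where the present genotypes disagree split
the event and are flagged `mixed`. Direction is *reference-relative
polarity*, not an ancestral-state claim: a genotype carrying sequence where
the standard reference has a gap shows an insertion; a genotype with a gap
where the reference has sequence shows a deletion. Swapping the reference
therefore flips labels without changing spans or sizes, which is tested as
an invariant.

An event is SSR-related when its present allele is a whole-number tandem
repetition of some rotation of a locus motif *and* its alignment span
overlaps or directly abuts (distance 0) that locus's tract in any genotype;
everything else is a common indel. Distance 0 is the implemented default
for "abuts"; a wider window would admit alleles that merely resemble a
nearby motif. The common-indel size spectrum and per-region frequencies are
reported for sizes 1 to the observed maximum.

## Small inversions and the stem-loop rule

Candidate cores are maximal runs of gap-free mismatch columns between the
reference and a genotype; runs separated by at most `merge_gap` (default 2)
matching columns are also considered jointly, because an inverted core can
agree with the reference wherever a position equals the complement of its
mirror position. A candidate of core length within `[min_len, max_len]`
(defaults 2 and 100 — these are *small* inversions) is an inversion when
the genotype's core equals the reverse complement of the reference core.
The thermodynamic folding step that studies often cite is deliberately
replaced by an exact-complementarity stem rule: the detector searches up to
`flank_window` bases (default 30) on each side for the longest exact
inverted-repeat pair bracketing the core and reports the candidate only
when that stem is at least `min_stem` bp (default 6). The stem is the
flanking repeat, the loop is the inverted core — precisely the quantities
such studies tabulate — so the folding model would add a dependency without
changing any reported number. Mismatch runs failing the reverse-complement
test are left to the SNP caller, and the pipeline masks reported inversion
cores out of SNP calling so the two detectors partition the variant
columns.

One consequence of sequence-only detection: a core that is a perfect
palindrome is unobservable when inverted (the genotype equals the
reference), so no event is reported — there is no variant. The
`palindromic_core` flag marks reported cores whose reverse-complement
equality is trivially true within a wider candidate span.

## The simulator and what passing tests show

`simulate_plastomes()` builds a reference of random LSC/IRb/SSC/IRa at a
target GC (default 0.37), with IRa written as the exact reverse complement
of IRb and the junction bases fixed so the IR pair cannot extend by chance.
The background is screened free of threshold-qualifying tandem repeats by
local repair (an independent regex screen, not the miner under test), and
every planted event's neighbourhood is re-screened after editing — including
the mutated genotypes' contexts, since a deletion or substitution can
otherwise join background into an accidental tract. Events are placed
non-overlapping with ≥50 bp separation (SSR tracts further apart than the
compound-merge distance, or two planted tracts would legitimately merge
into one compound locus). Genotype `G1` is the unmutated standard
reference; each event affects a random nonempty subset of the others.

Default parameters are the study-sized conditions: ~153 kb genomes, 141
SNPs with the transition budget fixed at `round(141 * r/(1+r)) = 88` for
`r = 88/53` (the planted spectrum is exact, not sampled), 66 SSR tracts in
the observed unit mix (37/11/7/4/7 mono–penta, used as exact counts when
the weights sum to the tract budget), 24 of them polymorphic by ±1–3 repeat
units, 44 noncoding common indels of 1–28 bp with geometrically decaying
sizes (1 bp modal) and the range maximum planted once, and 5 inversions
with 2–51 bp cores and 6–22 bp flanks. Inversion flanks are written into
the *reference* so the stem is shared by all genotypes, and cores are
constructed mirror-complement-free so an inverted copy mismatches at every
position and is recovered as a single run. The true alignment is emitted
directly from the edit script — no aligner runs — so detector tests are
independent of aligner behaviour; the aligner is an input contract, not
logic under test.

What passing recovery tests do and do not show: on screened backgrounds
with well-separated events, every detector achieves sensitivity and
precision 1.0, which validates the *definitions and bookkeeping*. Real
plastomes add repeat-rich backgrounds, near-identical IRs, alignment errors
around homopolymers, and overlapping events; none of these are claimed to
be handled beyond what the rules above state. In particular, real SNP and
indel counts inherit any instability of the upstream alignment.

## Numerical and scale choices

Unit tests run on toy genomes of a few kb; the oracle-equivalence checks
use 50 random 10 kb sequences (SSR) and 20 five-kb toys against an O(n²)
brute-force inverted-repeat scan (structure); the end-to-end recovery check
uses six ~30 kb genotypes carrying the full 141/20/44/5 event budget, with
a spacer-rich toy annotation so the noncoding placement constraint has
room. These sizes keep the whole suite near a minute while exercising
every code path at full event density; the simulator defaults remain
study-sized (~153 kb), and `scripts/acceptance.R` runs at that full scale.

Known limitations: exact-IR assumption (no boundary-shift analysis across
species); no imperfect/mismatch-containing SSRs; no codon-aware SNP
classes; indel polarity is descriptive, not ancestral; primer design and
phylogenetics are external.
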
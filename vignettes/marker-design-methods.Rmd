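---
title: "Designing ARMS and CAPS markers from resequencing alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ARMS and CAPS markers from resequencing alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armscaps)
```

## The problem

Marker-assisted selection needs cheap, reliable PCR assays that distinguish
two cultivars at single-nucleotide polymorphisms. Two classic assay types
dominate practice:

* **ARMS** (Amplification Refractory Mutation System): an allele-specific
  primer places its 3′-terminal base on the SNP, so extension proceeds only
  on the matching allele. A *tri-primer* marker combines two
  same-orientation allele-specific primers at two nearby SNPs with one
  shared common primer, giving allele-diagnostic band sizes; a
  *tetra-primer* marker uses opposite-orientation allele-specific primers
  at a single SNP flanked by two common primers, giving an outer control
  band plus two allele bands.
* **CAPS** (Cleaved Amplified Polymorphic Sequences): a SNP creates or
  destroys a restriction-enzyme recognition site; a plain primer pair
  amplifies across it and the digest pattern reads out the genotype.

`armscaps` automates both designs directly from coordinate-sorted
alignments of the two cultivars against a shared reference, so the many
SNPs found by resequencing become usable assay candidates without manual
sequence inspection.

## Genotype calls from the SNP-index

For a position covered by `n` reads of which `k` carry the cultivar-B
specific allele, the *SNP-index* is `k/n`. The package's genotype filters
rest on one statistical object: with true variant dosage `d` of ploidy `m`,
`k ~ Binomial(n, d/m)`, and `snp_index_interval()` returns the central
confidence interval of `k/n` on the exact quantile grid — `lo = q/n` with
`q` the smallest integer whose CDF reaches `(1-confidence)/2`, and
symmetrically for `hi`. The convention (R's type-1 quantile) is stated so
results are bit-reproducible; `monte_carlo_interval()` reproduces the same
interval by simulation and is kept purely as a cross-check oracle.

Three consequences drive the defaults:

```{r intervals}
snp_index_interval(6, 1, 2)   # shallowest depth separating het from hom
snp_index_interval(5, 1, 2)   # one read fewer: nothing can be excluded
min_depth_excluding_homozygous(2, 1)
min_discernible_depth(4)
```

At depth 5 or less the 95% interval of a diploid heterozygote spans [0, 1],
so homozygous positions cannot be excluded; depth 6 is therefore the
default `min_depth` everywhere. In an autotetraploid the three heterozygous
dosage classes (simplex/duplex/triplex) have exactly disjoint 95% intervals
from depth `r min_discernible_depth(4)` upward. We define "discernible" as
disjointness of the closed intervals — the strictest reading — and report
the exact-quantile value; a simulation-based construction with finite
replicates can land a step or two away on this staircase-like quantity, so
small discrepancies with published simulation values are expected and not
corrected for.

## Site selection

`select_target_snps()` emits a position when both cultivars sit within
`[min_depth, max_depth]`, cultivar A shows no non-reference base above
`tolA`, and exactly one non-reference base in cultivar B lies within the
target index range (`[1, 1]` for homozygous markers; the open `(0, 1)`
feeds the dosage filter). Multi-allelic positions are rejected outright: an
assay needs a single discriminating allele. `max_depth` defaults to three
times the region's mean depth, a standard guard against collapsed repeats.

Two refinements mirror the breeding workflows:

* `hetero_select()` keeps sites whose observed index falls inside the exact
  interval for the requested dosage at that site's depth, relabelling them
  (`simplex`, `duplex`, `triplex`, or `heterozygous_diploid`). By
  construction its retention of true-dosage sites equals the interval
  coverage (at least the confidence level), which the tests verify on
  simulated site tables.
* `progeny_filter()` keeps sites that look heterozygous in a random-bulk
  progeny pileup. The bulk of a segregating F2 family carries the two
  parental alleles at an expected 1:1 ratio at every true SNP, so the
  filter always tests against the dosage-1-of-2 interval regardless of
  parental ploidy; the `ploidy` argument is informational.

Two different uses of `tolA` deserve emphasis. During *selection* it
defaults to 0: any non-reference read in cultivar A disqualifies the
position, the strictest notion of cultivar specificity. During *primer
footprint screening* (`primer_params()`) it defaults to 0.1: a footprint
position counts as polymorphic only when a non-reference base exceeds 10%
of its reads. With a strict zero there, a single sequencing-error read
anywhere in a candidate footprint would disqualify it, and at realistic
error rates most thermodynamically valid primers would be discarded for
noise rather than biology.

## Primer design

No external primer-design engine is used; candidates are enumerated and
scored internally so the whole pipeline is deterministic and offline.

* **Thermodynamics.** `melting_temperature()` implements the unified
  nearest-neighbor model (duplex initiation terms per terminal base pair,
  entropic salt correction) at fixed assay conditions: 50 mM monovalent
  salt, 50 nM total oligo (effective annealing concentration 12.5 nM). The
  test suite pins it against an independent nearest-neighbor implementation
  to well under 0.5 °C.
* **Allele-specific primers** (`design_specific_primers()`): the 3′ end is
  anchored on the SNP with the terminal base equal to the targeted allele
  on the primer strand; the base at 3′-offset 3 carries a deliberate
  destabilizing substitution, `A→C, C→A, G→T, T→G`, applied to the
  primer-strand base. The table is one deterministic choice among the
  "non-complementary" substitutions: it never reproduces the original
  base, never complements the template at that position, and favors
  purine↔pyrimidine swaps. Lengths 18–28 are scanned under Tm 57–63 °C
  (optimum 60), GC 30–70%, homopolymer runs ≤ 4, a footprint free of other
  polymorphisms and with in-range coverage in both cultivars; the
  minimum-penalty candidate per allele and orientation is kept, up to four
  primers per site.
* **Common primers** (`design_common_primer()`): exact reference substrings
  within a window, required to contain no polymorphic position and no
  selected site, same thermodynamic constraints. All candidates in a window
  are scored via cumulative-sum nearest-neighbor arithmetic (O(window)
  rather than O(window × candidates)); a brute-force enumeration oracle in
  the tests confirms the optimum is exact.
* **Scoring.** `penalty = |Tm − Tm_opt| + 0.5·|len − len_opt|`; ties break
  to the smaller start coordinate, then the lexicographically smaller
  sequence. Re-running any design on identical inputs is bit-identical.

## Marker assembly and validation

Tri-ARMS pairing requires the two specific primers' 3′ ends (the SNP
positions) to lie 100–300 bp apart and places the common primer 100–700 bp
beyond the nearer specific primer's 3′ end — the window bounds the whole
footprint, a convention we fix explicitly because "within a distance" is
otherwise ambiguous. The two allele products share the common primer, so
their size difference equals the specific-primer spacing exactly, an
invariant the tests assert. Pairs involving non-homozygous sites carry a
`trans_risk` flag: without phase information two heterozygous
cultivar-specific SNPs may lie in trans, and such a marker cannot separate
homozygotes from heterozygotes.

Tetra-ARMS assembly takes the best candidate from each third of both flank
windows and picks the minimum-penalty combination whose allele bands differ
by at least `min_band_separation` (default 50 bp, a practical agarose
resolution limit; the assay literature states none). The identity
`product_A + product_B = product_outer + span(specific 5′ ends)` is checked
exactly.

CAPS design (`find_discriminating_enzymes()`, `digest()`,
`design_caps_marker()`) slides every recognition-width window across the
SNP and requires the site to match for exactly one allele with no window
matching the other; non-palindromic recognition sequences are matched on
both strands with the cut offset mirrored. Fragments are predicted for both
allele products counting *all* sites in the amplicon, and a marker is
accepted only when the two band patterns are distinguishable: every
fragment unique to one pattern must differ by at least
`min_band_separation` from every fragment of the other pattern (our
resolution of the open design question; requiring a unique site in the
product would be stricter than gels demand).

Every emitted marker is validated by construction against an in-silico PCR
oracle (`in_silico_pcr()`): a primer anneals only if its 3′-terminal base
matches the template perfectly with at most one internal mismatch (the
deliberate one), and a marker must amplify each haplotype at exactly its
predicted size and the wrong haplotype not at all. The oracle is
deliberately independent of the design code — it rescans full haplotype
sequences built by applying each cultivar's alleles to the reference.

## The synthetic study and what it does (not) show

`fixture_spec()`/`generate_alignments()` synthesize the whole input side:
a seeded random reference at a chosen GC content and pre-aligned
fixed-length reads (all-match CIGAR, uniform Q40) whose variant-allele
counts are Binomial(depth, dosage/ploidy) per position, with substitution
errors injected at 0.001/base — roughly Illumina-like. Reads are generated
aligned by construction, keeping every test hermetic and alignment-free.

The canonical end-to-end study (`demo_fixture_spec()`) is a 100 kb diploid
genome with 40 homozygous cultivar-B SNPs (400 SNPs/Mb) at depth 30. Two
placements are deliberate rather than uniform: six clusters of three SNPs
at 110–150 bp spacing, because real cultivar-pair SNPs are clustered and a
40-SNP uniform scatter would under-sample the 100–300 bp neighbor pairs
tri-ARMS markers need; and six SNPs inside AluI sites, because only a few
percent of random SNPs overlap a 4-cutter site — guaranteed to occur among
hundreds of thousands of genome-scale SNPs but easily absent from a sample
of 40. The two-density companion (`density_fixture_spec()`, 1 Mb at depth
20, 50 vs 500 SNPs/Mb in adjacent 500 kb bins) reproduces the qualitative
relation between SNP density and marker type: tri-ARMS counts rise steeply
with density while tetra-ARMS markers remain available in the sparse bin.

What passing these fixtures does *not* show: robustness to indels,
structural variants, mapping ambiguity, coverage waves, base-quality
miscalibration, or cross-amplification between subgenomes of allopolyploids
— none of which the generator emulates. Problem sizes (100 kb / 1 Mb
genomes, 2,000 sites for dosage calibration at depth 100) were chosen as
the smallest at which the binomial calibration claims and density trend are
statistically unambiguous.

## Numerical and degenerate-input conventions

All user-facing coordinates are 1-based inclusive. The SNP-index at depth 0
is an explicit error, never silently 0. Pileups skip reference-N positions,
duplicates, secondary and supplementary alignments, and indel-aligned
bases. An empty window, a window shorter than the minimum primer length, or
a flank containing a polymorphism in every footprint yields "no primer"
(and thus "no marker") rather than an error. Sites absent from a progeny
pileup are dropped as unsupported. The HTML report is byte-deterministic
for fixed inputs; run metadata lives in a single header block.

## Limitations

Primer screening covers length, Tm, GC, homopolymer runs, footprint
polymorphism and coverage — not hairpins, primer-dimer thermodynamics, or
genome-wide uniqueness beyond the in-silico PCR check on the fixture
haplotypes. Dosage filtering assumes pure binomial sampling
(no overdispersion or sequencing-error-aware model). Tri-ARMS markers at
heterozygous sites are emitted with a warning flag, not phased.
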
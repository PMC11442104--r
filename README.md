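# armscaps

Automated design of ARMS and CAPS genotyping markers from whole-genome
resequencing alignments of two cultivars against a shared reference.

## The problem

Breeding programs genotype thousands of plants at SNPs that distinguish two
cultivars, using two inexpensive PCR assay families:

* **ARMS** (Amplification Refractory Mutation System): an allele-specific
  primer whose 3′-terminal base sits on the SNP extends only on the
  matching allele. *Tri-primer* markers combine two same-orientation
  allele-specific primers at two nearby SNPs with one shared common primer;
  *tetra-primer* markers place opposite-orientation allele-specific primers
  at a single SNP between two common primers. Genotypes are read from band
  sizes on a gel.
* **CAPS** (Cleaved Amplified Polymorphic Sequences): the SNP creates or
  destroys a restriction site; a plain primer pair amplifies across it and
  the digestion pattern reads out the genotype.

Designing these by hand means hunting for suitable SNPs, checking primer
thermodynamics, avoiding nearby polymorphisms and low-coverage regions, and
predicting allele-resolved product/fragment sizes. `armscaps` automates the
whole path from alignments (BAM/SAM) + reference (FASTA) to an annotated
marker report.

## The statistics at the core

For a position covered by $n$ reads of which $k$ carry the cultivar-B
allele, the **SNP-index** is $k/n$. With true variant dosage $d$ of ploidy
$m$, $k \sim \mathrm{Binomial}(n, d/m)$. Genotype filters use the exact
central confidence interval of $k/n$ on the $1/n$ grid:
$\mathrm{lo} = q/n$ with $q = \min\{k : F(k) \ge \alpha/2\}$ and
$\mathrm{hi} = r/n$ with $r = \min\{k : F(k) \ge 1 - \alpha/2\}$, where $F$
is the binomial CDF and $\alpha = 1 - \text{confidence}$.

```r
library(armscaps)
snp_index_interval(6, 1, 2)     # diploid heterozygote at depth 6
snp_index_interval(100, 1, 4)   # simplex dosage in an autotetraploid
min_depth_excluding_homozygous(2, 1)
min_discernible_depth(4)
```

```
SNP-index 95% interval: depth 6, dosage 1/2 -> [0.1667, 0.8333]
SNP-index 95% interval: depth 100, dosage 1/4 -> [0.1700, 0.3400]
min usable diploid depth: 6
tetraploid dosage discernibility depth: 58
```

At depth 5 or below, a diploid heterozygote's 95% interval spans [0, 1] —
indistinguishable from a homozygote — so depth 6 is the default coverage
floor. In an autotetraploid, the simplex/duplex/triplex dosage intervals
become pairwise disjoint (with exact quantiles and closed-interval
disjointness) from depth 58 upward.

## Worked example

Everything is runnable offline: the package ships a synthetic-study
generator that writes a seeded random reference and pre-aligned reads with
known SNP truth.

```r
library(armscaps)
spec <- demo_fixture_spec(seed = 1)     # 100 kb, 40 SNPs, depth 30
ref  <- generate_reference(spec)
fx   <- generate_alignments(spec, ref, dir = "demo_fx")
res  <- marker_pipeline(ref, fx$sam_A, fx$sam_B)
```

Output of the run above:

```
selected sites: 36
specific primers: 101
tri-ARMS markers: 19
tetra-ARMS markers: 18
CAPS markers: 6

CAPS example: SNP chrSim:24636 G>A, AluI product 538 bp
  fragments (ref allele cut): ref 25,49,155,309 | alt 25,49,464
tri-ARMS example: SNPs 40900/41029, spacing 129, bands 597 vs 468 bp
```

Reading the numbers: 36 of the 40 true SNPs survive selection (the rest
lose reads to simulated sequencing error under the strict
cultivar-A-must-be-clean rule); up to four allele-specific primers are
attempted per site. The tri-ARMS marker distinguishes the cultivars by a
597 vs 468 bp band — the difference equals the 129 bp SNP spacing exactly,
because the two allele products share the common primer and the pair is
re-selected at one shared primer length. The CAPS marker's AluI digest
cuts the reference allele (309 + 155 = 464: one fragment of the variant
pattern splits in the reference pattern; fragment sums equal the product
size on both alleles).

Every emitted marker is validated against an in-silico PCR/digestion
oracle on the two haplotype sequences: each allele product must amplify at
exactly its predicted size on its own haplotype and not at all on the
other.

### Command-line use

The same pipeline is exposed as five staged subcommands with TSV handoffs
(`exec/armscaps`, installed with the package):

```sh
armscaps target_SNP_selection --ref ref.fa --bam-a A.bam --bam-b B.bam \
    --region chr1:1-100000 --out sites.tsv
armscaps ARMS_preparation --snps sites.tsv --ref ref.fa \
    --bam-a A.bam --bam-b B.bam --out primers.tsv
armscaps tri_ARMS   --primers primers.tsv --ref ref.fa --bam-a A.bam \
    --bam-b B.bam --out-html tri.html   --out-tsv tri.tsv
armscaps tetra_ARMS --primers primers.tsv --ref ref.fa --bam-a A.bam \
    --bam-b B.bam --out-html tetra.html --out-tsv tetra.tsv
armscaps CAPS --snps sites.tsv --ref ref.fa --bam-a A.bam --bam-b B.bam \
    --out-html caps.html --out-tsv caps.tsv
```

`target_SNP_selection` supports `--hetero-select PLOIDY:DOSAGE` (dosage
filtering via the binomial intervals) and `--progeny-bam` (keep only sites
heterozygous in a progeny bulk). The HTML reports list each marker's
amplicon, primers, product sizes and target SNP, with polymorphic and
out-of-coverage positions highlighted by CSS class.

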
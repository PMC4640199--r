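---
title: "Mapping ENU-induced mutations from pooled sequencing: models and methods"
author: "enumapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ENU-induced mutations from pooled sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enumapper)
```

## The genetic model

A mutagenized G0 male transmits one ENU-treated gamete to each G1 son,
so a G1 founder is heterozygous for a private set of induced variants —
on the order of 3000 genome-wide at roughly one SNV per Mb. The G1 is
crossed to wild-type females; his G2 daughters are backcrossed to him;
recessive phenotypes appear among the G3.

Three consequences drive everything in this package
(`cross_model()` and friends compute them by exact enumeration of
transmission outcomes; all defaults are dyadic probabilities, exact in
floating point):

* a G2 dam carries any given G1 variant with probability 1/2, and a G3
  offspring of a carrier dam is homozygous with probability 1/4, so an
  unlinked locus is homozygous in a single G3 mouse with probability
  1/8 (`p_homozygous_unlinked()`), and in an entire pool of N affected
  mice with probability 0.125^N (`p_spurious_region()`) — about 2 ×
  10⁻⁴ for N = 4;
* a fully penetrant monogenic recessive affects 12.5 % of the G3 in
  expectation (`expected_affected_fraction()`);
* the expected pooled allele fraction at an unlinked variant is 1/2
  conditioned on a carrier dam — the "random" background against which
  elevated regions are judged — and 3/8 marginally over dam status
  (`expected_pool_naf()`). Both values are exposed; the conventional
  50 % figure corresponds to the carrier-dam conditioning, and the
  marginal 0.375 is what an unconditional average over all induced
  variants approaches before ascertainment.

Every closed form is cross-checked in the test suite against
Monte-Carlo transmission draws (`mc_*()`) and against the full
multi-locus simulator — two independent routes to the same numbers.

## Filtering to presumptive induced variants

Calls from a pooled sample are filtered to the high-confidence set used
as mapping markers. A variant is removed if it matches a known-variant
database or in-house control set (by chrom + pos + ref + alt — a novel
alternate allele at a known SNP position is still novel), lies in a
repeat-masked interval, has site quality below Q30 or depth below 5
(strict inequalities: the boundary values pass), is multiallelic, or
sits on a sex chromosome (the breeding scheme cannot maintain X- or
Y-linked recessives). Each removal is attributed to the first failing
rule in that fixed order, making the report deterministic and the
counts conservative: input = passing + Σ removals.

The parser is deliberately lossless — multiallelic records are flagged
at read time and removed by the filter, not the reader — so the filter
is testable in isolation. `virtual_exome()` restricts a whole-genome
set to exon-resident and splice-site categories, emulating what exome
capture would query; with ~5 % of variants exon-resident it leaves few
markers, which is exactly the sparse-window regime the `min_snps` guard
below addresses.

## Window statistics and region calling

Windows of `size` bp (default 20 Mb) advance by `step` bp (default
1 Mb) along each autosome; the final window is truncated at the
chromosome end so every bp is covered. Per window, over the variants
whose position falls inside: the count, the number with NAF ≥ 0.9
(classed homozygous), the homozygote percentage, and the mean NAF.
Pooled reads give no per-individual genotypes, so homozygosity must be
classed from NAF; 0.9 keeps a site with one dissenting read at 10×
while rejecting the 7/8-dosage signature of a contaminated pool
(7/8 = 0.875 < 0.9). The threshold is configurable.

A window qualifies for region calling when it holds at least `min_snps`
(default 5) variants and its metric strictly exceeds the threshold;
qualifying windows that overlap or abut merge into one region (no gap
bridging), ranked by peak metric with ties in genome order. The
`min_snps` guard exists for the exome regime, where windows with one or
two markers would otherwise qualify on noise.

### Choice of the region thresholds

The working homozygosity threshold (hom_pct > 50) and the NAF threshold
(avg_naf > 0.7) sit far above the unlinked expectations (≈ 2 % of
markers spuriously classed homozygous; average NAF ≈ 0.4–0.5), and the
NAF value follows the convention of flagging windows above 70 %.

A single homozygosity threshold cannot serve both as a sensitive
region caller and as the trigger for the NAF fallback. In a power study
with the bundled simulator at default settings (50 replicates per
condition), the causal variant's region was recovered by the
homozygosity criterion in 50/50, 49/50, 48/50, 44/50 and 43/50
replicates at thresholds 50, 60, 70, 80 and 90: short recombinant
intervals dilute 20 Mb windows with flanking heterozygous markers, so
high thresholds miss them. Conversely, pools spiked with one
heterozygous mouse still produce scattered majority-homozygous windows
(linked markers at dosage 7/8 are classed homozygous ~40 % of the time
at 15× pooled depth), so at low thresholds "zero regions called" almost
never happens and a fallback gated on it would not fire.

The pipeline therefore separates the two roles: regions are called at
the working threshold (50), and the `auto` criterion falls back to NAF
unless some region is *definitive* — its peak window exceeding
`definitive_hom` (default 80) percent homozygous. With this rule the
same power study gives clean-pool recovery in 50/50 replicates (the
causal candidate in the top NAF rank in 50/50), and spiked pools fall
back to NAF with the causal region recovered in 43/50.

### Candidate ranking under ties

Candidates inside regions are the variants with damaging annotation —
non-synonymous, stop-gain, stop-loss (read as non-synonymous coding
changes), or splice-site within 10 bp of an exon — passing the zygosity
rule (classed homozygous under the homozygosity strategy; NAF ≥ 0.7
under the NAF strategy). They are ranked by descending NAF with a dense
rank: in a clean pool every fully linked variant reads NAF exactly 1,
so a positional tie-break would be arbitrary; instead all tied
candidates share the top rank and individual genotyping of further mice
(`concordance_table()`) separates them, mirroring how candidate genes
are actually confirmed or excluded.

## The simulator: what it emulates and what it does not

`simulate_cross()` realizes the breeding scheme forward: all induced
variants on a single mutagenized G1 haplotype (one treated gamete), a
Haldane no-interference recombination model at a uniform 0.5 cM/Mb,
`n_g2_dams` G2 daughters, G3 offspring drawn until the pool holds
`pool_size` affected mice (homozygous causal and penetrant), then
un-barcoded pooled sequencing: per site, depth ~ Poisson(coverage),
alternate reads ~ Binomial(depth, dosage/2N), each read flipped with
probability `seq_error`, and sites with no alternate read not emitted —
a pooled caller would not report them, and this ascertainment is why
the observed marginal NAF of emitted unlinked sites exceeds 3/8.

Defaults are the study conditions: 19 equal autosomes of 130 Mb
(≈ 2.47 Gb, mouse-autosome scale at desk-scale runtime), 1.2 variants
per Mb (≈ 3000 genome-wide), pools of 4, 15× mean pooled depth, full
penetrance, 5 % exon-resident variants split 55/25/5/15 between
missense, synonymous, nonsense and splice-site (an ENU-typical mix;
the causal draw is restricted to damaging categories since a
synonymous causal would be undiscoverable by construction).
`spike_outlier()` swaps one pooled mouse for a heterozygous (or
wild-type) animal and regenerates the reads, reproducing the failure
mode that motivates the NAF fallback.

What the simulator does not emulate — and hence what passing tests do
not show about real data: non-uniform mutation and recombination
landscapes, reference/alignment artifacts and systematic base errors,
repeat-region miscalls (flags exist but no error model feeds them),
indels and structural variants, codon-level annotation (categories are
assigned, not derived from sequence), and X-linked biology (excluded by
the breeding scheme). Real exome capture also has non-uniform
target coverage that the flat `exon_fraction` does not model.

## Numerical and degenerate-input conventions

VCF positions are 1-based; all internal interval arithmetic is 0-based
half-open; conversions happen only at I/O boundaries. Windows with no
variants carry undefined (`NA`) metrics, are ineligible for region
calling, and are dropped from plots rather than drawn as zero. NAF uses
the first alternate allele; multiallelic records keep a computable NAF
but are destined for the filter. Zero-depth variants have undefined NAF
and zygosity classification refuses them. Region ties are broken by
genome order. A dam set with no causal carrier (probability 2⁻ⁿ) cannot
yield affected offspring and is redrawn, with the count reported.
Single-locus screens (`simulate_screen()`, `mc_*()`) draw transmissions
marginally at one position — which is exactly what a meiosis reduces to
at a single locus — and are tested for agreement with the full
multi-locus machinery.

Problem sizes used by the validation suite: Monte-Carlo cross-checks at
10⁵–10⁶ draws against 3-standard-error bands; oracle-equivalence checks
on 20 random instances of up to 10⁴ variants; recovery rates on 50
seeded pipeline replicates per condition at the default genome scale.

## Known limitations

Region resolution is bounded by pool size (few meioses) and depth
(heterozygous markers defining breakpoints are incompletely
ascertained); with 4 mice, called regions span tens of Mb and may
include several damaging candidates in the shared top NAF rank —
follow-up genotyping is part of the method, not an afterthought. The
NAF fallback inherits the background rate of spuriously elevated
windows, so it can return several regions of which only one skews
toward homozygosity. No significance model beyond the threshold rules
is attempted, and no multi-pool case/control contrast is implemented.
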
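# enumapper

Positional cloning of ENU-induced mutations in inbred mice by pooled
homozygosity and allele-frequency mapping.

## The problem

Forward-genetic screens treat mice with the mutagen ENU
(N-ethyl-N-nitrosourea), which scatters ~3000 single-base variants per
founder genome (~1 per Mb), and recover recessive phenotypes through a
G1 × G2 backcross: a mutagenized founder's son (G1) is crossed to
wild-type females and then to his G2 daughters, so recessive mutations
surface in the G3. On an inbred background there are no natural
strain-specific markers to map with — but the induced variants
themselves segregate, and sequencing a small pool of affected G3 mice
reads out their allele frequencies in one step. Mapping and candidate
discovery collapse into a single experiment.

`enumapper` is for mouse geneticists running such screens: it consumes
a pooled-sample SNV VCF (plus optional masks and annotations), filters
it to high-confidence presumptive induced variants, localizes the
mutation, and extracts candidate causal changes. A forward simulator of
the breeding scheme with a known truth channel validates the whole
chain and supports power analysis.

## The method

For each variant the pooled **non-reference allele frequency** is
NAF = alt reads / total reads, and a variant is classed homozygous when
NAF ≥ 0.9. The autosomes are scanned with sliding windows (default
20 Mb advancing 1 Mb) and three statistics are computed per window:
homozygote count, homozygote percentage, and average NAF.

Two region-calling criteria implement the mapping logic:

* **Homozygosity**: in a pool of N affected mice, all 2N chromosomes
  carry the mutant haplotype across the recombinant interval, so linked
  windows approach 100 % homozygous markers, while an unlinked locus is
  homozygous in a single G3 mouse with probability
  ½ × ¼ = 0.125 (carrier dam × het×het backcross), and in the whole
  pool with probability 0.125^N ≈ 0.0002 at N = 4.
* **Average NAF**: if one pooled mouse is not homozygous (a phenocopy,
  mis-ascertainment, or a handling error) strict homozygosity fails —
  linked markers sit near (2N−1)/2N — but average NAF still rises far
  above the ~50 % expected at unlinked loci on carrier-dam
  chromosomes. Windows with average NAF > 70 % flag the region.

The `auto` pipeline runs homozygosity first and falls back to NAF when
no region shows *definitive* homozygosity. Inside a called region,
candidates are the variants with damaging annotation (non-synonymous,
stop-gain/loss, or splice-site within 10 bp of an exon) passing the
zygosity rule, ranked by NAF; a concordance table against individually
genotyped follow-up mice confirms or excludes each one.

## Worked example

Simulate a clean pooled screen and map it:

```r
library(enumapper)
sim <- simulate_cross(sim_config(seed = 11, seq_error = 0))
print(sim)
#> Simulated G1 x G2 backcross pool
#>   induced variants : 2931
#>   causal           : gene01168 stopgain at 9:40151452
#>   pool             : 4 affected of 25 screened G3 mice
#>   emitted sites    : 2813

res <- run_all(pipeline_config(sim = sim_config(seq_error = 0), seed = 11))
res$manifest$criterion_used
#> [1] "homozygosity"
res$regions
#>   chrom start     end    criterion n_windows n_snps peak_value
#> 1     9     0 5.9e+07 homozygosity        40     62        100
res$candidates[, c("gene", "naf", "chrom", "pos", "category", "rank")]
#>        gene naf chrom      pos             category rank
#> 1 gene01168   1     9 40151452             stopgain    1
#> 2 gene01148   1     9 41096186 exonic_nonsynonymous    1
#> 3 gene02082   1     9 41357040 exonic_nonsynonymous    1
#> 4 gene01938   1     9 45933966 exonic_nonsynonymous    1
```

The screen needed 25 G3 mice to collect 4 affected ones (the expected
affected fraction is 12.5 %). Mapping finds one region of definitive
homozygosity on chromosome 9 holding 62 filtered markers; it contains
the true causal stop-gain, which sits in the top NAF rank (every fully
linked variant reads NAF exactly 1 in a clean pool, so the top rank is
shared — follow-up genotyping separates them, see
`concordance_table()`). The closed-form genetics are available
directly:

```r
print(cross_model())
#> G1 x G2 backcross model
#>   P(G2 dam carries a variant)      : 0.5
#>   P(offspring hom | carrier dam)   : 0.25
#>   penetrance                       : 1
#>   pool size                        : 4
#>   P(unlinked locus hom, one mouse) : 0.125
#>   P(spurious hom region, pool)     : 0.0002441406
#>   expected affected G3 fraction    : 0.125
```

The same stages are available from the shell via `exec/enumapper`
(`simulate`, `filter`, `map`, `candidates`, `concordance`, `power`,
`run-all`).

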
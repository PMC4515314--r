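# imbalign

Allele-aware alignment and allelic imbalance detection for quantitative
short-read sequencing data (ChIP-seq, DNase-seq and similar), for analysts
who want to find allele-specific regulatory activity — differential
transcription-factor binding or chromatin accessibility between the two
alleles of a heterozygous site — without the reference mapping bias that
plagues naive pipelines, and usually without complete sample genotypes.

## The method in brief

At a heterozygous site covered by `n = n1 + n2` quality-passing reads
(`n1` carrying allele 1, `n2` allele 2), imbalance is assessed with the
exact two-sided binomial probability

P = Pr(|X − n/2| ≥ |n1 − n/2|),  X ~ Binomial(n, 0.5),

at an uncorrected threshold of 0.01 with at least 5 reads required per
allele.  An overdispersion-adjusted alternative models the per-site
reference-allele proportion as Beta(α, α) and tests

Z = (P̂ − 0.5) / sqrt((2α + N) / (4N(2α + 1))),

with α fitted across sites by the method of moments (α = ∞ when the data
show no overdispersion, recovering the binomial z-score).

Before any testing, mapping biases are removed: reads are aligned against
a custom reference carrying population major alleles and/or sample
alleles, with the alternate allele at every known heterozygous or common
variant site held in a sidecar table and treated as an equal match during
alignment.  Multi-mapping reads, blacklist regions and PCR duplicates are
filtered, and an allele-swap mappability filter keeps only reads that map
uniquely to the same locus no matter which allele they carry.  Novel
heterozygous sites are predicted from read evidence (≥ 5 reads per
allele), optionally feeding a second alignment round.  Runs with partial
(imputed, Rsq > 0.3) or no genotypes (common variants, MAF > 0.05) are
scored against the complete-genotype run by sensitivity TP/(TP+FN) and
precision TP/(TP+FP), stratified by site class.

## Worked example

Simulate the standard desk-scale study — a 20 kb genome with 300 variants
(200 heterozygous, 60 truly imbalanced at ratio 0.8) sequenced at depth
60 — then run the pipeline with complete and with partial genotypes and
compare:

```r
library(imbalign)

binomial_pvalue(27, 33)   # a 27-vs-6 split at a heterozygous site
#> [1] 0.0003240635

cfg <- sim_config(seed = 1)
sim <- simulate_truth(cfg)
reads <- simulate_reads(sim$genome, sim$complete, sim$truth, cfg)

complete_run <- run_pipeline(reads, sim$genome, genotypes = sim$complete)
complete_run
#> <pipeline_result>
#>   reads in / uniquely mapped / final: 19773 / 19302 / 11435
#>   sites tested: 198, imbalanced: 57

partial_run <- run_pipeline(reads, sim$genome, genotypes = sim$partial)
stratified_evaluation(
  partial_run$calls, complete_run$calls,
  known_sites = partial_run$calls[
    partial_run$calls$site_class == "known_het", c("contig", "pos")])
#> # A tibble: 4 × 6
#>   stratum               tp    fp    fn sensitivity precision
#>   <chr>              <int> <int> <int>       <dbl>     <dbl>
#> 1 all                   57     3     0           1     0.95
#> 2 known_variants        51     1     0           1     0.981
#> 3 predicted_variants     6     2     0           1     0.75
#> 4 truth_restricted      57     3     0           1     0.95
```

Reading the run above: of 19,773 simulated reads, 19,302 placed uniquely
and 11,435 survived the duplicate and mappability filters; 198 known
heterozygous sites had enough reads to test and 57 were called
imbalanced.  The partial-genotype run (about 80 % catalog coverage)
recovered every one of those 57 calls at the sites available to it
(`truth_restricted` sensitivity 1.0), with 3 extra calls — 2 of them at
read-predicted sites, the lower-confidence tier.

`autoplot()` methods on call and evaluation tables give the standard
allele-fraction-vs-depth and sensitivity/precision figures; `tidy()` and
`glance()` summarize the fitted overdispersion model.  A command-line
wrapper (`inst/scripts/imbalign`) exposes the stages as subcommands
(`simulate`, `build-ref`, `align`, `count`, `call`, `evaluate`,
`pipeline`), each writing a JSON manifest sufficient to re-run it.

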
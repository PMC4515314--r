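---
title: "Detecting allelic imbalance without reference mapping bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allelic imbalance without reference mapping bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbalign)
library(dplyr)
```

## The problem

Quantitative short-read experiments — ChIP-seq, DNase-seq, ATAC-seq —
measure regulatory activity as local read depth.  At a heterozygous SNV the
reads additionally carry one of the sample's two alleles, and a lopsided
allele split (*allelic imbalance*) is evidence that the two alleles differ
in regulatory activity, for example through differential transcription
factor binding.

Testing that split naively is biased.  Aligning against a single reference
genome penalizes every read carrying the non-reference allele with one
extra mismatch, so non-reference reads are lost disproportionately and
sites drift toward apparent reference-allele excess.  A second, subtler
bias is mappability: when one allele makes a read's sequence match a second
genomic location, reads carrying that allele are discarded as
multi-mapping while reads with the other allele survive.

`imbalign` removes both biases and then tests per-site allele counts, under
three levels of genotype information:

* **complete** — per-site sample genotypes (the best case, and the truth
  standard for evaluation);
* **partial** — imputed genotypes with an imputation quality `rsq`,
  filtered at `rsq > 0.3` before use;
* **none** — population common variants (`MAF > 0.05`) standing in for the
  unknown sample genotypes.

## Reference construction

The pipeline aligns against a *custom reference* paired with an
alternate-allele *sidecar*:

1. `build_population_reference()` replaces the base at every common variant
   with the population **major** allele (frequency strictly above 0.5; an
   exact 0.5/0.5 tie keeps the original base, a deterministic tie-break the
   method leaves open) and records the minor allele in the sidecar.
2. `customize_for_sample()` overwrites this with sample genotypes where
   available: homozygous sites carry the sample allele and leave the
   sidecar; heterozygous sites put one allele in the genome and the other
   in the sidecar.  Which of the two goes into the genome is not
   observable downstream (alignment treats them symmetrically), so we keep
   the pre-existing genome base whenever it is one of the two sample
   alleles — deterministic, and it keeps complete- and partial-genotype
   references identical at shared sites.
3. `build_complement_reference()` swaps genome and sidecar allele at every
   sidecar site.  It is an involution, and aligning the same reads
   allele-aware to the reference and its complement must give *identical*
   placements and calls — the package's built-in symmetry audit.

All constructions are SNV-only: contig lengths never change, so
coordinates stay comparable across references.  Positions are 1-based
inclusive in memory (the R/Bioconductor convention); 0-based formats such
as BED are converted at the file boundary.

## Alignment and filtering

`align_reads()` is an exhaustive ungapped scanner over every position and
both strands, written for desk-scale genomes (tens of kilobases): a read
base at a sidecar site counts as a match when it equals *either* allele,
indels are never allowed, and a read is kept only when exactly one
placement attains the minimal mismatch count (default budget: 1).
Correctness, not throughput, is the contract — the test suite holds it to
a brute-force oracle.  Production-scale data aligned with an external
allele-aware aligner enters through `ingest_sam()` instead; both paths
produce the same alignment table.

Post-alignment filters mirror standard practice: multi-mapping reads and
reads in blacklist regions are dropped (`filter_alignments()`), PCR
duplicates sharing a strand-aware 5' position are collapsed to the
highest-quality read with ties broken by read id (`remove_duplicates()`
— the tie-break is our own determinism choice, finer-grained than
duplicate-marking tools document), and `mappability_filter()` re-aligns
every read with its variant-site base swapped to the other allele, keeping
the read only if each swapped copy maps uniquely to the same locus.  Reads
spanning several variant sites are swapped one site at a time (linear
cost) rather than over all `2^k` combinations.

## The statistics

Per site, quality-passing observations (base quality strictly greater
than 30) are partitioned into the two catalogued alleles (`n1`, `n2`) and
anything else.  The default test is the exact two-sided binomial at
`p = 0.5` over `n = n1 + n2` (third-allele observations are excluded from
`n`, consistent with a two-allele model):

$$P = \Pr\left(|X - n/2| \ge |n_1 - n/2|\right), \quad X \sim
\mathrm{Binomial}(n, 0.5),$$

with an uncorrected threshold of 0.01 and at least 5 reads per allele
required for testing (`allow_complete = TRUE` relaxes the per-allele
minimum at known sites with at least `2 * min_reads_per_allele` total
reads, so one-allele-only "complete" imbalances — e.g. imprinted loci —
can be detected).  No multiple-testing correction is applied by default;
a BH option exists.

Read counts at a site are often overdispersed relative to binomial
sampling.  The beta-binomial alternative models the per-site
reference-allele proportion as `p ~ Beta(alpha, alpha)` and tests

$$Z = \frac{\hat{P} - 0.5}{\sqrt{\dfrac{2\alpha + N}{4N(2\alpha + 1)}}},$$

two-sided against the standard normal.  The estimation method for `alpha`
is not pinned down by the formula, so we chose a method-of-moments fit:
`alpha` solves "mean model variance of the proportion = empirical mean of
`(p̂ - 0.5)^2`", which is closed-form solvable by monotone root finding
and testably recovers the generating `alpha` from simulated counts
(within 20 % at 2,000 sites, depth 50).  When the empirical dispersion is
at or below the binomial floor `mean(1/(4N))`, `alpha = Inf` is returned
and the Z-statistic reduces exactly to the binomial z-score — the correct
no-overdispersion limit.  A maximum-likelihood fit would be a drop-in
alternative behind the same contract.  Whether the original analysis used
an exact beta-binomial tail or the normal tail of `Z` is not stated; we
default to the normal tail of the printed statistic.

## Heterozygous-site prediction and the second round

Sites absent from the catalog are predicted heterozygous when at least 5
quality-passing reads carry the genome base and at least 5 carry one
single other base.  Predicted sites are tested like any other but
reported in a lower-confidence tier; with `second_alignment = TRUE` they
are added to the sidecar (`update_reference_with_predicted()`) and
alignment through calling is repeated.  After the second round, sites
that entered via prediction keep the `predicted_het` class: the
evaluation strata are defined by first-alignment catalog membership, so
second-round gains at predicted sites remain visible as such.

Imputation-quality filtering happens *before* reference customization
(i.e. as a requirement of inclusion during alignment), matching how the
threshold is swept in the source analyses.

## Evaluation

`stratified_evaluation()` scores a reduced-information run against the
complete-genotype run: `sensitivity = TP/(TP+FN)` and
`precision = TP/(TP+FP)`, with sites matched by position only (the allele
pair is logged; an optional strict mode also requires the favored allele
to agree, since published counts do not state direction matching).
Strata restrict both call sets to a site set: all sites, catalog (known)
sites, predicted sites, and `truth_restricted` — truth intersected with
the sites actually available to the run, the "considering only these
sites" comparison that separates disagreement from simple absence.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the package's standard study conditions,
chosen to look like a small regulatory-site panel:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 20 kb | desk-scale genome (one contig) |
| `variant_density` | 15 / kb | 300 variants, 200 heterozygous |
| `imbalanced_fraction` | 0.3 | 60 truly imbalanced het sites |
| `imbalance_ratio` | 0.8 | true major-allele ratio at those sites |
| `depth` | 60 | mean reads per site (Poisson) |
| `read_length` | 50 bp | matches common ChIP-seq read lengths |
| `error_rate` | 0.005 / base | errored bases emitted at Phred 20 |
| `duplicate_rate` | 0.1 | exact PCR copies |
| `partial_coverage` | 0.8 | fraction of variants in the partial catalog |

Reads are placed uniformly over the windows covering each site; at every
heterozygous site a read overlaps, its allele is drawn independently at
that site's true ratio, so per-site allelic ratios are controlled exactly
even where sites sit within one read length of each other.  Errored bases
carry Phred 20, below the counting gate, so sequencing errors perturb
*mapping* (the mechanism behind reference bias) without contaminating
allele counts — which is exactly how the quality gate is meant to work.

The simulator does **not** model fragment-size or peak-shape structure,
indels, base-composition bias, or linkage between neighboring het sites
(alleles are drawn independently per site).  Passing tests therefore
demonstrate the pipeline's bookkeeping, bias removal and statistical
calibration under controlled conditions — not performance on real
chromatin data, where signal dispersion and total coverage dominate.

## Numerical and design choices

* Exact binomial tails are computed by direct summation of `dbinom` terms
  (exact to double precision for the depths involved); ties
  (`n1 == n2`) are never flagged imbalanced and have no favored allele.
* `alpha` root finding brackets `[1e-12, 1e12]` on a function that is
  monotone decreasing from 0.25 to the binomial floor; degenerate inputs
  (zero dispersion, fewer than two covered sites) return the sentinel or
  error.
* The micro-aligner treats `N` as matching nothing, on either side; a
  variant substitution over an `N` genome base proceeds (variant evidence
  overrides the unknown base).
* Multiallelic records and indels are skipped (and counted) at VCF load:
  the pipeline is biallelic-SNV throughout.
* All writers are deterministic (sorted by contig, then position), so
  repeated runs with the same seed produce byte-identical outputs.
* Problem sizes in the test suite and acceptance script (20 kb genome,
  depth 60, 10,000-site calibration panels) were chosen as the smallest
  sizes at which the statistical assertions have comfortable margins.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_truth(cfg)
reads <- simulate_reads(sim$genome, sim$complete, sim$truth, cfg)

complete_run <- run_pipeline(reads, sim$genome, genotypes = sim$complete)
partial_run <- run_pipeline(reads, sim$genome, genotypes = sim$partial)

stratified_evaluation(
  partial_run$calls, complete_run$calls,
  known_sites = partial_run$calls[
    partial_run$calls$site_class == "known_het", c("contig", "pos")])

autoplot(complete_run$calls)
```

## Known limitations

* The internal aligner is exhaustive and single-threaded: fine for tens of
  kilobases, not for mammalian genomes — use an external allele-aware
  aligner and `ingest_sam()` there.
* Single-end, ungapped, biallelic only; no phasing, no CNV adjustment
  (known CNV regions can be supplied as blacklist intervals).
* Complete imbalance detection (`allow_complete`) cannot distinguish true
  monoallelic activity from a genotyping error at the site; it is off by
  default for that reason.
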
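---
title: "Estimating germline mutation rates from trio sequencing: methods and design"
author: "trioDNM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating germline mutation rates from trio sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioDNM)
```

## The problem

A germline de novo mutation (DNM) is a variant present in an offspring's
constitutive genome but absent from both parents. When a
father--mother--offspring trio is whole-genome sequenced, DNMs appear as
*Mendelian violations*: offspring alleles that inheritance cannot explain.
The per-site per-generation mutation rate is then

$$\mu = \frac{n_{\text{candidates}} \times (1 - \mathrm{FDR})}
             {2 \times \mathrm{CG} \times (1 - \mathrm{FNR})}$$

with four ingredients that each demand care: the raw candidate count
$n$, the false discovery rate (FDR) among those candidates, the callable
genome (CG; the number of sites at which a DNM *would have been
detected* had it occurred), and the false-negative rate (FNR; the
fraction of true DNMs the filter stack itself throws away). The factor 2
counts the two haploid genomes an offspring inherits.

Raw Mendelian violations outnumber true DNMs by orders of magnitude:
sequencing errors, mis-mapping, allele dropout in a parent, and somatic
mutations all masquerade as violations. Published pedigree studies
therefore apply deep stacks of hard filters, and their choices differ
enough to drive near twofold variation in estimated rates from a single
dataset. This package implements the whole workflow — violation
detection, the full filter taxonomy with provenance, FDR/CG/FNR
corrections, rate assembly with confidence intervals — plus a synthetic
trio simulator so that every stage is testable without sequencing data,
and reporting utilities for cross-pipeline comparison.

## Detection and the filter taxonomy

`detectViolations()` supports three definitions of a violation,
selectable via `violation_mode`:

* `homref_config` (default): both parents `0/0`, offspring `0/1` — the
  restriction most studies use;
* `all_configs`: additionally `1/1 x 1/1 -> 0/1` and
  `0/0 x 1/1 -> 0/0 or 1/1`. At a divergence $d$ to the reference
  genome, roughly a fraction $d$ of true DNMs arise on a hom-alt
  background (`altBackgroundFraction()`), so dropping them biases rates
  down by that factor;
* `allele_absence`: any offspring allele carried by neither parent,
  which admits multi-allelic sites (a DNM on top of a parental
  heterozygous site).

Filters are grouped exactly as practitioners describe them:

* **site filters** on the variant-calling annotations QUAL, QD, MQ, FS,
  SOR and the MQ/ReadPos/BaseQ rank sums;
* **sample filters** per trio member: read depth (absolute bounds,
  bounds relative to the individual or trio mean, an n-sigma rule, or an
  exact two-sided Poisson test of the observed depth), genotype quality
  (GQ thresholds per role, or PL-gap thresholds per zygosity — PL gaps
  escape the GQ cap of 99), parental alternative-allele reads
  (`parent_ad_max`, optionally low-quality-read alt counts), and the
  offspring's allelic balance (window or exact binomial test against
  0.5);
* **auxiliary filters**: alt support on both strands, mutation-cluster
  removal (dense windows and close pairs), and exclusion against other
  samples, population SNP lists and region masks (low-complexity,
  repeats, A/T homopolymer runs via `homopolymerMask()`).

`filterPreset()` materializes the five published pipeline
configurations (`CV`, `RW`, `TT`, `LB`, `SB`) and the plain GATK
hard-filter set (`gatk_default`); `readFilterConfig()` lets a YAML file
start from a preset and override keys individually.

`runPipeline()` applies the stages in a fixed order — site filters,
violation detection, depth, genotype quality, parental reads, allelic
balance, strand, exclusion, and the cluster filter last on the
survivors — and records per-stage in/out counts. The order of the
per-candidate stages cannot change the final set (each filter judges a
candidate on its own data); it only changes which stage gets the blame
in the accounting. Every removed candidate carries machine-readable
reasons (`"father:parentAD=1>0"`), so any failure can be replayed.

### Numerical and convention choices

* **Strict inequalities.** Published threshold tables write pass
  conditions like `GQ > 60` but are routinely applied inclusively;
  values exactly at a bound *pass* here, uniformly across all filters,
  and the tests pin that boundary behaviour.
* **Two-sided exact tests** (binomial AB, Poisson depth) use the
  doubled-smaller-tail convention, `min(1, 2 min(lower, upper))`,
  computed with `lower.tail = FALSE` upper tails so that p-values far
  into a tail keep full precision. The doubled-tail form is symmetric in
  `(ref, alt)` and reproducible without reference to any particular
  statistics library's convention.
* **Poisson depth-test direction.** The literature describes removing
  sites whose depth yields a p-value *higher* than 2e-4, which read
  literally would remove nearly every site; this is treated as an
  erratum for "lower". The direction is configurable
  (`poisson_direction = "high"`) rather than silently corrected.
* **Allelic-balance denominator.** AB is `ad[alt] / (ad[ref] +
  ad[alt])`, not `ad[alt]/DP`; at candidate sites the two differ only
  through reads assigned to third alleles. When AD is absent the
  AB-dependent filters report "not evaluable" instead of inventing
  counts from DP.
* **Missing data are never defaulted.** A missing annotation or FORMAT
  field stays `NA`; each filter routes it per `missing_policy`
  (`"pass"`, recording the filter as not evaluable — consistent with
  hard-filtering behaviour on absent annotations — or `"fail"`).
* **Cluster removal is one pass**, computed on the surviving candidate
  set; removal is not iterated, which keeps it deterministic and
  order-free.

## Corrections: FDR, callable genome, FNR

FDR can be estimated from PCR/Sanger validation counts
(`fdrFromValidation`: failed over amplified) or from the deviation off
the expected 50% transmission to a third generation
(`fdrFromTransmission`: `max(0, 1 - 2 t/n)`, clamped because sampling
can push observed transmission above one half). Twin-discordance FDRs
from external analyses can be supplied as plain numbers.

CG is estimated either by counting (`callableGenomeCount`): sites with
both parents confidently hom-ref and all members passing the depth and
GQ filters, from BP-resolution-style per-site records; or
probabilistically (`callableGenomeProbabilistic`): inherited variants
give an empirical probability that a DNM would survive the filters
conditional on the trio's depths, and those probabilities are summed
over the genome's depth profile. The probabilistic estimate folds part
of the FNR into CG, which is why the two routes must not be combined
with a double FNR correction.

FNR estimators: `fnrSpikeIn` (inject heterozygotes at callable sites,
re-run the full pipeline, report the missed fraction — the spike
operates at the genotype-record level, with alt reads resampled
binomially and PL/GQ recomputed, since this package's inputs are
variant records rather than raw reads), `fnrAb` (the out-of-window
fraction of obligate heterozygotes — offspring of a `0/0 x 1/1` pair —
using the same strict window convention as the filter), and
`fnrSiteFilterProportion` (the fraction of a trusted variant set lost
to the site filters). Independent sources combine as
$1 - \prod_i (1 - \mathrm{FNR}_i)$ (`combineFnr`), the natural choice
for loss processes that act on disjoint information (site annotations
vs. read sampling); the published pipelines do not state their
combination rule.

The confidence interval on $\mu$ is the Wilson score interval on the
effective proportion $n(1-\mathrm{FDR}) / (2\,\mathrm{CG}\,(1 -
\mathrm{FNR}))$ — Wilson because it is the default of the binomial-CI
routine the field cites and is well behaved at the ~1e-8 proportions a
mutation rate is; Clopper--Pearson is available. Uncertainty in FDR and
FNR is deliberately not propagated, matching field practice; the
interval is a sampling interval on the candidate count, not a full
error budget.

### Design calculators

Two closed-form binomial calculators quantify study-design choices:
`alleleDropoutProbability(depth)` $= 0.5^{\text{depth}}$, the chance a
heterozygote shows no read for one allele (at 15x, 3.05e-5 — about 30
spurious hom calls per million het sites); and
`somaticLeakProbability(depth, cellFraction, readFractionThreshold)`
$= P(X \ge \lceil t \cdot d \rceil)$, $X \sim \mathrm{Bin}(d, f)$, the
chance a mosaic variant in a fraction $f$ of cells passes a
read-fraction threshold $t$ (for $f = 0.1$, $t = 0.3$: 0.0113 at 20x
falling to 0.0004 at 35x, the rationale for sequencing beyond ~35x).
The model equates the variant-read fraction with the cell fraction;
the alternative convention (half the cell fraction, for a heterozygous
somatic variant) does not reproduce those reference values and was
rejected. Note the integer ceiling makes the leak probability
saw-toothed in depth at single-read resolution; it declines when depth
grows in steps that scale the cutoff.

## The simulator

`simulateTrio()` generates per-site trio records with a complete truth
ledger. Its defaults are the study conditions the package targets: a
deep-coverage primate trio (father 40x, mother/offspring 70x),
heterozygosity 2e-3, same-species reference (divergence 2e-3),
sequencing error 1e-3 per base, gq_cap 99.

The generative model, per site:

* a site is polymorphic with probability `2 * heterozygosity`, with
  parental genotypes drawn Hardy--Weinberg at allele frequency 0.5 — so
  each parent is heterozygous with probability `heterozygosity`
  exactly, and `0/0 x 1/1` pairs (obligate-heterozygote offspring, the
  basis of `fnrAb`) arise at rate `heterozygosity/4`;
* with probability `divergence` both parents are fixed hom-alt;
* the offspring inherits by Mendelian sampling; germline DNMs are
  injected at `mu_true` per haploid transmission (expected count
  `2 L mu_true`) with parent-of-origin recorded; somatic events get
  configurable cell fractions, with read fraction equal to cell
  fraction (matching the leak calculator's convention);
* depths are Poisson per individual; alt reads are
  `Binomial(dp, f(1-e) + (1-f)e)` for allele fraction `f` and error
  `e`; PL comes from the standard per-read diploid likelihood
  (`P(alt read | dosage 0,1,2) = e, 1/2, 1-e`), normalized to min 0;
  GQ is the capped PL gap; **the genotype is the maximum-likelihood
  call**, so allele dropout, parental miscalls and somatic leakage
  produce false candidates through exactly the channel they do in real
  data;
* per-strand alt counts are `Binomial(ad_alt, 1/2)`; site annotations
  (QD, MQ, FS, SOR, rank sums) are drawn from stylized null
  distributions with a configurable outlier fraction.

**Sparse materialization.** Only polymorphic, divergent, DNM and
somatic sites plus a uniform sample of `n_background_sites` monomorphic
hom-ref sites become records; the genome length is carried in the
ledger. A 1e8-site genome therefore costs ~6e5 records instead of 1e8.
`backgroundRecords()` recovers the background sample and
`callableGenomeCount(..., genomeSites = genomeLength(truth))`
extrapolates the callable fraction to the genome; the bias from
enumerated variant sites is below the polymorphic fraction (~0.5%).

What the simulator does **not** emulate — and what passing tests
therefore cannot certify about real data: mapping and alignment
artifacts (the site annotations are stylized nulls whose absolute
scales carry no meaning; only their threshold-crossing fractions
matter), indels and structural variation, linkage and mutation
clustering (unless `n_cluster_pairs` is set to exercise the cluster
filter), base-context mutation-rate heterogeneity (CpG), and
batch/library effects. Conclusions about real-data FDR must come from
validation or transmission data, not from the simulator.

`injectSpikes()` converts chosen parental-hom-ref background sites into
offspring heterozygotes (AD resampled binomially, PL/GQ/GT recomputed)
for spike-in FNR estimation; `simulateThirdGeneration()` adds a
grandchild (mate drawn from the same population background) with
explicit, ledger-recorded DNM transmission for testing transmission
summaries and transmission-based FDR.

## Problem sizes in the test suite

The shipped tests run the complete stack at sizes chosen to make the
checked properties sharp rather than large: unit and property tests use
genomes of 3e4--2e5 sites; the binomial/Poisson tail oracles enumerate
all counts up to n = 30; the AB-FNR closed-form comparison uses 1e4
heterozygotes at depth 20; filter monotonicity is checked over 50
random configurations on a 1e5-site simulation.

The end-to-end recovery study runs 100 seeded replicates of a 2e7-site
trio at 40x, error 1e-3, mu_true 1e-8, through the LB preset, the
count-based CG and the combined (site + AB) FNR, asking that the 95%
Wilson interval cover the true rate in at least 90 replicates. The
2e7-site genome is the smallest at which this coverage property is
informative: at these rates coverage is governed by the expected
detected count `2 L mu (1 - FNR)`; below roughly 1.7e7 sites that
expectation drops far enough that a single detected DNM already places
the Wilson lower bound marginally above the true rate, and apparent
coverage reflects interval geometry at near-zero counts rather than the
pipeline. At 2e7 the interval at one detection still contains the
truth, and only the far Poisson tail (two or more detections, ~4.5%)
misses — the same regime as a full-scale genome.

## Known limitations

* Indels and multi-nucleotide variants are out of scope; records whose
  alleles differ in length are dropped and counted.
* Sex chromosomes are excluded by default (`exclude_chroms`); admitting
  them does not yet disable AB logic on hemizygous calls — callers
  should treat X/Y candidates with care.
* Phasing candidates to parental haplotypes, read-level validation and
  mosaicism classification beyond AB reporting are not implemented.
* `fdrFromTransmission` assumes false positives never transmit;
  inherited variants mis-called as DNMs violate that assumption and
  bias the estimate down.
* The per-year extrapolation of rates from parental ages is outside the
  package's scope; ages read from the pedigree sidecar are carried but
  unused.
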
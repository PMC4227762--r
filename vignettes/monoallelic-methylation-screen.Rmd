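---
title: "Detecting monoallelic DNA-methylation from enrichment sequencing with MAMscreen"
author: "MAMscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting monoallelic DNA-methylation from enrichment sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MAMscreen)
```

## The idea

Enrichment-based methylation assays (MethylCap-seq, MBD-seq, MeDIP-seq)
capture and sequence only the *methylated* fraction of a genome.  That makes
them cheap and genome-wide, but it also means the reads carry a peculiar
population signal at SNP positions:

* at a **biallelically methylated** locus both alleles of every methylated
  sample are captured, so the genotypes visible in the reads of a cohort
  follow Hardy–Weinberg proportions — with allele frequencies $p$ and
  $q = 1-p$, the genotypes $AA$, $Aa$, $aa$ appear at rates $p^2$, $2pq$,
  $q^2$;
* at a **stably monoallelically methylated** locus (imprinting-like), each
  heterozygous sample exposes only its methylated allele.  Heterozygotes are
  therefore miscalled homozygous, and the cohort shows a *heterozygote
  deficit* relative to Hardy–Weinberg expectations.

MAMscreen quantifies that deficit per SNP locus and turns it into a
Monte-Carlo P-value, with FDR control across the genome.  Two companion
statistics validate candidates in orthogonal data: a per-allele methylation
chi-square for whole-genome bisulfite sequencing, and an exact binomial test
for allele-specific expression (ASE) in RNA-seq.

## The coverage-conditioned null

Low coverage mimics monoallelic methylation: a sample with a single read can
never show two alleles.  The null therefore conditions on the observed
per-sample coverages of each locus.  A typed sample with coverage $c$ is
*called* heterozygous under the null with probability

$$\Pr(\text{het call}) \;=\; 2\hat p \hat q\,\bigl(1 - 0.5^{\,c-1}\bigr),$$

the product of being heterozygous and of both alleles appearing among $c$
reads split evenly between chromosomes.  `simulateNullHetCounts()` draws the
null heterozygote-count distribution from these per-sample probabilities
(grouped by coverage value, which is exactly equivalent to drawing a genotype
from $(\hat p^2, 2\hat p\hat q, \hat q^2)$ and then individual reads — a
homozygote can never be called heterozygous).  The test suite checks this
equivalence against a naive genotype-by-read simulator and against full
enumeration on tiny loci.

The one-sided Monte-Carlo P-value uses the add-one rule
$P = (1 + \#\{\text{null} \le \text{observed}\})/(1 + B)$, so $P$ is never
zero and the smallest attainable stage-2 value ($10^{-6}$ at the default
$B_2$) lies safely below the screen's operating threshold.

Allele frequencies are estimated from *genotype calls*,
$\hat p = (2 n_{RR} + n_{het})/(2 n_{typed})$, not from read counts — read
counts at heterozygotes are distorted by both reference-mapping bias and
partial capture, genotype calls much less so.

## Pipeline stages and their parameters

| stage | function | defaults | notes |
|---|---|---|---|
| SNP tracing | `traceSnps()` | — | catalogue membership, allele compatibility, ≥1 alt read somewhere |
| filtering | `filterLoci()` | MAF < 0.9; total coverage ≥ 350 (autosomes), ≥ 250 (chrX, females only) | loci failing these have essentially no power anyway |
| error correction | `correctSequencingErrors()` | ε = 0.0025, 2 rounds | see below |
| screen stage 1 | `twoStageScreen()` | B₁ = 1000, gate P ≤ 0.005 | cheap triage |
| screen stage 2 | `twoStageScreen()` | B₂ = 10⁶ | only gated-in loci |
| significance | `bhThreshold()` | Benjamini–Hochberg, q = 0.1 | over all tested loci |
| enrichment | `enrichmentTest()` | 1000 chromosome-matched draws | two-sided empirical P |
| bisulfite validation | `validateWgbs()` | B = 2000 fixed-margin permutations | per-sample and global |
| ASE validation | `aseSiteTests()`, `callGeneAse()` | depth ≥ 10, FDR 1%, ≥ 2 significant sites/gene | base quality filtering happens upstream |

The coverage thresholds correspond to roughly 1× per sample in a cohort of a
few hundred samples; the X-chromosome threshold is lower because only female
samples carry two X copies and contribute to the test (male samples are
excluded from X loci throughout).

### Sequencing-error correction

A sample showing both alleles is either a true heterozygote or a homozygote
with miscalled reads.  For a mixed profile with $n$ reads, three posteriors
are compared:

* het: prior $2\hat p\hat q$, likelihood $\mathrm{Binom}(n, 1/2)$ at the
  ref count;
* hom-ref: prior $\hat p^2$, likelihood $\mathrm{Binom}(n, \varepsilon)$ at
  the alt count;
* hom-alt: prior $\hat q^2$, likelihood $\mathrm{Binom}(n, \varepsilon)$ at
  the ref count.

$\varepsilon$ is interpreted as the per-read probability of being miscalled
as the *specific other* retained allele (a single scalar, not $\varepsilon/3$
per alternative base — the conservative reading).  If a homozygous
hypothesis wins *strictly*, the minority reads are deleted; ties and the
degenerate $\hat p \in \{0,1\}$ case keep the heterozygote, which disfavours
monoallelic calls.  Frequencies are re-estimated after each round; two
rounds are the default, and the filter is re-applied afterwards in
`runPipeline()` because corrected frequencies can cross the MAF cut-off
(the stricter choice; the alternative order is defensible too).
Correction never increases a count and never invents an allele.

## What the simulator emulates — and what it does not

`simulateMethylcap()` reproduces the statistical structure the screen
assumes, with ground truth attached:

* Hardy–Weinberg genotypes at a drawn allele frequency (default uniform on
  [0.1, 0.9], the regime surviving the MAF filter);
* *enrichment dropout* as a per-sample event: with probability `meth_prob`
  (default 0.8) a locus is methylated in a sample at all; unmethylated
  samples emit no reads.  Methylation status is a per-sample property —
  at a biallelic locus both allele copies of a methylated sample are
  methylated.  (Modelling dropout per allele copy instead would make
  heterozygotes at *biallelic* loci look homozygous at a coverage-independent
  rate, i.e. it would inject the very signal the screen tests for into its
  null condition.);
* monoallelic loci mark exactly **one** allele per heterozygote, chosen at
  random but stable — the imprinting-like pattern the method detects.
  Random-per-cell (X-inactivation-like) mosaicism is deliberately *not* the
  monoallelic mode: such loci expose both alleles across reads and should
  not be detected;
* read depth per methylated allele copy follows a Poisson law by default
  (mean 10), the zero-dispersion member of the negative-binomial family
  (`depth_dispersion` > 0 enables overdispersion).  With Poisson depths a
  biallelic heterozygote's reads split exactly $\mathrm{Binom}(c, 1/2)$
  given its coverage $c$ — identical to the screen's null — so calibration
  experiments measure the screen itself rather than a generator/null
  mismatch;
* each read flips to the other allele with probability ε (default 0.0025);
* X-chromosome loci yield no reads in male samples.

Not emulated: fragment-level capture chemistry and GC bias, mapping bias,
batch/platform structure, population substructure (non-panmixia), and
linkage between loci.  Passing tests on simulated data therefore show that
the statistics behave as designed under the model's assumptions; on real
cohorts, deviations from panmixia or strong mapping bias can still produce
false positives, which is why the bisulfite and ASE validation modules
exist.

## Numerical choices and degenerate inputs

* Per-locus RNG substreams are derived from `(seed, chrom, pos)`, so screen
  results are identical regardless of locus processing order and safe to
  parallelise.
* Untestable loci ($\hat p \in \{0, 1\}$, or no typed samples) are reported
  with `NA` P-values rather than dropped silently.
* A locus where every sample has coverage 1 returns $P = 1$ exactly: both
  the observed and the null heterozygote count are identically zero.
* The bisulfite 2×2 test excludes samples that are uncovered, effectively
  homozygous (calls on one allele only), or degenerate (a zero
  methylated/unmethylated column margin); exclusion reasons are reported.
  C/T and A/G SNPs are flagged as bisulfite-ambiguous — on one strand the
  conversion chemistry itself interconverts those bases — but still tested.
* Two-sided empirical enrichment P-values double the smaller tail (add-one
  corrected) and are capped at 1; sampling is without replacement within a
  draw.
* The two-sided binomial ASE P-value uses the minimum-likelihood convention
  (`stats::binom.test`), stated explicitly because two-sided binomial
  conventions differ.

## Calibration: what "uniform P-values" can and cannot mean here

Two deliberate design facts shape the null behaviour of the P-values:

1. **The screen's plug-in frequency.**  The null is simulated at
   $\hat p$ estimated from the *same* observed genotypes that form the test
   statistic.  This makes mid-range P-values mildly conservative (the null
   distribution is slightly wider than the statistic's distribution around
   its own estimate), an effect inherent to the published design.  The
   practical consequences are benign: the type-I error at nominal 0.05 is
   close to (slightly below) 0.05, and FDR control only becomes more
   conservative.  Re-running the screen with the generator's true $p$
   restores uniformity, which the decision to estimate $\hat p$ from
   genotypes trades for robustness to allelic mapping bias.
2. **Discreteness of the 2×2 conditional null.**  For per-sample bisulfite
   tables of realistic size the observed table is frequently the modal one
   under the fixed-margin null, so the Monte-Carlo P carries a sizeable atom
   at 1 and is conservative by construction.  "Calibrated" for this test
   means *valid* — $\Pr(P \le \alpha) \le \alpha$ at every level — which is
   what the test suite asserts; exact uniformity is not attainable for a
   discrete statistic.

## Problem sizes used in the checks

The packaged calibration and recovery experiments run at 300 samples × 500
loci (mean depth 10), with stage-2 Monte-Carlo at $10^5$ iterations and BH
q = 0.1; the oracle comparisons use loci of ≤ 4 samples with coverages ≤ 3,
where the genotype-by-read outcome space can be enumerated exactly.  These
sizes were chosen so every distributional property is measured on hundreds
of independent loci while a full run of the suite stays under a minute.

## Known limitations

* The heterozygote count is the test statistic; parental origin of the
  methylated allele is not inferred.
* The error model uses one scalar ε for all samples and platforms.
* The correction deletes putative error reads rather than reassigning them;
  with ε = 0 it reduces to the identity on all profiles.
* BH-FDR is applied over all tested loci, with the stage-1 P standing in
  for loci that did not pass the gate; a permutation-based FDR could be
  substituted where the BH independence assumptions are a concern.
* The ASE FDR is controlled per tissue; pooling across tissues is a
  configuration choice, not a default.
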
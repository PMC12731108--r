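---
title: "Rare-variant burden testing with variable deleteriousness thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden testing with variable deleteriousness thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenscan)
```

## The problem

Early-onset colorectal cancer has a substantial heritable component that is
only partly explained by established susceptibility genes. Individually,
rare coding variants (allele frequency at or below $10^{-4}$) are too
scarce to test one at a time; collapsing them per gene into a single burden
count restores power. `burdenscan` implements such a case–control
collapsing analysis for exome cohorts, together with the quality-control
harmonisation that makes a cross-cohort comparison valid, a synthetic
cohort generator that provides ground truth for every statistical claim,
and reporting data (QQ and lollipop structures).

The package consumes annotated tables — per-variant transcript
consequences, VEST4 deleteriousness rank scores for missense variants,
population allele frequencies, site and genotype quality metrics — and
performs no alignment, variant calling, or annotation of its own.

## The burden model

For one gene, let $k$ be the number of qualifying variant *observations*
in $n_1$ cases and $c$ the number in $n_2$ controls, with
$m = k + c$ and $N = n_1 + n_2$. An observation is one (individual,
variant) pair: an individual with two qualifying variants contributes two
observations, and a homozygous genotype contributes one (at the allele
frequencies involved, homozygotes are vanishingly rare, and burden is
reported per carried variant). Under the null each observation falls in a
case with probability $\pi = n_1/N$, giving the one-sided enrichment test

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(m, \pi).$$

Dependence between observations of the same carrier is deliberately
ignored at this stage; the permutation correction below restores validity.
Enrichment is summarised by the pooled-rate relative risk

$$\mathrm{RR} = \frac{k/n_1}{(k+c)/N},$$

whose pooled denominator stays finite when no control carries a qualifying
variant — with four case carriers among 212 cases and zero among 31,699
controls it evaluates to 150.5, reproducing the headline magnitude of this
design.

### Qualifying variants

Loss-of-function observations (stop gained, start/stop lost, frameshift,
canonical splice-site) qualify whenever the LoF class is analysed.
Missense observations qualify when their VEST4 rank score reaches a
threshold $t$. Because the informative score range differs markedly from
gene to gene, a fixed $t$ is left to replication mode only; discovery uses
a **variable-threshold scan**: candidate thresholds are the unique
observed scores among the gene's missense variants (the qualifying count
is a step function of $t$, so no other cutoffs can change the statistic),
and the scan returns the candidate minimising the binomial $p$.

One non-obvious candidate is always added: a sentinel $t = \infty$,
meaning "no missense qualifies". In combined LoF + missense analyses a
high-scoring control missense variant can make every score-valued
threshold worse than the pure LoF count; without the sentinel the scan's
defining guarantee — its optimum is at least as small as every fixed
threshold's $p$-value — fails, as our property tests demonstrated during
development. A reported threshold of `Inf` therefore reads "the optimal
analysis used LoF observations only".

Ties on the minimal $p$ resolve to the smallest (most inclusive)
threshold, making the scan deterministic.

### Permutation correction

Scanning thresholds is a selection procedure, so the scan minimum is not a
valid $p$-value. It is corrected by label shuffling: case/control status
is permuted over the analysis samples, the *entire* scan is re-run per
permutation, and with $r$ permutations achieving a strictly smaller
binomial $p$ than observed, the corrected value is

$$p_{\mathrm{perm}} = \frac{r + 1}{n_{\mathrm{perm}} + 1}.$$

Choices worth recording:

* **Strict inequality.** A permutation "wins" only with a strictly smaller
  $p$; ties are counted and reported separately. With zero exceedances at
  $10^7$ iterations the corrected value is $1.0 \times 10^{-7}$ — the
  $+1$-corrected floor, matching the reported floor behaviour of this
  design (a plain fraction of wins would report 0, which a finite
  permutation run cannot support).
* **Rescanning is the default.** A cheaper variant (`rescan = FALSE`)
  freezes the observed optimal threshold, but only per-permutation
  rescanning absorbs the selection multiplicity: our type-I study
  (below) is run in rescanning mode. Because both modes share the same
  random label streams, the frozen-mode estimate is never larger.
* **Implementation.** Only carrier samples can affect the statistic, so
  labels are assigned to the (few) carriers by sequential sampling without
  replacement from the label pool — exactly the multivariate
  hypergeometric law of a full-cohort shuffle — vectorised over
  permutation chunks. Ten million iterations on a four-carrier gene take
  seconds. When every carrier holds exactly one variant and the statistic
  is monotone in the case-carrier count, the exceedance probability has
  the closed form $P(X > k_{\mathrm{obs}})$ with $X$ hypergeometric;
  `exact_permutation_oracle()` provides this tail and the test suite
  checks the Monte-Carlo engine against it.
* **Early exit.** Estimation stops once $r$ reaches a ceiling (default
  1000, relative standard error about 3%); headline genes are run at full
  depth with `early_exit_r = Inf`.
* **Seeding.** A master seed is split into named substreams by a
  polynomial hash (`seed` $\times$ stream name), one stream per gene, so
  results are independent of gene processing order and identical seeds
  give byte-identical result files.

Genes with no qualifying observations report $p = 1$ without permuting: a
constant statistic carries no evidence, and the floor value that the
strict-inequality count would produce there is meaningless.

### Six analyses per gene, and multiple testing

Risk mechanisms differ: tumor suppressors act through LoF, oncogenes
through gain-of-function missense. Each gene is therefore analysed as
missense-only, LoF-only, and combined, each in the full case set (cancer
plus significant-polyp cases) and the confirmed-cancer subset — six
analyses, with the per-gene best labelled. Dropping polyp cases *shrinks*
the case cohort (they are never recycled as controls). Genome-wide
significance uses Bonferroni ($\alpha/G$; with the default
$G = 18{,}500$ genes, $2.7\times10^{-6}$) and a borderline level of
$1/G \approx 5.4\times10^{-5}$, the level at which one false positive is
expected among all tested genes.

### Gene-set tests

For a curated risk-gene panel, observations are pooled across the set
under one of three rules: LoF (skipping LoF in oncogene-role genes, since
loss of an oncogene is presumed protective), missense with VEST4 $\ge
0.5$ (a fixed, literature-motivated cutoff appropriate when pooling
heterogeneous genes), or their union. The package ships empty templates
for the ASCO and OMIM colorectal panels plus a clearly-labelled synthetic
placeholder list; the true panels are user-supplied inputs.

## Quality control and cross-cohort calibration

Using one cohort as cases and another, differently sequenced cohort as
controls invites batch artefacts that masquerade as association. The
defence has three layers:

1. **Fixed filters.** Genotype level: GQ $\ge 10$, alternate-allele depth
   $\ge 2$, depth $\ge 7$, allele balance $\ge 0.1$ (discovery profile;
   the replication profile uses the strict forms GQ $> 25$, alt depth
   $> 3$, depth $> 10$, AB $> 0.2$, mirroring how each threshold set is
   stated). Site level: VQSLOD $> 2$ or QUAL $> 38$, matched to each
   cohort's calling pipeline. Frequency: at most $10^{-4}$ in both gnomAD
   and UKBB, a missing frequency meaning "absent from the database" and
   treated as zero (the count of such variants is logged).
2. **Neutral-class calibration.** Rare synonymous and in-frame indel
   variants are functionally neutral, so their per-individual rates must
   agree across cohorts. `calibrate_thresholds()` evaluates a user-supplied
   grid of threshold sets and picks the one minimising
   $|\log(\text{synonymous ratio})|$ subject to both neutral classes
   being statistically indistinguishable ($p > 0.05$, two-sided: a
   deviation in either direction signals a batch effect, so the smaller
   binomial tail is doubled and capped at 1). Ties break toward stricter
   site quality, then stricter allele balance. The grid itself is a
   config input — the published filter values are *outcomes* of such a
   search, not inputs — and the full grid trace is retained.
3. **QQ diagnostics.** Per-gene binomial $p$-values on a neutral class
   should be uniform; `qq_data()` supplies observed versus expected
   $-\log_{10} p$ with pointwise 95% bands from the
   $\mathrm{Beta}(i,\,n-i+1)$ law of uniform order statistics, the
   standard construction for $p$-value QQ plots.

## Replication mode

Replication in a population biobank uses ICD-10 codes to define proximal
(C18.0, C18.2–C18.4) and distal (C18.5–C18.7, C19, C20) colorectal cancer
cases; individuals with no C18–C20 code are controls. Two deliberate
edge rules: a sample matching both case groups is flagged ambiguous and
joins neither (avoiding double counting), and colorectal codes absent from
both printed lists — appendix (C18.1), overlapping/unspecified (C18.8,
C18.9) — make a sample ineligible as a control without making it a case.
Each significant gene is then evaluated twice: at the discovery-fixed
VEST4 threshold (validating the original signal) and with a fresh
variable-threshold scan (the maximal signal in the new data).

## The synthetic cohort generator

`simulate_cohort()` draws datasets with the structure the analysis
assumes, and its defaults *are* the discovery study conditions: 212 cases
(174 cancer, 38 polyp) versus 31,699 controls, per-individual rare
synonymous counts Poisson with mean 26.5 (between the two published cohort
means of 26.43 and 26.65), an in-frame indel rate of 1.0 per individual (a
realistic per-exome rate for this frequency stratum; the source reports
only the cross-cohort ratio), VQSLOD-scale site quality for the case
cohort and QUAL-scale for the control cohort — centred so that roughly 9%
of raw calls sit below the default site filters in either cohort — and an
optional additive batch shift on one cohort's site quality or allele
balance. Background (null) deleterious variation uses a per-gene,
per-individual carrier probability of 0.01 — the order of magnitude of
cumulative rare deleterious carrier frequency for a typical gene in this
frequency stratum — with 15% LoF and uniform VEST4 rank scores (rank
scores are uniform by construction). Planted risk genes take explicit
case/control carrier rates, a LoF fraction, and a Beta law for missense
scores; every simulated variant is private to one individual, which is the
correct regime at these frequencies. Planted genotype-QC failures each
violate exactly one criterion, so per-criterion filter counters can be
checked exactly against the returned truth table.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium and recurrent
(shared) variants, relatedness and ancestry structure, realistic
site-frequency spectra, gene length variation in neutral-variant
placement, and correlated (multi-criterion) QC failures. Tests built on it
verify the *statistical machinery* under the model's assumptions, not
robustness to their violation.

## Validation studies and problem sizes

The package's test suite computes, at sizes chosen to keep a full run in
the low minutes:

* **Oracle equivalence** — 20 randomised single-variant-per-carrier
  instances, $10^6$ permutations each, agreeing with the exact
  hypergeometric tail within three Monte-Carlo standard errors.
* **Scan optimality** — 200 random genes checked exhaustively against
  every fixed threshold.
* **Type-I error** — 50 genes × 100 null replicates at 200 cases / 2,000
  controls, 999 permutations per gene test in rescanning mode: the
  gene-level rejection rate at $\alpha = 0.05$ must lie inside its exact
  binomial 95% confidence interval. Neutral-class variants are switched
  off here (they never enter the burden statistic), which keeps the study
  honest while fast.
* **Calibration recovery** — a planted $-1.0$ site-quality shift on the
  control cohort visibly distorts the synonymous ratio; a grid search
  over QUAL thresholds restores it to within 5% of unity.
* **Parameter recovery** — the planted headline-magnitude effect (case
  carrier rate 0.019, control rate $2\times10^{-4}$, at 212 / 31,699):
  carrier-level relative risk averaged over 500 replicates is centred on
  the generator's true pooled-rate value within Monte-Carlo error, and
  the scan-plus-permutation pipeline (at $10^5$ permutations) detects
  the gene at the borderline threshold in the clear majority of 200
  replicates, with the estimated power reported by the test.
* **Determinism** — identical seeds yield byte-identical result files.

## Known limitations

The binomial model conditions on nothing: covariates (ancestry principal
components, sex, sequencing batch) cannot be adjusted for — samples must
be harmonised *before* testing, which is exactly what the calibration
layer is for. The framework is not a kernel/dispersion test (SKAT-style
methods are out of scope by design). Relative risk from pooled rates is a
crude effect measure at very low counts; it is reported alongside, never
instead of, the permutation $p$. Finally, the variable-threshold scan
assumes the deleteriousness score is informative; for genes where it is
not, the scan spends its multiplicity for nothing and the permutation
correction simply returns an honest, larger $p$.
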
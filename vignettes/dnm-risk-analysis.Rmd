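---
title: "De novo mutation burden and risk-gene discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo mutation burden and risk-gene discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmrisk)
```

# The problem

Whole-exome sequencing of affected parent–child trios detects de novo
mutations (DNMs): variants present in the child and absent from both
parents. Because each child carries only on the order of one coding DNM,
cohort-level inference rests on a *mutational null model*: for gene $g$ and
functional class $c$ (synonymous, missense, loss-of-function), the number
of DNMs observed in $N$ trios is

$$X_{gc} \sim \mathrm{Poisson}(2 N \mu_{gc}),$$

where $\mu_{gc}$ is the per-gene, per-class mutation probability per
chromosome per generation (the factor 2 counts the two transmitted
haplotypes). Everything in this package — burden testing, the risk-gene
count estimate, and the gene-level Bayes factors — is built on that null.

`dnmrisk` packages the full analysis chain for such a study: QC filtering
of candidate trio calls, class-wise burden against the null, a permutation
maximum-likelihood estimate of the number of risk genes, a de novo-only
TADA gene test, and replication statistics, together with a synthetic
cohort generator so every stage is exercisable and testable without any
cohort data.

# Filtering candidate calls

Filtering runs in five stages, in order, with each removed record
attributed to the first failing rule so that the audit conserves counts
(input = retained + sum of per-rule rejections):

1. **Trio identity** — parent–child identity-by-descent (IBD) sharing must
   lie in $[0.45, 0.55]$, inclusive at both bounds ("between 45 and 55%"
   is read as a closed interval). Values outside flag swaps, contamination
   or wrong pedigrees; the whole trio is dropped.
2. **Sample outliers** — per-sample variant-calling metrics are projected
   onto their first two principal components; samples with a robust
   z-score (median/MAD) above `k_sd` (default 4) on either component are
   dropped. The threshold is configurable because no universal criterion
   exists for this screen; MAD degenerating to zero falls back to the
   standard deviation.
3. **Region masks** — BED intervals (low-complexity regions, segmental
   duplications) are 0-based half-open; VCF positions are 1-based, so a
   call at `pos` is masked iff `pos − 1 ∈ [start, end)`. Overlap testing
   uses GenomicRanges.
4. **Variant QC** — VQSR pass required; genotype quality ≥ 40;
   Fisher-strand score ≤ 30; child depth ≥ 10. The boundary semantics are
   implemented literally ("less than 40" excludes 39.9 and keeps 40).
5. **DNM candidate criteria** — child heterozygous with both parents
   homozygous reference; child:parent depth ratio ≥ 0.3 *against each
   parent separately* (the conservative reading when only "parent depth"
   is specified — an under-covered parent cannot certify absence);
   alternate allele depth ≥ 10; coding consequence; allele balance
   strictly > 0.2. Parental reads supporting the alternate allele are
   tolerated up to 5% of the parent's depth (the de novo definition
   implies clean parents, but index hopping and low-level contamination
   make a strict zero impractical). A parent depth of zero leaves the
   ratio undefined and fails closed.

Multi-allelic VCF records are decomposed to bi-allelic records on reading
(alternate depths beyond the first ALT are collapsed onto it). Missing
fields always fail closed with reason `missing_field`.

# Class-wise burden

For class $c$, the expected count is $E_c = 2N\sum_g \mu_{gc}$, with the
protein-altering class defined as missense + LOF. Enrichment is
observed/expected; the p-value is the one-sided upper Poisson tail
$P(X \ge \mathrm{obs})$ — the scientific question is excess, and the
direction is switchable for depletion tests. The 95% interval is the exact
(Garwood) Poisson interval on the observed count divided by the
expectation; we place the interval on the enrichment scale because that is
the quantity reported. The discrete Poisson test is conservative: across
2000 null draws the fraction of $p < 0.05$ stays at or below ~5–7%, which
the test suite verifies.

# Estimating the number of risk genes

Let $K$ be the total number of damaging DNMs in cases (damaging = LOF or
probably-damaging missense — the stricter of the two phrasings in
circulation, used consistently), $R_1$ the number of genes hit exactly
twice, $R_2$ the number hit three or more times. With $M_1$ and $M_2$ the
damaging DNM rates per case proband and per unaffected sibling, the
fraction of damaging DNMs carrying risk is estimated as

$$E = \frac{M_1 - M_2}{M_1},$$

clamped to $[0, 1]$ with a warning when siblings out-rate cases. For each
candidate risk-gene count $G$, a permutation draws $G$ risk genes uniformly
from the gene universe, samples $C \sim \mathrm{Binomial}(K, E)$
contributing mutations, places them multinomially over the risk genes, and
places the remaining $K - C$ over all genes — both placements weighted by
the per-gene damaging rate $\mu_{mis} + \mu_{lof}$, which absorbs gene
length and base composition. The likelihood at $G$ is the fraction of
permutations whose $(R_1^*, R_2^*)$ matches the observed $(R_1, R_2)$;
the MLE is the maximising $G$ (ties to the smallest, logged).

Design choices made where the procedure is genuinely open:

* **Match rule.** "Consistent with the observed counts" is undefined;
  the default is exact equality, and a $\pm 1$ tolerance band is available
  (`match_rule = "tolerance"`) and flagged in the output.
* **Placement weighting.** Rate weighting is applied to both the
  contributing and non-contributing draws for internal consistency, rather
  than only to the non-contributing one.
* **Gene universe.** Risk genes are drawn from the full rate table by
  default; restricting to the observed-DNM gene set is supported by
  passing a subsetted table, since which of the two a study intends is
  ambiguous.
* **Grid and permutations.** The reference-scale grid is 1–2500 with
  25,000 permutations per point; desk-scale runs use a coarser grid and
  fewer permutations (the package's tests use 5–150 step 5 with 2000).
  Internally the scan batches all permutations at one grid point and
  counts recurrences with a single sort; the test suite checks this
  batched path against exhaustive enumeration of the placement
  distribution on tiny universes.

The estimator is *noisy at desk scale*: $E$ enters through a binomial and
is itself estimated from finite sibling cohorts, so individual-cohort
estimates of $G$ scatter widely (a factor of ~2–3 around the truth is
routine), while the median over ~20 replicate cohorts is stable. The test
suite measures exactly that: over 20 synthetic cohorts with 50 risk genes
in a 2000-gene universe ($\gamma = 18$, chosen so $E \approx 0.3$ by the
closed form $M_1/M_2 = 1 + s(\gamma - 1)$ with $s \approx 2.5\%$ the risk
genes' share of damaging rate), the median estimate lands within 30% of
the truth. In that recovery experiment the sibling cohort is set to the
same size as the case cohort so that sampling noise in $E$ does not
confound the property being measured — the estimator's ability to recover
$G$ — which is a calibration-experiment choice, not a claim about real
sibling cohort sizes.

# De novo-only TADA

For one gene and class, the evidence for risk is the Bayes factor of

$$H_1: x \sim \mathrm{Poisson}(2N\mu\,\gamma),\ \gamma \sim
\Gamma(\bar\gamma\beta, \beta) \quad\text{vs}\quad
H_0: x \sim \mathrm{Poisson}(2N\mu),$$

whose marginal under $H_1$ is negative binomial, giving in closed form

$$\mathrm{BF}(x) = \frac{\Gamma(x + \bar\gamma\beta)}
{x!\,\Gamma(\bar\gamma\beta)}
\left(\frac{\beta}{\beta + \nu}\right)^{\bar\gamma\beta}
\left(\frac{\nu}{\beta + \nu}\right)^{x} \Big/
\frac{e^{-\nu}\nu^x}{x!}, \qquad \nu = 2N\mu,$$

computed entirely in log space (log-gamma throughout) so large
$\bar\gamma\beta$ cannot overflow. The total per-gene evidence is
$\mathrm{BF}_{mis}\cdot\mathrm{BF}_{lof}$. The hyperparameters come from
cohort-level counts: $\pi = G_{\mathrm{mle}}/\text{total genes}$ (at
reference scale, 419/17,726 ≈ 0.0236), class fold enrichments
$\lambda = \text{caseX} / (\text{sibX} \cdot \text{caseSyn}/\text{sibSyn})$
— synonymous counts act as the neutral yardstick for cohort size — and
prior mean relative risk $\bar\gamma = 1 + (\lambda - 1)/\pi$.

* **$\beta$** is never pinned down by the cohort counts; the default is 1
  (prior coefficient of variation $1/\sqrt{\bar\gamma\beta}$), exposed in
  the interface. Sensitivity is mild for ranking: $\beta$ rescales how
  sharply the prior concentrates at $\bar\gamma$, and the BF ordering of
  genes with equal rates is unchanged.
* **Missense counting** defaults to all missense DNMs (the conventional
  TADA input); a `missense = "damaging"` switch restricts to
  probably-damaging missense.
* **p-values** are empirical: for each of 1000 null samplings (default),
  per-gene counts are drawn from each gene's own Poisson null and the BF
  recomputed; $p = (1 + \#\{\mathrm{BF}^{null} \ge \mathrm{BF}\}) /
  (1 + B)$, add-one so p is never zero. The observed log-BF is recomputed
  from the counts inside the comparison so ties at identical counts are
  exact.
* **q-values** use TADA's native Bayesian FDR — posterior
  $P(H_0 \mid x) = (1-\pi)/((1-\pi) + \pi\,\mathrm{BF})$, ranked by
  decreasing BF, q = running mean — with a Benjamini–Hochberg adjustment
  of the sampling p-values appended as an alternative column. Candidate
  genes are those at $q \le 0.1$.

An aside on a behaviour worth knowing: for genes with a *large* baseline
$\nu$ the Bayes factor at $x = 0$ can exceed 1 and the BF need not be
monotone in $x$, because the gamma prior also has mass at $\gamma < 1$
(protective); at the small $\nu$ typical of single genes the BF is
strictly increasing in the count and a zero-count gene has $p = 1$.

# Replication statistics

Candidate genes are tested in external DNM cohorts with the Poisson upper
tail on expected damaging count $2 n \,(\mu_{mis}+\mu_{lof})$, and in
sporadic case/control carrier data with the two-sided Fisher exact test
(minimum-likelihood convention, conditional-MLE odds ratio, via
`stats::fisher.test`). As a worked example, 9 carriers among 1155 cases
against 2 among 2813 controls gives $p = 4.42\times10^{-4}$. External
cohorts of mixed sex are not sex-adjusted, and the same rate table is used
as for the discovery cohort.

# The synthetic generator

`simulate_rates` draws per-gene total coding rates from a log-normal
($\sigma = 1$ on the log scale — published per-gene rate tables are
right-skewed with roughly this spread, and a heavy tail is what exercises
the rate-weighted machinery), rescales so $\sum_g 2(\mu_{syn} + \mu_{mis}
+ \mu_{lof})$ equals the target coding DNMs per trio (default calibration
1.02), and splits each gene's rate at fixed class proportions
syn:mis:lof = 0.25:0.62:0.13, matching the observed class mix of coding
DNMs in trio studies of this kind. `simulate_dnm_cohort` draws
$X_{gc} \sim \mathrm{Poisson}(2N\mu_{gc} m_{gc})$ with $m_{gc} = \gamma$
for damaging classes of risk genes and 1 otherwise; 30% of missense DNMs
are flagged probably damaging at generation time (a Bernoulli flag, not a
modelled score — the pipeline only ever consumes the binary
classification). `simulate_raw_calls` wraps every true DNM in a fully
passing trio call record and adds exactly the requested number of records
failing each named QC rule, which is what makes the per-rule audit and the
round-trip recovery property exactly testable. All randomness flows from
explicit seeds; no operation reads the global RNG state.

What the generator does *not* emulate: sequence context (no trinucleotide
mutation model), read-level artefacts (strand bias and depth are injected
summary statistics, not remeasured from reads), relatedness structure
beyond the trio, annotation error, or correlated QC failures. Passing
tests therefore certify the statistical machinery on data satisfying the
stated model, not the upstream calling pipeline on real sequencing data.

# Problem sizes and numerical choices

The test-suite and acceptance-script experiments run at desk scale, chosen
as the smallest sizes at which each property is statistically decisive:
burden neutrality over 300–500 null cohorts of 100–300 genes; MLE recovery
over 20 cohorts of 2000 genes and 473 + 473 trios at 2000 permutations per
grid point; TADA calibration on 400 genes with 1000 null samplings; spike
detection over 100 simulations of 500 genes and 500 trios. Monte-Carlo
tolerances are stated as 3 standard errors of the quantity measured.
Degenerate inputs are handled explicitly: empty cohorts produce zero-count
tables rather than errors; $M_1 = 0$ makes $E$ undefined and is an error;
an all-zero likelihood curve is an error advising a looser match rule;
zero-variance QC metrics flag no outliers.

# Known limitations

* **Gene-level spike detection is power-limited under rate
  heterogeneity.** With 5 risk genes at $\gamma = 20$ in a 500-gene
  universe and 500 trios, a spiked gene's expected damaging count is
  $\lambda = 2N\mu_{dam}\gamma$, and under the log-normal rate spread
  roughly 70% of uniformly chosen risk genes have $\lambda < 8$. Measured
  over 100 simulations, spiked genes rank in the BF top 10 in ~93% of
  cases when $\lambda > 8$ but only ~43–81% below that, for an overall
  per-gene rate of ~0.73–0.76. High per-gene detection of *all* spiked
  genes is achievable only with near-homogeneous rates; this is a property
  of the experiment, not a defect of the statistic, and the corresponding
  end-to-end check documents the measured rate rather than hiding it.
* The risk-gene MLE at desk scale has large per-cohort variance (above);
  report the likelihood curve, not just the argmax.
* Hyperparameter $\beta$ and the null-sampling tail convention are
  package defaults, documented rather than asserted as the only choice.
* The filtering stage consumes annotation (consequence class, damaging
  prediction, VQSR flag) as input; it does not recompute any of them.

# Session

```{r}
sessionInfo()
```
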
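---
title: "Union testing: model, conventions, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Union testing: model, conventions, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unionscan)
```

## The test

`unionscan` tests case-control association with a one-degree-of-freedom
composite statistic over a set of markers. Each marker's genotype is coded
binary with respect to its minor allele B — dominant (AA, AB, BB) → (0, 1, 1)
or recessive → (0, 0, 1) — and the union indicator over the set is 1 when any
member codes 1. The 2×2 table of the indicator against case-control status is
tested with Fisher's exact test. Because the construction simply counts
individuals with pre-specified multi-locus genotypes, it requires no estimate
of allele frequencies, linkage disequilibrium, or haplotype phase, and it
does not assume Hardy-Weinberg equilibrium. The union probability identity

$$P(X \cup Y) = P(X) + P(Y) - P(X)P(Y) - r\sqrt{P(X)(1-P(X))P(Y)(1-P(Y))}$$

shows what the statistic responds to: differences between cases and controls
in the marginal coded-genotype frequencies *or* in the indicator correlation
$r$. A union of one marker reduces to single-marker analysis
($P(X \cup X) = P(X)$), and a dominant union over rare variants is the
collapsing (burden) indicator.

## Missing-data semantics

The two-marker coding rules extend to arbitrary union sizes as a Kleene
three-valued OR: 1 if any member is 1; 0 if all members are 0 with none
missing; missing otherwise. This is the unique monotone extension of the
two-marker rules — a known 1 makes the union certain regardless of gaps,
while an all-zero-so-far union with a gap is genuinely undetermined.
Individuals with a missing indicator are excluded from that union's table
only (and counted in `n_excluded`); they still contribute to every union
where their indicator is determined. Half-missing PED genotypes ("A 0") are
treated as fully missing, matching PLINK's convention.

## Windows and the testing burden

Unions are formed over consecutive, non-overlapping windows of $k$ markers in
map order. Windows never span a chromosome boundary: the grouping is
motivated by linkage disequilibrium among neighbouring markers, which does
not cross chromosomes. The last window per chromosome may be short. The
burden for a scan is $|\text{codings}| \times \sum_k \lceil M/k \rceil$ and
the per-test threshold is $\alpha$ divided by that count, always recomputed
from the marker count actually scanned (after any call-rate filter). Unions
whose table degenerates (e.g. all cases excluded for missingness) are
reported untestable but still count in the denominator, which by construction
depends only on $M$.

```{r}
count_tests(319813, 1:5, 2)
signif(0.05 / count_tests(319813, 1:5, 2), 3)
```

## Allele orientation

The minor allele is determined from the pooled sample (cases and controls
together): pooling is the common convention and avoids the ambiguity of
group-specific orientation when case and control minor alleles disagree. An
exact frequency tie is broken toward the lexicographically smaller allele
character so that runs are deterministic. Markers observed monomorphic get an
all-zero dosage column (the standard MAP format carries no allele labels from
which to recover the unobserved allele); they are flagged and never fire an
indicator. PED phenotype codes follow the PLINK case-control dialect
(1 = control, 2 = case); anything else excludes the individual with a logged
count.

## Fisher test conventions

The two-sided p-value conditions on both table margins and sums the
hypergeometric probabilities of all tables whose point probability does not
exceed the observed table's — the standard convention, identical to
`stats::fisher.test`. Point probabilities are compared with a relative
tolerance of $10^{-7}$ so that exactly tied tables are kept despite floating
point; the test suite verifies agreement with an independent
binomial-coefficient enumeration to below $10^{-12}$ over every 2×2 table
with total count up to 60.

The reported odds ratio is the sample cross-product ratio, not the
conditional maximum-likelihood estimate that `fisher.test` reports: the
cross-product ratio is the estimator practitioners tabulate alongside burden
tests, and it pairs naturally with the Woolf log-odds interval
$\exp(\log\widehat{OR} \pm z_{0.975}\sqrt{\sum 1/n_{ij}})$. When any cell is
zero the Haldane–Anscombe correction adds 0.5 to all four cells before both
the estimate and the interval. A table whose indicator is constant across all
individuals carries no information about association: p = 1 and the odds
ratio is reported as `NA`.

## Simulation design

The generator reproduces a standard validity/power study design: binary
coded genotypes (not three-state raw genotypes) drawn Bernoulli at given
frequencies, case-control status from a logistic model, exactly 938 cases
and 863 controls per replicate, 1,000 replicates per configuration. Choices
the design leaves open were fixed once:

* **Logistic intercept** $\beta_0 = 0$ (baseline risk 0.5). The intercept is
  not identified by a case-control quota design — it only changes how many
  draws are discarded while filling the quotas — and the union test
  conditions on the table margins, so $\beta_0$ affects sampling efficiency,
  not the tested contrast. $\beta_0 = 0$ maximizes efficiency.
* **Quota filling.** Individuals are drawn in vectorized batches; cases and
  controls are retained until both quotas are exact, overflow discarded. A
  cap (2,000 draws per requested individual) turns a pathological
  specification into an informative error instead of a hang.
* **Correlated pairs.** A pair $(i, j, r)$ is realized by redrawing $X_j$
  conditionally on $X_i$ so that
  $P(X_i = X_j = 1) = f_i f_j + r\sqrt{f_i(1-f_i)f_j(1-f_j)}$ with marginals
  preserved; every pair is checked against the Fréchet bounds before any
  sampling. Pairs are applied in order, so structures over more than two
  markers compose as a chain of pairwise conditionals — an approximation for
  higher-order dependence, adequate for the pairwise designs studied here.
* **Phase.** When correlation is quoted as $r^2$, the positive root
  (coupling phase) is used; `r_from_r2(r2, sign = -1)` selects repulsion.
* **Differential correlation** (different $r$ in cases and controls with
  equal marginal frequencies) is realized by drawing each group directly
  from its own joint distribution rather than through the logistic model,
  which cannot produce it. Non-unit odds ratios are then honoured by
  retention sampling within each stream (keep a case draw with probability
  $\text{logit}^{-1}(\eta)$, a control draw with the complement).
* **Frequency grid.** The panel suites evaluate coded-genotype frequencies
  {0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5} — a realistic sweep from
  rare-variant to common-variant territory on a roughly logarithmic scale.

Monte-Carlo uncertainty at 1,000 replicates is
$\sqrt{p(1-p)/1000} \approx 0.007$ at $p = 0.05$; automated checks of
stochastic claims use 3–4 such standard errors as tolerance, which is the
resolution the replicate count supports.

### What the generator does and does not emulate

It emulates the ingredients the test responds to: marginal coded-genotype
frequency differences, pairwise correlation (including group-specific
correlation), epistasis on the logit scale, and exact case/control group
sizes. It does **not** emulate three-state genotypes with Hardy-Weinberg
structure, linkage-disequilibrium decay along a map, genotype missingness,
genotyping error, or population stratification. Passing simulation tests
therefore demonstrate the statistical properties of the test under its own
model — validity of the per-comparison error rate, the documented power
orderings — not robustness to real-data artefacts, which is what the
PED/MAP path, call-rate filter, and missing-data semantics address
separately.

## Problem sizes in the automated suite

The test suite runs each stochastic claim at 1,000 replicates with the full
938/863 group sizes (the study's own scale), keeps fixture genotype tables at
tens of individuals × ≤ 12 markers, and verifies the exact-test
implementation exhaustively up to table total 60. The whole suite completes
in well under a minute on one CPU.

## Known limitations

* Unions are homogeneous in coding: mixing dominant and recessive members
  within one union is not supported (per-union coding is an extension point).
* Windows are fixed and non-overlapping; sliding windows would raise the
  testing burden and are out of scope.
* The Woolf interval is approximate for very sparse tables; the
  conditional-MLE interval of `fisher.test` is an alternative when a single
  table deserves close inspection.
* Which marker inside a significant union drives the signal is not
  identified — the union is a region-level screen, and unions that mix
  risk-increasing and risk-decreasing effects lose power by cancellation.
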
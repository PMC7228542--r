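---
title: "Tree-bootstrap uncertainty for respondent-driven sampling: models, choices, limits"
author: "rdstreeboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-bootstrap uncertainty for respondent-driven sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdstreeboot)
```

## The sampling process being modelled

Respondent-driven sampling (RDS) reaches hidden populations — injection
drug users, sex workers, men who have sex with men — through their own
social networks: a handful of *seed* participants receive coupons and
recruit contacts, who recruit further contacts, wave by wave.  The result
is not a probability sample but a forest of recruitment trees, and the
statistical difficulty is that observations along a branch are dependent.

`rdstreeboot` works under the standard idealization of this process:

* The hidden population is an undirected simple graph $G$ on $N$ members;
  member $i$ carries a binary trait $x(i) \in \{0,1\}$ and has degree
  $\deg(i)$.
* Recruitment is a Markov walk indexed by the recruitment forest
  $\mathbb{T}$: the seed's identity is drawn from the stationary
  distribution $\pi_i = \deg(i)/\sum_j \deg(j)$, and each recruit is a
  uniformly chosen contact of its recruiter, independently per coupon and
  *with replacement* (the same contact can be recruited twice).
* Every tree is a **complete $m$-ary tree of height $h$** — each of the
  $k$ seeds yields $\ell = (m^{h+1}-1)/(m-1)$ observations, $n = k\ell$
  in total.

The complete-tree assumption is what makes exact analysis possible; real
recruitment is ragged, and the package deliberately does not model coupon
depletion, non-response, or differential recruitment.

## Estimators

For the observed traits $X_s$, $s \in \mathbb{T}$, the package computes

* the sample mean $\bar X_n = n^{-1}\sum_s X_s$, unbiased for the
  degree-weighted mean $\mu = \sum_i x(i)\pi_i$;
* the inverse-probability-weighted (Horvitz–Thompson) estimator
  $\hat\mu_{\mathrm{IPW}} = \frac{\sum_j \deg(j)}{nN}\sum_s
  X_s/\deg(W_s)$, unbiased for the true prevalence
  $\mu_0 = N^{-1}\sum_i x(i)$ but requiring the total-degree normalizer,
  which the package treats as a required input and never estimates;
* the Volz–Heckathorn (Hájek) ratio
  $\hat\mu_{\mathrm{VH}} = \sum_s (X_s/\deg_s) \big/ \sum_s (1/\deg_s)$,
  the self-normalizing approximation to IPW.

A notational caution for readers of the RDS literature: the VH weight is
always the *sampled member's* network size (the degree of $W_s$), the only
coherent reading even where formulas are sometimes typeset with the trait
symbol inside the degree operator.  The $x^\pi$ transform
$x/(\pi N)$ links the two worlds: the plain mean of transformed values
*is* the IPW estimator, which is why results proved for the sample mean
transfer to IPW unchanged.

## The tree bootstrap

To estimate the sampling distribution of any of these estimators, the
tree bootstrap resamples the *structure* of the observed forest: draw $k$
bootstrap seeds uniformly with replacement from the observed seeds, then
recursively draw each resampled node's $m$ recruits uniformly with
replacement from the recruits its origin had, down to the leaves.  Because
trees are complete, every replicate has exactly $n$ nodes.  Resampling
never mixes recruits across branches, so homophily — the correlation of
traits along recruitment chains — is preserved in the replicates.

On complete trees the bootstrap distribution can be **enumerated
exactly**.  Counting resampled trees with child order distinguished,
one seed tree of height $h$ has $a = f(h)$ possible resampled trees,
$f(0)=1$, $f(d) = \{m f(d-1)\}^m$, and all $K = ak$ (seed, outcome) pairs
are equally likely.  The bootstrap mean is then the average of $k$ i.i.d.
draws from this uniform law, so its exact distribution is a $k$-fold
convolution (`exact_distribution()`).  Two exact facts fall out and are
tested:

* the exact bootstrap mean equals $\bar X_n$ for every data set
  (exact unbiasedness);
* at $h = 0$ the whole construction collapses to the classical i.i.d.
  bootstrap of the $k$ seed values.

Enumeration is guarded at $K \le 10^7$ outcomes; beyond that
(`f` grows doubly exponentially in $h$) the error message points to
Monte Carlo (`bootstrap_replicates()`), which is vectorized across
replicates and cheap even at $B = 10^5$.

## The synthetic population: a stochastic block model

`make_sbm()` draws the hidden population from a stochastic block model
with $2K$ equal blocks of `block_size` vertices, within-block edge
probability $p$ and between-block probability $r$; traits are assigned by
block (by default the first $K$ blocks carry the trait), the
block-symmetric outcome regime for which tree central limit theory is
available.  The relevant summary is
$\tilde p = p/\{p + r(K-1)\}$, and the tree CLT regime is the *strictly*
below-threshold band $1/(2K) < \tilde p < 1/(2K) + 1/(2\sqrt 2)$
(`below_threshold()`; boundary values count as not below).  Note the
$\tilde p$ formula degenerates to $1$ when $K = 1$ regardless of $p, r$,
making the band unsatisfiable for a two-block model; the package computes
the formula exactly as defined and leaves this anomaly documented rather
than guessing an alternative.

SBM draws can be disconnected; walks require connectivity, so generation
and use are decoupled: the simulator *rejects* disconnected graphs with a
clear error, and `make_sbm(require_connected = TRUE)` resamples up to a
retry cap instead of silently taking a giant component.

What the generator does *not* emulate: degree heterogeneity beyond
Bernoulli mixing, overlapping communities, directed or weighted ties,
and any real-world recruitment raggedness.  Tests passing under this
generator show the machinery is correct under the stated model; they do
not certify behaviour on real RDS data, where the complete-tree and
with-replacement assumptions are approximations.

## The consistency experiment

Bootstrap consistency here means: conditional on a sample, the law of
$\sqrt n(\bar X_n^* - \bar X_n)$ approaches the sampling law of
$\sqrt n(\bar X_n - \mu)$ in Kolmogorov (sup-CDF) distance as $n$ grows,
provided (i) a tree CLT holds (below-threshold population), (ii) the
scaled exact bootstrap variance $n\hat\sigma^2_{\infty,n}$ converges to
the CLT variance $\rho^2$, and (iii) $\ell(n) = o(\sqrt n)$ with
$\ell \to \infty$.

`run_consistency_experiment()` makes this empirical:

* **Schedule.** Condition (iii) fixes only a rate, not a path; the
  default schedule takes $h_t = t$ and $k_t = \ell_t^2$, so
  $\ell/\sqrt n = \ell^{-1/2}$ falls geometrically.  With $m = 2$ the
  first two stages are $(n, k, h) = (27, 9, 1)$ and $(343, 49, 2)$.
  Schedules violating the monotone surrogate ($\ell$ increasing,
  $\ell/\sqrt n$ decreasing) are rejected.
* **Centring.** The bootstrap law is centred at each sample's own
  $\bar X_n$ and the sampling law at $\mu$ computed from the realized
  graph; both are $\sqrt n$-scaled so stages are comparable.
* **Aggregation.** The Kolmogorov distance is computed per sampled
  forest against a Monte Carlo estimate of the sampling law and
  summarized by the *median* across forests — robust to the occasional
  pathological small-$n$ sample.  Coverage is the fraction of nominal
  95% intervals containing the estimand.  Almost-sure convergence is
  untestable; the package's acceptance surface is a fixed-seed
  monotone-trend comparison across stages.
* **Problem sizes.** The shipped experiments use a 200-vertex SBM
  ($K=2$, blocks of 50, $p=0.3$, $r=0.2$, hence $\tilde p = 0.6$, inside
  the band), 2000 Monte Carlo samples for the sampling law, $R = 200$
  bootstrapped forests per stage and $B = 2000$ replicates each — sizes
  at which the two-stage trend is resolved in a few minutes on one CPU.
  All are configurable.

## Numerical conventions

* Percentile intervals use the linear-interpolation empirical quantile
  (`quantile(..., type = 7)`), fixed so intervals reproduce bit-for-bit
  given a seed.  Normal intervals are `estimate ± z·sqrt(variance)`.
  Both are provided because the theory's CI statement does not single
  out a construction; percentile is the default.
* The bootstrap variance divides by $B$, not $B-1$, so its
  $B \to \infty$ limit is exactly the enumerated variance.
* Distribution supports are aggregated with a 12-significant-digit key
  while keeping exact representative values, so integer trait sums never
  lose precision to string round-trips.
* Seeds are drawn i.i.d. from $\pi$ (the natural reading of independent
  seed-rooted trees); each recruiter's $m$ coupon draws are mutually
  independent.  A `seed_members` override supports convenience-seed
  realism studies but is excluded from consistency experiments.
* All stochastic entry points take an `rng_seed` (`NULL` = current RNG
  state); the experiment harness seeds once and consumes a single
  stream, so a run reproduces from its config alone.

## Known limitations

**Finite-height conservatism of the bootstrap variance.**  Resampling a
node's children *with replacement* duplicates whole subtrees, which adds
variance beyond what i.i.d. resampling of $\ell$ values would give.  One
can compute exactly: for i.i.d. node values with variance $\sigma^2$, the
exact scaled bootstrap variance $n\hat\sigma^2_{\infty,n}$ is
$\tfrac{4}{3}\sigma^2$ at $(m=2, h=1)$ and $\tfrac{12}{7}\sigma^2$ at
$(m=2, h=2)$, not $\sigma^2$ — and the inflation grows with $h$.  The
package's experiments show the same pattern on the SBM: at stage 2 the
median $n\hat\sigma^2$ exceeds $\hat\rho^2$ by roughly half, and 95%
percentile intervals cover at about 0.98–0.99 rather than 0.95.
Condition (ii) above is an *assumption* of the consistency theory, and at
the heights these experiments reach it is visibly not yet operative: the
intervals err on the conservative side, in line with what simulation
studies of the tree bootstrap have reported.  Users should read the
package's coverage numbers as "at least nominal", not "exactly nominal",
at realistic tree heights.

**Other limits.**  Exact enumeration is infeasible past $h \approx 3$
for $m \ge 2$ (the $10^7$ guard); the Volz–Heckathorn ratio admits no
per-node linear relabelling, so only Monte Carlo (not enumeration) is
available for it; above-threshold populations are generated and warned
about but carry no guarantee; and the experiment harness measures trends
at two or three stages, which exhibits — but cannot prove — convergence.
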
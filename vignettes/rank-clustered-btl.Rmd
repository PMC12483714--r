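---
title: "Rank-clustered Bradley-Terry-Luce models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-clustered Bradley-Terry-Luce models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcbtl)
```

## The problem

Given ordinal comparisons from $I$ judges over $J$ objects — complete or
partial rankings, incomplete (subset) rankings, pairwise or groupwise
comparisons — classical rank aggregation produces an overall ranking in
which every object receives a distinct rank. That is often unwarranted:
objects can be genuinely equal in quality, or the data can be too thin to
separate them. `rcbtl` instead estimates an overall ranking *with
rank-clusters*: groups of objects whose population-level ranks are tied,
together with full posterior uncertainty about which objects are tied, how
many tiers there are, and where every object sits.

## Model

Each object $j$ carries a positive worth $\lambda_j$. A judge who considers
the set $S$ and reports the ordered prefix $\pi_1, \dots, \pi_R$ contributes

$$\prod_{s=1}^{R} \frac{\lambda_{\pi_s}}{\sum_{j \in S \setminus \{\pi_1, \dots, \pi_{s-1}\}} \lambda_j},$$

the sequential-choice (Plackett-Luce) form of the Bradley-Terry-Luce
family; a pairwise comparison is the special case $|S| = 2$, giving
$P(i \succ j) = \lambda_i / (\lambda_i + \lambda_j)$. The likelihood is
invariant to rescaling $\lambda$, and the final stage of a ranking that
orders its whole considered set contributes probability one and is never
iterated.

Rank-clusters enter through the prior. A partition $g$ of the $J$ objects
into $K$ nonempty clusters is drawn first, with mass depending only on $K$:
every partition with the same number of clusters is equally likely, with
$K$-mass proportional to a Poisson($\nu$) pmf truncated to $\{1..J\}$. Each
cluster then receives one worth drawn i.i.d. from a Gamma($a$, $b$) slab,
and every object inherits its cluster's worth. Two objects are tied in rank
exactly when they share a cluster, so the pair $(\lambda_j, \lambda_{j'})$
has a spike of prior mass on the diagonal $\lambda_j = \lambda_{j'}$ and a
smooth slab off it — a spike-and-slab prior for *parameter fusion* that
needs neither the parameter order nor the number of clusters in advance.

Two structural facts are load-bearing and are verified in the test suite:

* **Marginal-Gamma property.** Whatever the partition prior, the marginal
  prior of each expanded worth is exactly Gamma($a$, $b$).
* **Stirling-weighted $K$.** Because mass is assigned per partition, the
  induced prior on $K$ is proportional to $f(K)\,S(J, K)$ with $S(J,K)$ a
  Stirling number of the second kind, not to $f(K)$ alone.
  `partition_log_prior()` documents this deliberately.

## Posterior computation

`run_chain()` alternates two updates.

**Reversible-jump partition moves.** A *birth* selects a cluster with at
least two members uniformly at random, assigns its members to two children
independently with equal probability conditional on both being nonempty,
and splits the cluster worth through the mean-preserving bijection
$(\lambda, u) \mapsto (2\lambda u,\, 2\lambda(1-u))$ with
$u \sim \mathrm{Uniform}(0,1)$ and Jacobian $4\lambda$. A *death* merges
one of the $K-1$ pairs of clusters adjacent in worth order, solving the
same equations in reverse. Births whose children would not be adjacent in
the proposed worth ordering are rejected outright; this keeps the pair of
moves exactly reversible, and the acceptance ratio combines the likelihood,
the two prior terms, the proposal ratio (with $2^{N-1}-1$ unordered
two-way splits of an $N$-member cluster) and the Jacobian. Births are
attempted with probability $b_K$ = 1, 0, or 1/2 at $K = 1$, $K = J$, and
interior $K$ respectively; the acceptance ratio uses the actual attempt
probabilities, so any choice is valid — the symmetric interior choice
simply maximises mixing. Shuffle moves at fixed $K$ are unnecessary since
any reshuffle is reachable by a birth followed by a death. The bijection,
its inverse, its Jacobian, and the density of $u$ are kept as one pluggable
unit in the source so an alternative split map is a local change.

**Augmented worth updates.** At a fixed partition the worths are updated by
exact Gibbs sampling after a latent-variable augmentation: each ranking
stage with a non-trivial denominator receives an independent latent
$y \sim \mathrm{Exponential}(\text{that stage's denominator})$. Conditional
on the latents, each cluster worth is Gamma with shape $a$ plus the number
of stages won by the cluster's members, and rate $b$ plus
$\sum_s y_s \times (\text{cluster members still remaining at stage } s)$.
Latents are regenerated fresh on every sweep and never persisted across
partition moves, so the reversible-jump ratio always acts on the
non-augmented posterior. One sweep per iteration (`n_aug = 1`) is the
default; correctness holds for any `n_aug >= 1`.

**Initialisation and burn-in.** The default start is all singletons
($K = J$) with worths drawn from the slab, so rank-clusters form during
estimation rather than being imposed; the all-in-one start is available,
and agreement of posteriors from the two extremes is part of the test
suite. Summaries discard the first half of the chain by default.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `nu` | Poisson rate on the number of rank-clusters | 2 | Small values encourage fusion; `nu = J` discourages it. Sensible practice is to fit at a vague value and check sensitivity. |
| `a`, `b` | Gamma slab shape and rate (unitless; worths are scale-free) | 1, 1 | Generally non-influential because the likelihood is scale-invariant, but `a` should leave density near 0 so extreme worth ratios stay reachable. |
| `n_iters` | recorded iterations | 2000 (function default) | Applications in the literature of this model family use $10^4$–$10^5$; always run several seeds. |
| `n_aug` | Gibbs sweeps per iteration | 1 | More sweeps lower worth autocorrelation at fixed cost per sweep. |

## Numerical choices

* Likelihood evaluation is in log space; the user-facing evaluators guard
  stage denominators with log-sum-exp so worth ratios spanning hundreds of
  orders of magnitude stay finite.
* Cluster worths must be pairwise distinct (a tie has probability zero and
  would silently merge clusters); proposed children that tie, and Gibbs
  draws that tie, are rejected and redrawn.
* The split/merge bijection round-trips to floating-point precision
  (relative error below $10^{-13}$ in the test battery); acceptance-ratio
  reversibility holds to $10^{-10}$.
* The MAP partition breaks posterior-mode ties toward the partition seen
  earliest in the chain, with a warning.
* Posterior worths are normalised post hoc to sum to one. Any fixed scale
  is valid by ratio invariance; the simplex scale makes each worth the
  probability of being the population's first choice.
* The posterior predictive discrepancy is a chi-square-style statistic on
  pairwise win counts, with denominator guard $10^{-8}$. Expected counts
  are exact (Bradley-Terry form per co-consideration) whenever every
  ranking orders its full considered set — which covers complete rankings
  and pairwise data — and are otherwise estimated by Monte Carlo over the
  observed design, since no closed form exists for genuinely partial
  prefixes.

## The synthetic-data generator

`make_true_worths()` reproduces the canonical simulation design of this
model family: equal-sized rank-clusters whose worths form the geometric
sequence $4^0, 4^1, \dots$, so consecutive tiers are separated fourfold and
a one-tier head-to-head is won at probability 0.8 — strong but not
absolute separation. `generate_dataset()` draws each judge's considered
set uniformly among size-$S$ subsets and ranks the top $R$ sequentially.
The label $K = 1$ conventionally denotes the all-singleton regime ("every
object is independent"); `k1_means_singletons = FALSE` selects the literal
single-cluster reading instead. The generator emulates exchangeable judges
with a common worth vector; it does not emulate judge heterogeneity,
covariates, presentation-order effects, or observed ties, so passing
recovery tests demonstrate correctness of the inference machinery under
the model's own assumptions, not robustness to their violation.

## Validation and problem sizes

The package validates itself at sizes chosen to make exact oracles
available and runs short: likelihood normalisation by brute-force
enumeration up to $J = 5$; prior recovery of a no-data chain against the
enumerated partition prior at $J = 4$ (50,000 iterations); posterior
recovery against a quadrature oracle at $J = 3$, $I = 20$, where the
per-partition marginal likelihood reduces to a Dirichlet integral because
the Gamma scale integrates out of the scale-free likelihood; and a scaled
recovery study at $J = 8$, two true rank-clusters, $I \in \{100, 400,
1600\}$ complete rankings, five replicates per setting and 10,000
iterations per fit, reporting worth MAE after normalisation and mean
co-clustering probabilities over truly-fused and truly-separate pairs.
`scripts/acceptance.R` re-runs the $I = 400$ study end to end from a seed.

## Known limitations

* Tied observations (a judge declaring indifference) have no likelihood
  here; ties live only at the population level through the prior.
* No judge covariates or mixture-of-judges heterogeneity.
* Reversible-jump mixing over partitions degrades as $J$ grows; for large
  $J$ run multiple chains from dispersed starts and compare partition
  summaries, not just worth traces.
* The truncated-Poisson partition prior is intentionally vague; fields
  with strong prior knowledge about the number of tiers would want the
  negative-binomial style alternatives, which are out of scope here.
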
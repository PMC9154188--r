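---
title: "Backbone extraction: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone extraction: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbackbone)
```

A complex network **N** — weighted, a weighted bipartite projection, or
unweighted — often carries more edges than signal. Its *backbone* **N′** is a
sparse, unweighted (optionally signed) subgraph that keeps the edges carrying
important structure. netbackbone implements three families of backbone
models, one per input type, plus the inferential machinery they share. This
vignette explains each model, its assumptions, the tunable parameters, the
numerical choices behind the implementation, and what the synthetic test
networks do and do not demonstrate.

## Weighted networks

**Global threshold** (`global_threshold()`). Keeps edge (i, j) when
$w_{ij} > t$, strictly. `upper` may be a number or a function of the
adjacency matrix; a function is evaluated over *all* $n^2$ cells of the
matrix, zeros and diagonal included, so `upper = mean` is the mean cell
value, not the mean edge weight. This convention changes results (on the
fixed 10-node toy network it gives $t = 1162/100 = 11.62$) and is stated
prominently for that reason; both conventions coincide qualitatively there,
and we keep the all-cells form because thresholds are usually quoted against
the raw matrix. An optional `lower` threshold retains existing edges with
$w_{ij}$ strictly below it as negative edges; it is off by default because
signed extraction is primarily meaningful for the statistical models.

The global model is *structural* (no null model) and known to fail on
long-tailed, multi-scale weight distributions: a single threshold cannot be
right in both a high-weight and a low-weight region at once.

**Disparity filter** (`disparity()`). A *local, statistical* model. Under
the null, a node's strength $s_i = \sum_j w_{ij}$ is split uniformly at
random across its $k_i$ edges (the spacings of $k_i - 1$ uniform points on
the unit interval). The probability that a share exceeds the observed
normalized weight $p_{ij} = w_{ij}/s_i$ is
$$a_{ij} = (1 - p_{ij})^{k_i - 1}, \qquad k_i > 1 .$$
Numerical choices, all deterministic:

* **Edge-level combination.** $p^{upper}_{ij} = \min(a_{ij}, a_{ji})$: an
  edge survives if it is significant from *either* endpoint, the published
  rule for this filter.
* **Degree-1 endpoints** contribute $a = 1$ (the exponent $k-1 = 0$ would
  otherwise make $0^0$ conventions matter); such an edge can still enter
  through its other endpoint.
* The null is continuous, so $p^{lower} = 1 - p^{upper}$ exactly.
* A node of zero strength has no edges, hence nothing to test.

The filter is invariant under uniform rescaling $w \to cw$, and on a star
with $n$ equal spokes the hub-side value is $(1 - 1/n)^{n-1}$ for every
spoke — two properties the test suite checks.

## Bipartite projections

The projection $\mathbf P = \mathbf B \mathbf B'$ of a binary incidence
matrix counts shared artifacts, and its weights are inflated by both agent
degrees (row sums $d_i$) and artifact degrees (column sums $f_k$). The five
models below test the observed $P_{ij}$ against nulls that constrain the
margins of **B** to different degrees; all p-values are computed for *every*
dyad, including zero-weight ones, so that signed extraction can mark
significantly *weak* pairs.

* **SDSM** (`sdsm()`): margins fixed *in expectation*. Cell probabilities
  come from the maximum-entropy bipartite configuration model
  ($Q_{ik} = x_i y_k/(1 + x_i y_k)$, `bicm_fit()`), chosen over historical
  regression-based estimators because it is deterministic, dependency-free,
  and exactly margin-consistent; the estimator is recorded in the result
  metadata. Under the null, $W_{ij}$ is Poisson-binomial with parameters
  $\{Q_{ik} Q_{jk}\}_k$.
* **fixedrow**: agent degrees fixed exactly, artifacts chosen uniformly —
  $W$ is hypergeometric (population $c$, successes $d_i$, draws $d_j$).
* **fixedcol**: artifact degrees fixed exactly — artifact $k$ contains a
  given pair with probability $\pi_k = (f_k/r)\,((f_k-1)/(r-1))$ and $W$ is
  Poisson-binomial.
* **fixedfill**: only the total fill $q = \sum B/(rc)$ fixed —
  $W \sim \mathrm{Binomial}(c, q^2)$.
* **FDSM** (`fdsm()`): both margins fixed exactly. The null has no closed
  form; we sample the margin class with curveball trades.

**Poisson-binomial evaluation.** Exact dynamic-programming convolution of
the PMF up to 1024 parameters (quadratic cost, negligible at that size),
then a refined normal approximation with skewness and continuity
corrections. The crossover is configurable
(`poisson_binomial_tail(exact_limit = )`); 1024 keeps every desk-scale
problem exact while bounding the cost of very wide incidence matrices.

**Curveball chain** (`curveball_sample()`). A trade picks two agents at
random and re-deals their non-shared artifacts, preserving both margins
exactly. `fdsm()` uses a sequential chain with $5r$ trades between retained
samples (and before the first), a spacing at which the chain decorrelates
quickly on the instance sizes the package targets; the test suite verifies
uniformity over an enumerable margin class. Seeds are exposed everywhere and
never touch the caller's RNG state.

**Empirical p-values** use the add-one estimator
$(1 + \#\{W^* \ge P_{ij}\})/(\text{trials}+1)$, so a p-value is never
exactly 0 and multiple-test corrections receive usable input. When `trials`
is omitted, the automatic rule picks the smallest $n$ whose 95% binomial
confidence half-width at $p = \alpha$ is at most $\alpha/10$
($n = \lceil 1.96^2\,\alpha(1-\alpha)/(\alpha/10)^2 \rceil$, about 7,300 at
$\alpha = 0.05$). This is a documented calibration of this package, not a
reproduction of any particular historical trial count.

## Unweighted networks

`sparsify()` composes four explicit steps — *score, normalize, filter,
connect* — and two presets name the standard combinations:
`sparsify_lspar()` (Jaccard scores; community-preserving) and
`sparsify_localdegree()` (neighbour-degree scores; hub-preserving).

Decisions the literature leaves open, fixed here deterministically:

* **Open neighbourhoods** for Jaccard and triangle scores: a node is not
  its own neighbour, so on a triangle each edge scores $1/3$.
* **Competition ranking** within each node (ties share the best rank), and
  a retention budget of $\lceil d^s \rceil$ edges for a node of degree $d$,
  $s \in [0,1]$. At $s=0$ every node keeps its top edge(s); at $s=1$
  everything survives; ceilings make the budget integral without random
  tie-breaking.
* **Union semantics**: an edge is kept if either endpoint retains it.
  Consequently no non-isolated node is isolated by the degree filter — the
  connected-node reduction of both presets is 0% by construction.
* **Spanning-tree connector** (`umst = TRUE`): "union of minimum spanning
  trees" is interpreted on similarity scores, i.e. *maximum*-score spanning
  trees (equivalently minimum trees of distance $1/\text{score}$). An edge
  belongs to some maximum tree exactly when its endpoints are not connected
  by strictly higher-scoring edges, which we evaluate by processing score
  tie-groups against a union-find forest. Adding these edges preserves the
  component count.
* The quadrangle-completion score family is not implemented; triangle
  counts are the closed-neighbourhood option provided.

## Inference

Statistical models return, at `alpha = NULL`, a tibble of per-dyad
weights and upper/lower-tail p-values (`backbone_result`); extraction is a
separate, cheap step (`extract_backbone()`), so several significance levels
can be tried without re-computing p-values. Conventions:

* strict inequality $p < \alpha$;
* family size $m$ = dyads with a defined p-value (positive-weight dyads for
  unsigned extraction; all dyads for signed extraction under bipartite
  models);
* signed extraction is two-tailed at $\alpha/2$ per tail, each tail
  adjusted separately over the same $m$ (the corrections only increase
  p-values, so the positive and negative edge sets cannot overlap);
* corrections are delegated to `stats::p.adjust`
  (none/bonferroni/holm/BH/BY).

`familywise_rate(m, alpha)` $= 1-(1-\alpha)^m$ quantifies why corrections
matter: testing 9,678 dyads at $\alpha = 0.001$ leaves a 99.99% chance of
at least one false-positive edge.

`narrative_text()` renders the provenance of any backbone as
manuscript-ready text. Reduction percentages are rounded to one decimal
with a trailing ".0" trimmed (so both "91.4%" and "40%" print naturally);
edge reduction counts undirected positive-weight edges, connected-node
reduction counts nodes of degree at least one.

## Synthetic networks and what the tests show

The generators in this package define the test conditions:

* `toy_weighted()` — a fixed 10-node, 21-edge multi-scale network: two
  hub-and-spoke clusters (spoke weights 10 and 100, internal weights 1 and
  10) bridged by a weight-75 edge. The global mean threshold (11.62) keeps
  only the five heavy edges and drops the entire low-weight cluster, while
  the disparity filter at $\alpha = 0.05$ recovers the nine hub-spoke edges
  of both clusters — the canonical demonstration of why multi-scale weights
  defeat global thresholds.
* `bipartite_blocks()` — 3 matched groups of 10 agents and 25 artifacts,
  within-group edge probability 0.8 against 0.2 between. The projection is
  complete or nearly so, hiding the groups; SDSM recovers them.
* `sbm_graph()` — SBM with 3 blocks of 20 and 0.75/0.25 edge
  probabilities, the community-recovery testbed for L-Spar at $s = 0.5$.
* `pa_graph()` — preferential attachment with $n = 60$, $m = 3$, the
  hub-recovery testbed for Local Degree at small $s$.

These sizes keep every oracle comparison exhaustive or near-exhaustive
(complete enumeration of $2^n$ Bernoulli outcomes and of margin classes;
20,000-trial Monte-Carlo runs) while the whole suite runs in well under a
minute of compute per heavy block. Passing tests show the implementations
agree with their definitions and nulls *under these generative conditions*;
they do not certify behaviour on real networks with degree correlations,
weight–degree dependence, or scales far beyond the fixtures, and FDSM
p-values on large matrices remain Monte-Carlo estimates with the stated
confidence, not exact values.

## Limitations

* Undirected networks only; directed variants, multigraphs, and node/edge
  attributes beyond labels and weights are out of scope.
* Only the agent-side projection of a bipartite network is modelled
  (transpose the incidence matrix for the artifact side).
* The model-suggestion heuristic (`suggest_model()`) inspects only the
  value of the matrix (binary/symmetric/integer structure); it is a
  documented approximation, not an oracle, and a weighted integer symmetric
  matrix that is *not* a projection will still trigger the projection
  advisory.
* FDSM cost grows linearly in trials and trades; at conservative
  significance levels the automatic trial rule makes it expensive by
  design — use `sdsm()` when the expected-margin null is acceptable.
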
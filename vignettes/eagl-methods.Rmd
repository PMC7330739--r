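---
title: "Spectral summarization of temporal comorbidity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral summarization of temporal comorbidity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eagl)
```

## The model

A temporal Bayesian network of multiple chronic conditions (MCC) has one
binary node per (condition, year) pair — `PTSD_Y2` is the presence of
post-traumatic stress disorder in year 2 — and directed edges pointing
forward in time. The joint distribution factorizes over the DAG,

$$P(x_1,\dots,x_n) = \prod_i P(x_i \mid \mathrm{Pa}(x_i)),$$

with one conditional probability table (CPT) per node. Everything in this
package is built for binary nodes (r = 2); rows with missing entries are
rejected rather than imputed.

Two tasks share a single spectral criterion:

1. **Learn** a sparse DAG directly from a patient-year cohort.
2. **Summarize** a given graphical model by pruning edges, with or
   without a supporting data set.

The criterion is the second-smallest eigenvalue $\lambda_2$ of a graph
Laplacian — algebraic connectivity. For an undirected graph
$L = D - A$; $\lambda_2 = 0$ exactly when the graph is disconnected, and
for a connected graph it measures the sparsest cut: how much redundant
connectivity the graph carries. An edge whose removal barely moves
$\lambda_2$ is structurally redundant; an edge whose removal collapses it
is a bridge.

## Laplacians for directed graphs

The package exposes three variants (`lap_config()`):

* `undirected` — the combinatorial $L = D - A$; requires a symmetric
  adjacency (used for lexicon graphs). Weighted degrees are used
  throughout, as co-occurrence graphs need.
* `directed_total` — the default for directed models: $L = D - A$ with
  $D = \mathrm{diag}(d^{in} + d^{out})$, symmetrized as $(L + L^T)/2$.
  The quadratic form of a single edge $(i, j)$ is
  $x_i^2 + x_j^2 - x_i x_j \ge 0$, so **adding an edge never decreases
  any eigenvalue**. This is what a sparsity penalty needs: $\lambda
  \cdot \lambda_2$ always charges for extra connectivity, and
  $\lambda_2$ decays monotonically as a summarizer prunes.
* `directed_chung` — the normalized construction
  $L = I - \tfrac12(\Phi^{1/2} P \Phi^{-1/2} + \Phi^{-1/2} P^T
  \Phi^{1/2})$, where $P$ is the row-normalized adjacency with dangling
  rows replaced by the uniform distribution, smoothed by PageRank-style
  teleportation (default damping 0.85, configurable; teleportation is
  required because a DAG is never ergodic), and $\Phi$ its stationary
  distribution, obtained by direct solve for $n \le 200$ and power
  iteration to $10^{-12}$ beyond.

Why `directed_chung` is *not* the default deserves a paragraph, because
we changed our minds while building the package. On a sparse DAG most
rows are dangling, so the smoothed walk is close to the uniform chain —
the fastest-mixing chain there is — and $\lambda_2$ is *large*. Adding
structure creates bottlenecks and *lowers* $\lambda_2$: measured on a
25-node fixture, an 18-edge fit had $\lambda_2 = 0.41$ and a 24-edge fit
$0.36$. A penalized search exploits this immediately and adds edges to
buy connectivity down, inverting the intended effect. A restriction of
the spectrum to non-isolated nodes fails differently: pendant edges then
lower $\lambda_2$, and a strongly penalized search grows pendants. The
total-degree symmetrization has neither pathology, and is the
construction the in+out-degree phrasing of the method describes. The
normalized variant remains available and fully tested (its closed forms:
the 2-cycle at teleport 1 gives $L = [[1,-1],[-1,1]]$; a reciprocated
digraph reduces to the symmetric normalized Laplacian of its undirected
skeleton).

"Second eigenvalue" always means second-*smallest* (the Fiedler value);
the sparsest-cut interpretation fixes that reading. Numerical policy:
spectra come from a dense symmetric eigensolver (`eigen(symmetric =
TRUE)`); eigenvalues in $[-10^{-9}, 0)$ are round-off and clipped to 0;
a matrix below $-10^{-9}$ (relative) raises an error.

## Learning: MWST + K2 with the spectral penalty

1. **Ordering.** Pairwise mutual information (plug-in estimate, natural
   log, clipped at 0; constant columns get MI 0 with a warning) feeds a
   maximum-weight spanning tree (Prim, ties broken toward the smaller
   node-index pair). The ordering is the breadth-first traversal from
   the root — by default the node with the largest total MI. For
   temporal columns the ordering is then stably re-sorted by year, so a
   parent can never follow its child's year.
2. **Parent search.** In ordering sequence, each node greedily adds the
   admissible parent that most improves the penalized score, stopping
   when nothing improves or `max_parents` (default 5) is reached.
   Admissible parents of $(c_j, y_t)$ are nodes $(c_i, y_s)$ with
   $s < t$, or $s = t$ and $i < j$ in the declared condition order
   (same-year edges are configurable off). A node with no admissible
   parents is simply parentless.
3. **Scores.** The local score is the Cooper–Herskovits (K2) log
   marginal likelihood
   $\sum_j [\log(r-1)! - \log(N_j + r - 1)! + \sum_k \log N_{jk}!]$
   computed with `lgamma`, or the AIC score (maximized log-likelihood
   minus $(r-1) r^{|\mathrm{Pa}|}$, with $0 \log 0 = 0$). The penalty
   $\lambda \cdot \lambda_2$ is evaluated, by default, on the candidate
   graph including the edge under test (`penalty_reference =
   "candidate"`); the `"previous"` mode freezes it at the last accepted
   graph, which makes the penalty a constant within a node's inner loop
   and is kept for fidelity experiments. No rescaling is applied to
   bridge the log-likelihood and eigenvalue scales — the canonical grid
   $\lambda \in \{0, 10^{-2}, \dots, 10^5\}$ spans them.

Two structural facts matter for interpreting sweeps. First,
$\lambda_2 = 0$ whenever two or more nodes carry no edge at all, so the
penalty is inert until the learned structure spans its node grid; on a
sparse ground truth whose fit leaves untouched node-years, the sweep is
flat — there is nothing for the penalty to prune. The regime the method
is for is a dense or spurious-edge-contaminated model that spans its
nodes, and that is the fixture our sweep demonstrations use. Second,
`eagl_sweep()` implements the stopping heuristic of watching
$\lambda_2$: once increasing $\lambda$ stops changing the learned
graph's $\lambda_2$ (change below $10^{-6}$ between grid points, with
`early_stop = TRUE`), larger values are not visited.

## Summarization

Given a model (directed temporal net or weighted undirected graph):

1. A depth-first-search spanning forest of the *undirected view* is
   extracted once, rooted at the year-1 nodes (or node 1), neighbors
   visited in index order, and **frozen**: its edges are never removal
   candidates. This is what guarantees no isolated nodes. Protection
   concerns connectivity, not direction, hence the undirected view; the
   skeleton is not recomputed between rounds because re-deriving it on a
   shrinking graph could silently shift which edges are protected.
2. Every candidate edge is scored by the **relative** change
   $|\lambda_2(G) - \lambda_2(G \setminus e)| / \lambda_2(G)$ (pure
   function; the graph is untouched). When $\lambda_2 \le 10^{-9}$ the
   absolute change is used instead and the trace flags the fallback.
   Ties are broken lexicographically by (source, target), so runs are
   deterministic.
3. `mode = "single"` removes the argmin each round; `mode = "multi"`
   removes every candidate below the threshold in one round. The loop
   stops when the minimum relative change exceeds the threshold
   (default 0.05, read as the relative fraction, i.e. a 5% change) — or,
   if a `target_ratio` is set, the ratio drives the loop alone until
   $\lfloor \mathrm{ratio} \cdot e_0 \rfloor$ edges are gone. A ratio
   that would require touching the skeleton stops early with a recorded
   warning: a connected graph on $n$ nodes cannot drop below $n - 1$
   edges, so e.g. a 70% summarization of 200 pairs over 100 terms halts
   at the 99-edge skeleton, while over 50 terms it reaches exactly 60
   edges.
4. With supporting data the CPTs are re-estimated once, on the final
   structure — not after every removal; parameter re-estimation is the
   terminal step, and a per-round mode is deliberately not offered.
   Without data, surviving edge weights are bit-identical to the input.

## Inference and evaluation

CPT estimation uses additive smoothing,
$P(x{=}1 \mid pa) = (N(1, pa) + c)/(N(pa) + 2c)$ with pseudo-count
$c = 1$ by default; with $c = 0$ an unseen configuration is set to 0.5
and flagged. Posteriors are exact, by variable elimination in reverse
topological order (binary factor tables; evidence with zero probability
raises an explicit error). Year-ahead prediction conditions on the
year-1 nodes only, matching the design of predicting years 2–5 from
year-1 status; a `cumulative` flag (off by default) conditions on all
years before the target instead. AUC is the rank-based Mann–Whitney
statistic with half-credit for ties; cross-validation shuffles patients
by seed into k near-equal unstratified folds (a stratified option is not
offered; folds whose test outcome is single-class are recorded as
missing and skipped). Per-fold AUCs are averaged; pooling predictions
across folds was considered and not adopted, to keep fold-level
variability visible.

## The synthetic cohort generator

The restricted clinical cohort behind the method cannot be shipped, so
the package generates layered binary networks that emulate its shape:
five conditions (TBI, PTSD, BaPa, SuAb, Depr) over five years, with CPTs
built from a logistic link

$$\mathrm{logit}\, P(x{=}1 \mid pa) = \mathrm{logit}(\textrm{base}) +
\textstyle\sum_{p \in pa, x_p = 1} \beta_p,$$

effects capped at $|\beta| \le 30$ (saturation: the child becomes a
near-copy of the parent). Defaults, chosen once as a realistic regime
for this veteran-cohort literature:

* year-1 prevalences 0.20 (TBI), 0.30 (PTSD), 0.35 (BaPa), 0.20
  (SuAb), 0.30 (Depr); spontaneous onset in later years at half the
  prevalence — incident onset is rarer than prevalent status, which is
  also what makes year-ahead prediction informative;
* persistence log-odds 2.2 on same-condition year-to-year edges; 18
  default true edges: full persistence for the chronic conditions
  (PTSD, BaPa, Depr), fading persistence for TBI (year 1→2 only) and
  SuAb (through year 4), plus cross-condition links TBI_Y1→PTSD_Y2 and
  PTSD_Y1→Depr_Y2 at log-odds 1.2;
* no node has more than two parents and every parent pair has joint
  mass above ~6%, so CPTs are estimable to within 0.02 from
  50,000-patient samples — a property the test suite asserts;
* under these defaults the true model's cross-validated year-2 AUCs
  land between 0.71 and 0.78, inside the 0.63–0.85 band reported for
  the real cohort. This calibration is a convenience for shaping experiments,
  not a claim of matching the clinical data.

`bn_spec_recovery()` is the compact benchmark: 3 conditions × 5 years,
18 true edges, every node on a persistence chain — so learned structures
span the grid and the spectral penalty is live.
`inject_spurious_edges()` adds temporally legal random edges with small
effects (cap 0.3 by default), labeling them so experiments can ask
whether summarization removes the right edges.
`make_lexicon_graph()` emulates the term-co-occurrence use case: a
random recursive tree for connectivity plus random extra pairs, with
heavy-tailed (Zipf-like) integer weights; defaults 100 terms, 200 pairs.

What the generator deliberately does not emulate: demographic
covariates, enrollment and dropout, diagnostic-code noise, secular
trends, and the long-tailed comorbidity spectrum of real claims data.
Green tests therefore certify the algorithms' contracts on controlled
regimes, not clinical performance.

## Problem sizes used by the shipped experiments

Structure recovery runs five cohorts of m = 20,000 from the 15-node
benchmark over the canonical λ grid; summarization experiments use five
contaminated 48-edge models with m = 5,000 (70/30 train/test);
cross-validation demonstrations use m = 10,000 with k = 5. These sizes
were chosen so the whole experiment battery completes in a few minutes
on one core while keeping binomial noise well below the effects being
measured.

## Known limitations

* The greedy K2 sweep is ordering-dependent by design; a poor MWST
  ordering cannot be repaired downstream.
* The spectral criterion is purely structural: with supporting data it
  re-estimates parameters but never consults the likelihood when
  choosing which edge to drop, so a statistically informative edge that
  is structurally redundant can be pruned; the mild-ratio regime keeps
  this risk small, heavy ratios do not.
* $\lambda_2$ of a non-spanning structure is 0, so the learning penalty
  cannot distinguish among structures that leave two or more node-years
  untouched.
* Only binary variables; no missing data; exact inference scales
  exponentially in treewidth and is intended for the ≤ 25-node models
  this domain uses.
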